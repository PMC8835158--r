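Package: eegdyn
Title: Spatio-Temporal Dynamics of Resting-State EEG: Microstates and
    Omega Complexity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the spatio-temporal dynamics of
    multichannel resting-state EEG. Temporal dynamics are characterised by
    microstate segmentation: global field power (GFP), topographic
    atomize-and-agglomerate hierarchical clustering (TAAHC) into four
    polarity-invariant classes, backfitting, global explained variance,
    and the duration / occurrence / contribution / transition-probability
    parameters. Spatial dynamics are characterised by omega complexity,
    the exponential of the Shannon entropy of the trace-normalised
    eigenvalues of band-wise cross-spectral matrices, at whole-scalp and
    anterior/posterior regional scopes. Includes a synthetic-EEG cohort
    generator with planted group effects, a mixed repeated-measures ANOVA
    battery with Greenhouse-Geisser correction and effect sizes, and
    nested cross-validated support-vector-machine classification with ROC
    analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    car,
    jsonlite,
    yaml,
    tibble,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
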