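# eegdyn

Spatio-temporal dynamics of resting-state EEG: microstate segmentation
and omega spatial complexity, with group statistics and SVM
classification.

Resting EEG carries two complementary kinds of structure. In time, the
scalp potential field passes through a small set of quasi-stable
topographies — *microstates* of roughly 60–120 ms, conventionally four
classes A–D — whose duration, occurrence rate, coverage and transition
probabilities index large-scale network dynamics. In space, the degree
of synchronization across channels within a frequency band is captured
by *omega complexity*, an eigenvalue-entropy measure of the band's
cross-spectral matrix. Shifts in both families (e.g. a higher class-B
occurrence, a shorter class-C lifetime, reduced high-frequency omega
complexity) have been reported in subclinical depression, and combining
them improves two-group discrimination. `eegdyn` implements this whole
analysis as a tested, reproducible pipeline, together with a synthetic
cohort generator that plants known effects so every stage can be
validated against ground truth.

## Methods at a glance

**Global field power.** For average-referenced potentials
`v_i(t)`, GFP(t) = sqrt( Σ_i (v_i(t) − v̄(t))² / n ) — the spatial
standard deviation of the momentary scalp map. GFP peaks are the moments
of highest topographic signal-to-noise and supply the maps for
clustering.

**Microstates.** Data are bandpassed to 2–20 Hz; the GFP-peak maps are
clustered by TAAHC (topographic atomize & agglomerate hierarchical
clustering): every map starts as a singleton cluster, and the cluster
contributing least global explained variance is repeatedly dissolved,
its members reassigned by absolute spatial correlation, until four
clusters remain (polarity is ignored throughout; prototypes are the
sign-invariant first principal direction of their members). Prototypes
are labelled A–D against canonical templates, backfitted to the data
(peaks by max |r|, other samples from the nearest peak), and summarised
as duration (ms), occurrence (/s), contribution (%) and the 12 ordered
transition probabilities. Fit quality is GEV =
Σ_t (GFP(t)·corr(v(t), p_label(t)))² / Σ_t GFP(t)².

**Omega complexity.** Per 2-s Hann-tapered epoch, channel Fourier
coefficients give, per 0.5 Hz bin, a cross-spectral matrix
C(f) = ⟨u(f) u(f)^H⟩ averaged over epochs. With eigenvalues λ_i of C and
λ′_i = λ_i/Σλ, Ω = exp(−Σ λ′_i log λ′_i) ∈ [1, K]: 1 means a single
spatial mode (full synchronization), K (the channel count) means a
uniform eigenvalue spectrum (maximal spatial complexity). Band values
average the per-bin Ω over delta (1–3.5), theta (4–7.5), alpha-1 (8–10),
alpha-2 (11–13), beta-1 (13–20), beta-2 (20–30) and gamma (30–45 Hz), at
the global 30-channel scope and 7-channel anterior (Fp1 Fp2 F7 F3 Fz F4
F8) and posterior (T5 T6 P3 P4 Pz O1 O2) scopes.

**Statistics and classification.** Mixed repeated-measures ANOVAs
(group × class, group × transition pair, group × scalp region) with
Mauchly sphericity checks, Greenhouse–Geisser correction and partial
η²; Bonferroni post hoc t-tests with pooled-SD Cohen's d; Wilcoxon
fallback; Spearman correlations with the symptom score. Classification
uses z-scored features and linear / Gaussian-RBF SVMs tuned by grid
search inside nested cross-validation (leave-one-out outer, stratified
5-fold inner), reporting accuracy and ROC/AUC from pooled out-of-fold
decision values, for microstate-only, omega-only and combined feature
sets.

## Worked example

```r
library(eegdyn)

spec     <- cohort_spec(n_per_group = c(6, 6), duration_s = 20, seed = 1)
cohort   <- make_cohort(spec)                    # two groups, planted effects
features <- extract_features(cohort, max_maps = 300, seed = 1)
features[, c("subject", "group", "score", "gev",
             "occurrence_B", "duration_C", "omega_global_gamma")]
#>   subject group score   gev occurrence_B duration_C omega_global_gamma
#> 1 S001    HC        4 0.759         2.1       122.                5.15
#> 2 S002    HC        1 0.747         2.85       94.3               5.70
#> 3 S003    HC        6 0.761         2.2       111.                5.50
#> 4 S004    HC       13 0.747         2.45       91.1               5.31
#> # ... 8 more rows
```

Each row is one subject: `gev` is the fraction of GFP-weighted variance
the four fitted prototypes explain (~0.75 at the generator's
signal-to-noise ratio of 10), `occurrence_B` and `duration_C` are the
microstate parameters carrying the planted group effects, and
`omega_global_gamma` is the 30-channel gamma-band spatial complexity.

```r
st <- stats_battery(features)
st$global_omega[st$global_omega$band %in% c("beta2", "gamma"), ]
#>    band test statistic        p cohens_d mean_HC mean_ScD
#> 1 beta2    t     -8.97 4.28e-06    -5.18    4.78     3.90
#> 2 gamma    t    -10.20 1.33e-06    -5.89    5.43     4.39
```

Group-2 ("ScD") subjects were generated with extra beta-2/gamma
common-mode synchronization, so their omega complexity is lower; the
independent-samples t-tests recover exactly that direction.

```r
rep <- nested_cv_svm(features, default_feature_sets()$combined,
                     classifier_config(kernels = "linear", seed = 1))
rep
#> <classification_report> positive class: ScD
#>  kernel accuracy auc  n
#>  linear        1   1 12
```

With both effect families planted at these sizes the combined feature
set separates the groups perfectly under leave-one-out nested CV.

`run_all(run_config(seed = 1, out_dir = "run1"))` executes the whole
chain (simulate → features → statistics → classification) and writes a
CSV/JSON results bundle with a provenance manifest; rerunning the same
config reproduces it bit-identically. A thin command-line front end with
the same stages as subcommands is installed at `inst/cli/eegdyn.R`.

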