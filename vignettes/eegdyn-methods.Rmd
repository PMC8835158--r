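---
title: "Microstates and omega complexity: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstates and omega complexity: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the scientific model behind `eegdyn`, the
parameters that matter, the numerical decisions taken where the
conventions of the field leave room, and what the synthetic validation
does and does not establish.

## The two measures

**Microstates.** The multichannel EEG is treated as a sequence of
momentary scalp topographies. At the peaks of global field power (GFP,
the spatial standard deviation over electrodes) the topography is most
stable and least noisy; resting EEG spends its time in a handful of
recurring, quasi-stable map families with lifetimes on the order of
60–120 ms. We fix the model order at four classes (A–D), the dominant
convention: A and B are mirrored diagonal gradients, C an
anterior–posterior gradient, D a fronto-central focal map. The quantities
of interest are per-class mean duration (ms), occurrence (complete
segments per second), contribution (fraction of time covered), the 12
ordered transition probabilities, and GEV — the fraction of GFP-weighted
variance the fitted prototypes explain.

The analysis assumes average-referenced data (all map comparisons use
zero-mean spatial vectors), a 2–20 Hz analysis band, and polarity
invariance: a map and its negation belong to the same state, because the
oscillatory carrier flips sign within a stable topography.

**Omega complexity.** For each frequency band, the channels' Fourier
coefficients define a cross-spectral matrix whose eigenvalue spectrum
describes how many independent spatial modes carry the band's power.
Omega is the exponential of the Shannon entropy of the trace-normalised
eigenvalues: 1 when a single mode carries everything (perfect
synchronization), K — the number of channels — when all eigenvalues are
equal (no preferred spatial structure). We compute it at the global
30-channel scope and at 7-electrode prefrontal and posterior scopes, in
seven classical bands from delta to gamma.

Two printed-formula ambiguities had to be resolved. First, a per-epoch,
per-bin cross-spectral "matrix" is a rank-one outer product whose omega
is identically 1; the only non-degenerate estimator averages the outer
products *across epochs* before the eigendecomposition, and then
averages per-bin omega within a band. That is what `cross_spectra` and
`band_omega` do. Second, omega is defined here strictly as
`exp(−Σ λ′ log λ′)` with `0·log 0 := 0`; this is the only form
consistent with the measure's documented range `[1, K]`. Trace
normalisation is used exactly as written — no per-channel variance
normalisation — and a correlation-normalised variant is deliberately not
the default.

## Pipeline and its parameters

| Stage | Parameter | Default | Why |
|---|---|---|---|
| bandpass | 0.5–45 Hz | — | standard resting-EEG analysis band |
| notch | 50 Hz, 4 Hz stop width | — | mains interference |
| epochs | 2 s, non-overlapping | — | gives 0.5 Hz spectral resolution |
| rejection | ±100 µV peak | — | deterministic artifact screen |
| microstate band | 2–20 Hz | fixed | microstate convention |
| clusters | 4 | fixed | classes A–D |
| peak cap | `max_maps = 1000` | per subject | agglomerative start is O(n²)-ish |
| bands | 7, half-open `[low, high)` | — | 13 Hz belongs to beta-1, not alpha-2 |
| SVM grids | C ∈ 10^(−2..2), γ ∈ 10^(−3..1) | log-spaced | small grids, nested CV guards selection |
| inner folds | 5, stratified | — | enough test samples per fold |

Artifact handling deserves a note: interactive ICA-based component
removal is standard for human recordings but is neither deterministic
nor reproducible in an automated pipeline, so `eegdyn` uses
amplitude-threshold epoch rejection instead. For synthetic data this is
exactly sufficient; for real data a user should clean the recording
first by whatever means they trust and can document.

## Numerical choices

**Filtering.** All filters are windowed-sinc (Hamming) FIR designs
applied zero-phase by multiplying the spectrum with |H(f)|² — the
magnitude response of a forward–backward pass — after odd reflection
padding. The order is chosen for a transition width of `min(1, low)` Hz
at the low edge (capped by data length), which keeps passband sinusoids
within 1 dB and attenuates one octave outside the edges by more than
20 dB. FFT application (mixed-radix length) keeps multi-thousand-tap
kernels cheap; the feature pipeline shares one forward transform across
the broadband, notch and microstate-band responses.

**TAAHC.** Initialisation is one singleton cluster per map. Each
iteration dissolves the cluster with the smallest GEV contribution
(GFP²-weighted, so low-amplitude noise maps go first) and reassigns its
members by absolute spatial correlation. Prototypes are the first
principal direction of the member maps — the sign-invariant analogue of
the mean map — computed by power iteration warm-started from the
previous prototype. Because agglomeration can merge but never split,
two genuinely distinct classes that merge early (their canonical
templates can correlate up to ~0.7) could otherwise never separate
again; a short sign-invariant k-means refinement with empty-cluster
reseeding therefore polishes the final partition (`polish = 20`,
settable to 0 for the bare agglomerative result). Ties in reassignment
go to the first (oldest) cluster.

**Group-level prototypes** are fitted in two stages: four prototypes per
subject, then TAAHC over the pooled subject prototypes. This weights
subjects equally regardless of how many clean epochs each contributes,
and every subject is backfitted with the same four group maps — the
within-subject parameters are then comparable across the cohort.

**Backfitting** labels GFP peaks by maximum absolute correlation and
lets every other sample inherit the nearest peak's label (exact
midpoints resolve to the earlier peak). No temporal smoothing or
minimum-duration pruning is applied by default. Peak interpolation
cannot represent state changes between peaks, so segment boundaries
carry a structural labelling error of up to half an inter-peak interval;
`backfit(..., interpolate = FALSE)` provides the per-sample labelling,
which is also the labelling that maximises GEV and is used when quoting
the model's explanatory ceiling.

**Degenerate inputs.** A zero map has undefined correlation and is
assigned correlation 0; an epoch without any GFP peak falls back to
per-sample labelling; a class never observed as a complete interior
segment reports `NA` duration (0 in the feature table) and occurrence 0;
a zero-trace cross-spectral matrix is an error, as is a band containing
no frequency bins.

**Mixed ANOVA.** The multivariate linear-model route (sum-to-zero
contrasts, type-III tests) supplies the Mauchly test and
Greenhouse–Geisser epsilon; GG-corrected p-values and degrees of freedom
are reported whenever Mauchly rejects at 0.05. Partial η² is
SS/(SS+SS_error) from the univariate table. Cohen's d uses the pooled
SD. The Wilcoxon fallback enumerates exactly for tie-free samples below
n = 25 per group and otherwise uses the tie-corrected normal
approximation with continuity correction.

**Classification.** Standardisation is fitted inside each training set
only — the outer held-out subject never touches the scaler or the grid
search (a test asserts this structurally). With a leave-one-out outer
loop the training sets are alternately imbalanced by one subject, which
shifts each fold's decision-value offset systematically against the
held-out class; pooled raw decision values are therefore pessimistic
under the null. Each held-out decision value is consequently taken
relative to the midpoint of the two training-class mean decision values
of its own fold, which restores exchangeability under label permutation
while leaving separable problems at AUC 1. Accuracy still uses the raw
SVM prediction.

## What the generator emulates — and what it does not

`make_cohort` builds, per subject: (i) a semi-Markov label sequence over
four planted prototype maps — gamma-distributed lifetimes (shape 4,
positive and unimodal without the excess of very short segments an
exponential would give) around per-class means of 70/85/100/115 ms,
class-to-class transitions proportional to per-class occurrence rates;
(ii) a 8–12 Hz band-limited unit-variance carrier under those maps;
(iii) seven band-limited background processes, each a weighted mixture
of 8 independent sources through an orthonormal mixing, whose geometric
weight profile sets the band's planted synchronization (and hence its
expected omega exactly, `exp(H(w))`); (iv) spatially correlated sensor
noise (half white, half exponential-decay in electrode distance — pure
white noise is unrealistically easy to cluster) at a planted
signal-to-noise power ratio, default 10; and (v) a BDI-II-like integer
symptom score, linear in the subject's planted effect deviations with
Gaussian noise, mapped into the groups' inclusion windows (1–13 and
14–27). Group 2 receives the planted contrasts: class-B occurrence
×1.3, class-C lifetime ×0.75, beta-2/gamma synchronization +0.25.
Between-subject variability is log-normal jitter (SD 0.08) on rates and
lifetimes and Gaussian jitter on synchronization levels. Everything is
deterministic given the seed; no quantitative noise calibration against
any particular acquisition hardware is claimed.

What it deliberately does not contain: no forward head model or dipole
sources, no eye-movement or muscle artifact channels, no 1/f continuum
beyond the seven band processes, no non-stationarity across the
recording, no eyes-open condition. Passing the recovery suites therefore
shows that the estimators are correct and well-calibrated under a
faithful generative model of the *measured quantities* — not that they
are robust to everything real scalp EEG can do.

## Validation problem sizes

The test suite validates at sizes chosen for a single desktop CPU:
prototype and lifetime recovery on one 20-per-group cohort of 40-s
recordings (peak cap 800); planted-effect direction recovery on 50
replicate 20-per-group cohorts of 20-s recordings (peak cap 300);
ANOVA type-I calibration on 100 null cohorts of 6 per group at 12 s;
permutation-null AUC over 50 label shuffles of one null cohort. Longer
recordings sharpen every estimate (duration estimates, omega bias);
nothing in the implementation depends on these sizes.

## Known limitations

- Peak-interpolated backfitting biases lifetime estimates: short-lived
  classes read long (segments shorter than an inter-peak interval are
  absorbed), long-lived classes read slightly short (single mislabelled
  peaks fragment them). At the default generator settings the cohort-mean
  per-class bias stays within ±10%; stronger noise or shorter lifetimes
  would widen it. Temporal smoothing is intentionally off by default.
- The sample cross-spectral matrix from E epochs biases omega downward
  (eigenvalue spread inflation), noticeably when E is not ≫ K; with 2-s
  epochs and the 30-channel scope, recordings of a few minutes are
  appropriate, and comparisons should hold epoch counts equal across
  groups.
- TAAHC with a polish step is a local optimiser; with strongly
  correlated true maps (|r| ≥ ~0.8) class identities can still merge.
  The generator refuses prototype sets above |r| = 0.8 for this reason.
- Leave-one-out outer CV yields high-variance performance estimates at
  n ≈ 40 and the decision-value calibration above is a first-order
  correction, not a guarantee of unbiasedness.
- The mixed-ANOVA battery assumes balanced within-subject designs;
  subjects missing a level are rejected rather than imputed.
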