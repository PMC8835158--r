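# Synthetic resting-EEG generator: semi-Markov microstate sequences driving
# four planted scalp topographies on a band-limited oscillatory carrier,
# plus per-band multi-mode background processes with controllable
# inter-channel synchronization, spatially correlated sensor noise, and a
# two-group cohort builder with planted effects and symptom scores.

#' Generator parameters for microstate dynamics
#'
#' @param n_classes number of microstate classes (default 4).
#' @param mean_duration_ms per-class mean segment lifetime in ms; recycled
#'   to `n_classes`. Defaults span the 60-120 ms range typical of resting
#'   microstates.
#' @param occurrence_rate_hz per-class relative occurrence rates; used to
#'   build the default transition matrix (transitions into a class are
#'   proportional to its rate).
#' @param transition_matrix optional n x n row-stochastic matrix with zero
#'   diagonal; overrides the rate-derived default.
#' @param carrier_band_hz two-element band (Hz) for the oscillatory
#'   carrier; default 8-12 Hz (dominant resting alpha rhythm).
#' @param snr signal-to-noise power ratio (prototype signal / sensor
#'   noise); `Inf` disables sensor noise.
#' @param seed integer seed.
#' @return A validated list of class `microstate_gen_params`.
#' @export
microstate_gen_params <- function(n_classes = 4,
                                  mean_duration_ms = c(70, 85, 100, 115),
                                  occurrence_rate_hz = rep(1, n_classes),
                                  transition_matrix = NULL,
                                  carrier_band_hz = c(8, 12),
                                  snr = 10,
                                  seed = 1L) {
  mean_duration_ms <- rep_len(mean_duration_ms, n_classes)
  occurrence_rate_hz <- rep_len(occurrence_rate_hz, n_classes)
  if (any(mean_duration_ms <= 0)) stop("mean durations must be positive")
  if (any(occurrence_rate_hz <= 0)) stop("occurrence rates must be positive")
  if (is.null(transition_matrix))
    transition_matrix <- rate_transition_matrix(occurrence_rate_hz)
  validate_transition_matrix(transition_matrix, n_classes)
  if (length(carrier_band_hz) != 2 || carrier_band_hz[1] >= carrier_band_hz[2])
    stop("carrier_band_hz must be (low, high) with low < high")
  if (snr <= 0) stop("snr must be positive")
  structure(list(n_classes = as.integer(n_classes),
                 mean_duration_ms = mean_duration_ms,
                 occurrence_rate_hz = occurrence_rate_hz,
                 transition_matrix = transition_matrix,
                 carrier_band_hz = carrier_band_hz,
                 snr = snr, seed = as.integer(seed)),
            class = "microstate_gen_params")
}

rate_transition_matrix <- function(rates) {
  n <- length(rates)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w <- rates
    w[i] <- 0
    P[i, ] <- w / sum(w)
  }
  P
}

validate_transition_matrix <- function(P, n) {
  if (!is.matrix(P) || nrow(P) != n || ncol(P) != n)
    stop("transition matrix must be ", n, " x ", n)
  if (any(abs(diag(P)) > 0)) stop("transition matrix diagonal must be 0")
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9))
    stop("transition matrix rows must be nonnegative and sum to 1")
  invisible(P)
}

# zero-mean unit-norm canonical class topographies on a montage:
# A: left-posterior -> right-anterior gradient; B: mirrored;
# C: anterior-posterior gradient; D: fronto-central focal map.
canonical_templates <- function(montage) {
  pos <- montage$positions
  x <- pos[, 1]; y <- pos[, 2]
  raw <- cbind(A = (x + y) / sqrt(2),
               B = (-x + y) / sqrt(2),
               C = y,
               D = exp(-((x)^2 + (y - 0.3)^2) / (2 * 0.35^2)))
  apply(raw, 2, function(v) { v <- v - mean(v); v / sqrt(sum(v^2)) })
}

#' Planted prototype topographies for the four canonical classes
#'
#' Builds the canonical A-D maps from the montage geometry and adds a
#' small seeded spatially smooth perturbation so distinct seeds give
#' distinct (but still canonical-looking) prototype sets. Maps are
#' zero-mean and unit-norm; pairwise absolute spatial correlation stays
#' below 0.8.
#'
#' @param montage an [channel_montage()] with at least 4 channels.
#' @param seed integer seed.
#' @param jitter relative amplitude of the smooth perturbation.
#' @return channel x 4 matrix with columns A-D.
#' @export
make_prototype_maps <- function(montage, seed = 1L, jitter = 0.05) {
  if (!inherits(montage, "eeg_montage")) stop("montage must be an eeg_montage")
  if (length(montage$names) < 4)
    stop("montage must have at least 4 channels with positions")
  base <- canonical_templates(montage)
  K <- exp(-montage_distances(montage)^2 / (2 * 0.35^2))
  set.seed(seed)
  pert <- K %*% matrix(stats::rnorm(nrow(base) * 4), ncol = 4)
  pert <- apply(pert, 2, function(v) { v <- v - mean(v); v / sqrt(sum(v^2)) })
  maps <- base + jitter * pert
  maps <- apply(maps, 2, function(v) { v <- v - mean(v); v / sqrt(sum(v^2)) })
  colnames(maps) <- c("A", "B", "C", "D")
  cc <- abs(stats::cor(maps))
  if (max(cc[upper.tri(cc)]) >= 0.8)
    stop("prototype maps insufficiently distinct (|r| >= 0.8)")
  maps
}

#' Sample a semi-Markov microstate label sequence
#'
#' Segment lifetimes are gamma-distributed (shape 4) around the per-class
#' mean; successive segment classes follow the transition matrix, so two
#' adjacent segments never share a class.
#'
#' @param params a [microstate_gen_params()] object.
#' @param duration_s sequence length in seconds.
#' @param fs_hz sampling rate in Hz.
#' @param seed optional seed override (defaults to `params$seed`).
#' @return Integer vector of per-sample class labels (1-based).
#' @export
sample_state_sequence <- function(params, duration_s, fs_hz,
                                  seed = params$seed) {
  stopifnot(inherits(params, "microstate_gen_params"))
  n_samp <- round(duration_s * fs_hz)
  if (n_samp < 1) stop("duration_s * fs_hz must be at least 1")
  validate_transition_matrix(params$transition_matrix, params$n_classes)
  set.seed(seed)
  shape <- 4
  labels <- integer(n_samp)
  pos <- 1L
  state <- sample.int(params$n_classes, 1,
                      prob = params$occurrence_rate_hz)
  while (pos <= n_samp) {
    mean_samp <- params$mean_duration_ms[state] / 1000 * fs_hz
    len <- max(1L, round(stats::rgamma(1, shape = shape,
                                       scale = mean_samp / shape)))
    end <- min(n_samp, pos + len - 1L)
    labels[pos:end] <- state
    pos <- end + 1L
    state <- sample.int(params$n_classes, 1,
                        prob = params$transition_matrix[state, ])
  }
  labels
}

# band-limited unit-variance noise carrier, one or more columns
bandlimited_noise <- function(n, n_col, fs_hz, band) {
  x <- matrix(stats::rnorm(n * n_col), n, n_col)
  nyq <- fs_hz / 2
  ord <- fir_order(fs_hz, max(0.5, band[1] / 2), n)
  b <- fir_design(ord, pmin(band, nyq * 0.99) / nyq, "pass")
  y <- apply_fir_zerophase(x, b)
  sweep(y, 2, apply(y, 2, stats::sd), "/")
}

# spatially correlated sensor noise: white noise mixed through a smooth
# exponential-decay spatial covariance (half white, half structured)
spatial_noise <- function(n, montage, decay = 0.6, white_frac = 0.5) {
  D <- montage_distances(montage)
  Sigma <- white_frac * diag(nrow(D)) + (1 - white_frac) * exp(-D / decay)
  L <- chol(Sigma)
  matrix(stats::rnorm(n * nrow(D)), n, nrow(D)) %*% L
}

#' Synthesize a recording from prototypes and a label sequence
#'
#' `signal(t) = prototype[label(t)] * carrier(t)`, where the carrier is
#' band-limited unit-variance noise in `params$carrier_band_hz`, plus
#' spatially correlated sensor noise scaled to the requested SNR
#' (mean signal power / mean noise power over channels).
#'
#' @param prototypes channel x class matrix of zero-mean unit-norm maps.
#' @param labels integer per-sample class labels indexing the columns.
#' @param params a [microstate_gen_params()] object (`snr`, carrier band,
#'   seed).
#' @param montage the montage matching `nrow(prototypes)`.
#' @param fs_hz sampling rate in Hz.
#' @param amplitude_uV carrier amplitude scale in microvolts.
#' @return An [eeg_recording()].
#' @export
synthesize_recording <- function(prototypes, labels, params, montage,
                                 fs_hz = 250, amplitude_uV = 15) {
  stopifnot(inherits(params, "microstate_gen_params"))
  prototypes <- as.matrix(prototypes)
  if (max(labels) > ncol(prototypes) || min(labels) < 1)
    stop("labels must index prototype columns")
  if (nrow(prototypes) != length(montage$names))
    stop("prototypes do not match montage")
  n <- length(labels)
  set.seed(params$seed + 1L)
  carrier <- bandlimited_noise(n, 1, fs_hz, params$carrier_band_hz)[, 1]
  sig <- (amplitude_uV * carrier) * t(prototypes)[labels, , drop = FALSE]
  if (is.finite(params$snr)) {
    noise <- spatial_noise(n, montage)
    p_sig <- mean(sig^2)
    p_noise <- mean(noise^2)
    # zero prototype amplitude degenerates to the bare noise process
    scale <- if (p_sig > 0) sqrt(p_sig / (params$snr * p_noise)) else 1
    sig <- sig + noise * scale
  }
  eeg_recording(sig, fs_hz, montage)
}

#' Generator parameters for spatial synchronization
#'
#' @param n_channels number of output channels.
#' @param n_modes number of independent band-limited source modes
#'   (`1 <= n_modes <= n_channels`).
#' @param mode_weights nonnegative weights summing to 1 giving each mode's
#'   share of total variance; defaults to equal weights.
#' @param band_hz two-element frequency band of the sources.
#' @param duration_s,fs_hz length and sampling rate of the recording.
#' @param noise_sd standard deviation of optional white sensor noise.
#' @param seed integer seed.
#' @return A validated list of class `sync_gen_params`.
#' @export
sync_gen_params <- function(n_channels, n_modes,
                            mode_weights = rep(1 / n_modes, n_modes),
                            band_hz = c(8, 12), duration_s = 60,
                            fs_hz = 250, noise_sd = 0, seed = 1L) {
  if (n_modes < 1) stop("n_modes must be at least 1")
  if (n_modes > n_channels) stop("n_modes cannot exceed n_channels")
  if (length(mode_weights) != n_modes || any(mode_weights < 0) ||
      abs(sum(mode_weights) - 1) > 1e-9)
    stop("mode_weights must be nonnegative and sum to 1")
  if (duration_s <= 0 || fs_hz <= 0) stop("duration and fs must be positive")
  structure(list(n_channels = as.integer(n_channels),
                 n_modes = as.integer(n_modes),
                 mode_weights = mode_weights, band_hz = band_hz,
                 duration_s = duration_s, fs_hz = fs_hz,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sync_gen_params")
}

#' Geometric mode-weight profile from a synchronization level
#'
#' `sync = 0` gives equal weights over the modes (maximal spatial
#' complexity for that mode count); as `sync` approaches 1 the first mode
#' dominates and omega complexity approaches 1.
#'
#' @param n_modes number of modes.
#' @param sync synchronization level in `[0, 1)`.
#' @return Normalised weight vector.
#' @export
geometric_mode_weights <- function(n_modes, sync) {
  if (sync < 0 || sync >= 1) stop("sync must be in [0, 1)")
  w <- (1 - sync)^(seq_len(n_modes) - 1)
  w / sum(w)
}

# generic circular montage for synthesized mixtures without scalp geometry
generic_montage <- function(n_channels) {
  th <- 2 * pi * (seq_len(n_channels) - 1) / n_channels
  channel_montage(paste0("ch", seq_len(n_channels)), cbind(cos(th), sin(th)))
}

#' Synthesize a multichannel recording with a known number of spatial modes
#'
#' Each channel is a weighted mixture (orthonormal mixing) of
#' `n_modes` independent band-limited unit-variance sources, plus optional
#' white sensor noise. The population band cross-spectrum then has
#' eigenvalue shares equal to `mode_weights`, so the expected omega
#' complexity in the band is `exp(H(mode_weights))` — increasing with the
#' number of (equally weighted) modes.
#'
#' @param params a [sync_gen_params()] object.
#' @param montage optional montage (defaults to a generic circular layout
#'   of `n_channels`).
#' @return An [eeg_recording()].
#' @export
synthesize_synchronized <- function(params, montage = NULL) {
  stopifnot(inherits(params, "sync_gen_params"))
  if (is.null(montage)) montage <- generic_montage(params$n_channels)
  if (length(montage$names) != params$n_channels)
    stop("montage size does not match n_channels")
  n <- round(params$duration_s * params$fs_hz)
  set.seed(params$seed)
  S <- bandlimited_noise(n, params$n_modes, params$fs_hz, params$band_hz)
  Q <- qr.Q(qr(matrix(stats::rnorm(params$n_channels * params$n_modes),
                      params$n_channels, params$n_modes)))
  X <- S %*% (sqrt(params$mode_weights) * t(Q))
  if (params$noise_sd > 0)
    X <- X + matrix(stats::rnorm(n * params$n_channels, sd = params$noise_sd),
                    n, params$n_channels)
  eeg_recording(X, params$fs_hz, montage)
}

#' Specification of a two-group synthetic cohort
#'
#' Group 1 plays the healthy-control role, group 2 the subclinical-
#' depression role. `effect_map` entries modify group-2 generator
#' parameters: `occurrence_B` multiplies the class-B occurrence rate,
#' `duration_C` multiplies the class-C mean lifetime (contribution follows),
#' and `sync_beta2` / `sync_gamma` are added to the beta-2 / gamma band
#' synchronization levels (raising synchronization lowers omega
#' complexity). An empty `effect_map` yields exchangeable groups.
#'
#' @param n_per_group two group sizes, each at least 2.
#' @param effect_map named list of group-2 offsets (see Details).
#' @param symptom_score_model list with `coefs` (length 4: weights on the
#'   planted class-B occurrence, class-C duration, beta-2 and gamma
#'   synchronization deviations) and `noise_sd`; scores are mapped into
#'   BDI-II-like windows (group 1: 1-13, group 2: 14-27).
#' @param duration_s,fs_hz per-subject recording length and sampling rate.
#' @param snr prototype signal / sensor-noise power ratio.
#' @param background_rel total band-background power relative to signal.
#' @param base_sync baseline per-band synchronization level.
#' @param subject_sd log-scale between-subject jitter SD on rates and
#'   durations.
#' @param seed integer seed.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(20, 20),
                        effect_map = list(occurrence_B = 1.3,
                                          duration_C = 0.75,
                                          sync_beta2 = 0.25,
                                          sync_gamma = 0.25),
                        symptom_score_model = list(coefs = c(4, 4, 6, 6),
                                                   noise_sd = 1.5),
                        duration_s = 40, fs_hz = 250, snr = 10,
                        background_rel = 0.4, base_sync = 0.45,
                        subject_sd = 0.08, seed = 1L) {
  if (length(n_per_group) != 2 || any(n_per_group < 2))
    stop("two group sizes of at least 2 are required")
  if (symptom_score_model$noise_sd < 0) stop("score noise SD must be >= 0")
  known <- c("occurrence_B", "duration_C", "sync_beta2", "sync_gamma")
  if (length(effect_map) && !all(names(effect_map) %in% known))
    stop("unknown effect_map entries: ",
         paste(setdiff(names(effect_map), known), collapse = ", "))
  structure(list(n_per_group = as.integer(n_per_group),
                 effect_map = effect_map,
                 symptom_score_model = symptom_score_model,
                 duration_s = duration_s, fs_hz = fs_hz, snr = snr,
                 background_rel = background_rel, base_sync = base_sync,
                 subject_sd = subject_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

# relative power of per-band background processes (alpha kept low because
# the microstate carrier already occupies 8-12 Hz)
.background_band_power <- c(delta = 0.22, theta = 0.18, `alpha-1` = 0.08,
                            `alpha-2` = 0.08, `beta-1` = 0.16,
                            `beta-2` = 0.16, gamma = 0.12)

#' Generate a two-group cohort with planted effects
#'
#' Every subject gets a semi-Markov microstate signal built on one shared
#' prototype set, per-band multi-mode background processes with
#' subject-specific synchronization levels, spatially correlated sensor
#' noise, and a symptom score linear in the planted per-subject effects.
#' Group-2 subjects get the `effect_map` offsets. Full parameter ground
#' truth is stored with each subject.
#'
#' @param spec a [cohort_spec()].
#' @param montage analysis montage (default [default_montage()]).
#' @return An object of class `eeg_cohort`: list with `subjects` (each a
#'   list of `recording`, `group`, `score`, `subject_id`, `truth`),
#'   `prototypes`, `montage`, and the `spec`.
#' @export
make_cohort <- function(spec, montage = default_montage()) {
  stopifnot(inherits(spec, "cohort_spec"))
  prototypes <- make_prototype_maps(montage, seed = spec$seed)
  bands <- default_bands()
  n_total <- sum(spec$n_per_group)
  groups <- rep(1:2, spec$n_per_group)
  subjects <- vector("list", n_total)
  raw_scores <- numeric(n_total)
  truths <- vector("list", n_total)
  em <- spec$effect_map

  for (i in seq_len(n_total)) {
    sseed <- spec$seed + 7919L * i
    set.seed(sseed)
    rates <- rep(1, 4) * exp(stats::rnorm(4, 0, spec$subject_sd))
    durs <- c(70, 85, 100, 115) * exp(stats::rnorm(4, 0, spec$subject_sd))
    sync <- pmin(0.95, pmax(0, spec$base_sync +
                              stats::rnorm(nrow(bands), 0, 0.03)))
    names(sync) <- bands$name
    if (groups[i] == 2) {
      if (!is.null(em$occurrence_B)) rates[2] <- rates[2] * em$occurrence_B
      if (!is.null(em$duration_C)) durs[3] <- durs[3] * em$duration_C
      if (!is.null(em$sync_beta2))
        sync["beta-2"] <- min(0.95, sync["beta-2"] + em$sync_beta2)
      if (!is.null(em$sync_gamma))
        sync["gamma"] <- min(0.95, sync["gamma"] + em$sync_gamma)
    }
    params <- microstate_gen_params(mean_duration_ms = durs,
                                    occurrence_rate_hz = rates,
                                    snr = Inf, seed = sseed + 1L)
    labels <- sample_state_sequence(params, spec$duration_s, spec$fs_hz)
    rec <- synthesize_recording(prototypes, labels, params, montage,
                                fs_hz = spec$fs_hz)
    sig <- rec$data
    p_sig <- mean(sig^2)
    n <- nrow(sig)

    # band-limited multi-mode backgrounds with planted synchronization
    set.seed(sseed + 2L)
    for (b in seq_len(nrow(bands))) {
      hi <- min(bands$high_hz[b], spec$fs_hz / 2 * 0.95)
      sp <- sync_gen_params(n_channels = length(montage$names), n_modes = 8,
                            mode_weights = geometric_mode_weights(8, sync[b]),
                            band_hz = c(bands$low_hz[b], hi),
                            duration_s = spec$duration_s, fs_hz = spec$fs_hz,
                            seed = sseed + 2L + b)
      bg <- synthesize_synchronized(sp, montage)$data
      target <- p_sig * spec$background_rel * .background_band_power[b]
      sig <- sig + bg * sqrt(target / mean(bg^2))
    }
    set.seed(sseed + 97L)
    noise <- spatial_noise(n, montage)
    sig <- sig + noise * sqrt(p_sig / (spec$snr * mean(noise^2)))

    truths[[i]] <- list(rates = rates, durations_ms = durs, sync = sync,
                        seed = sseed)
    cf <- spec$symptom_score_model$coefs
    raw_scores[i] <- cf[1] * log(rates[2]) - cf[2] * log(durs[3] / 100) +
      cf[3] * sync["beta-2"] + cf[4] * sync["gamma"] +
      stats::rnorm(1, 0, spec$symptom_score_model$noise_sd)
    subjects[[i]] <- list(recording = eeg_recording(sig, spec$fs_hz, montage),
                          group = groups[i], subject_id = sprintf("S%03d", i))
  }

  # map raw scores into BDI-II-like inclusion windows per group
  windows <- list(c(1, 13), c(14, 27))
  for (g in 1:2) {
    idx <- which(groups == g)
    r <- raw_scores[idx]
    if (diff(range(r)) < 1e-12) {
      sc <- rep(mean(windows[[g]]), length(r))
    } else {
      sc <- windows[[g]][1] +
        (r - min(r)) / (max(r) - min(r)) * diff(windows[[g]])
    }
    for (k in seq_along(idx)) {
      subjects[[idx[k]]]$score <- round(sc[k])
      subjects[[idx[k]]]$truth <- truths[[idx[k]]]
    }
  }

  structure(list(subjects = subjects, prototypes = prototypes,
                 montage = montage, spec = spec),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  g <- vapply(x$subjects, `[[`, 0, "group")
  cat("<eeg_cohort> ", sum(g == 1), " + ", sum(g == 2), " subjects, ",
      x$spec$duration_s, " s @ ", x$spec$fs_hz, " Hz\n", sep = "")
  invisible(x)
}

#' Write a cohort to disk
#'
#' Recordings go out via [write_recording()] (flat matrix + JSON sidecar);
#' a `manifest.csv` records subject id, group, symptom score and seed.
#'
#' @param cohort an `eeg_cohort`.
#' @param dir output directory (created if needed).
#' @return The manifest as a data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort$subjects, function(s) {
    write_recording(s$recording, file.path(dir, paste0(s$subject_id, ".txt")))
    data.frame(subject = s$subject_id, group = s$group, score = s$score,
               seed = s$truth$seed)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
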