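# Subject x feature tables: two-stage group-level microstate segmentation
# (subject prototypes -> pooled group prototypes -> shared backfit) plus
# per-subject omega complexity, assembled into one tidy table consumed by
# the statistics battery and the classifier.

band_key <- function(name) gsub("-", "", name)

#' Extract the full feature table from a cohort
#'
#' Each subject's recording is preprocessed (bandpass, notch, 2-s epochs,
#' average reference, artifact rejection), microstate-segmented and
#' omega-analysed. Microstate prototypes are fitted in two stages: TAAHC
#' on each subject's GFP-peak maps gives four subject prototypes, TAAHC on
#' the pooled subject prototypes gives the four group prototypes (A-D via
#' canonical templates), which are then backfitted to every subject so all
#' subjects share one prototype set.
#'
#' @param cohort an `eeg_cohort` from [make_cohort()], or a list of
#'   subject lists with elements `recording`, `group`, and optionally
#'   `score`, `subject_id`.
#' @param low_hz,high_hz,notch_hz,epoch_s,reject_uV preprocessing
#'   parameters (see [preprocess()]).
#' @param max_maps GFP-peak subsampling cap per subject.
#' @param seed seed for peak subsampling.
#' @return A tibble with one row per subject: `subject`, `group` (factor
#'   `HC`/`ScD`), `score`, `gev`, per-class `duration_*`, `occurrence_*`,
#'   `contribution_*`, the 12 transition probabilities `t_X_Y`, and 21
#'   omega columns `omega_<scope>_<band>`. Group prototypes are attached
#'   as the `prototypes` attribute.
#' @export
extract_features <- function(cohort, low_hz = 0.5, high_hz = 45,
                             notch_hz = 50, epoch_s = 2, reject_uV = 100,
                             max_maps = 1000, seed = 1L) {
  subjects <- if (inherits(cohort, "eeg_cohort")) cohort$subjects else cohort
  n <- length(subjects)
  montage <- subjects[[1]]$recording$montage
  bands <- default_bands()

  eps <- vector("list", n)      # preprocessed epochs
  epf <- vector("list", n)      # 2-20 Hz filtered epochs
  sub_protos <- vector("list", n)
  for (i in seq_len(n)) {
    fl <- filter_broadband_and_msband(subjects[[i]]$recording, low_hz,
                                      high_hz, notch_hz)
    ep <- rereference_average(epoch_recording(fl$broadband, epoch_s))
    keep <- seq_len(n_epochs(ep))
    if (!is.null(reject_uV)) {
      keep <- which(apply(abs(ep$epochs), 1, max) <= reject_uV)
      if (length(keep) == 0) stop("artifact rejection removed every epoch")
    }
    # microstate band applied to the continuous signal, then epoched with
    # the same rejection mask (cheaper than per-epoch filtering)
    epm <- rereference_average(epoch_recording(fl$msband, epoch_s))
    rej <- n_epochs(ep) - length(keep)
    ep$epochs <- ep$epochs[keep, , , drop = FALSE]
    ep$rejected_count <- rej
    epm$epochs <- epm$epochs[keep, , , drop = FALSE]
    epm$rejected_count <- rej
    eps[[i]] <- ep
    epf[[i]] <- epm
    pk <- gfp_peak_maps(epf[[i]], max_maps = max_maps, seed = seed + i)
    sub_protos[[i]] <- taahc_cluster(pk$maps, n_clusters = 4,
                                     weights = pk$gfp)$prototypes
  }
  pooled <- t(do.call(cbind, sub_protos))
  fit <- taahc_cluster(pooled, n_clusters = 4)
  prototypes <- order_classes(fit$prototypes, canonical_templates(montage))
  rownames(prototypes) <- montage$names

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    labels <- backfit(epf[[i]], prototypes)
    gev <- compute_gev(epf[[i]], labels, prototypes)
    ms <- segment_stats(labels, eps[[i]]$fs_hz)
    om <- omega_pipeline(eps[[i]], bands)
    row <- list(
      subject = subjects[[i]]$subject_id %||% sprintf("S%03d", i),
      group = factor(ifelse(subjects[[i]]$group == 1, "HC", "ScD"),
                     levels = c("HC", "ScD")),
      score = subjects[[i]]$score %||% NA_real_,
      gev = gev)
    dur <- ms$duration_ms
    dur[is.na(dur)] <- 0    # class never seen as a complete segment
    for (cl in c("A", "B", "C", "D")) {
      row[[paste0("duration_", cl)]] <- dur[[cl]]
      row[[paste0("occurrence_", cl)]] <- ms$occurrence_per_s[[cl]]
      row[[paste0("contribution_", cl)]] <- ms$contribution_pct[[cl]]
    }
    for (a in c("A", "B", "C", "D")) for (b in c("A", "B", "C", "D"))
      if (a != b) row[[paste0("t_", a, "_", b)]] <- ms$transitions[a, b]
    for (j in seq_len(nrow(om)))
      row[[paste0("omega_", om$scope[j], "_", band_key(om$band[j]))]] <-
        om$omega[j]
    rows[[i]] <- tibble::as_tibble(row)
  }
  out <- do.call(rbind, rows)
  attr(out, "prototypes") <- prototypes
  out
}

# long format for one microstate measure ("duration", "occurrence",
# "contribution") or the transition probabilities
measure_long <- function(features, measure) {
  cols <- if (measure == "transition") {
    grep("^t_[A-D]_[A-D]$", names(features), value = TRUE)
  } else {
    paste0(measure, "_", c("A", "B", "C", "D"))
  }
  do.call(rbind, lapply(cols, function(cn) {
    tibble::tibble(subject = features$subject, group = features$group,
                   level = sub(paste0("^", measure, "_|^t_"), "", cn),
                   value = features[[cn]])
  }))
}

#' Full statistical battery on a feature table
#'
#' Mirrors the standard resting-EEG group analysis: mixed
#' repeated-measures ANOVA (group x class) for microstate duration,
#' occurrence, and contribution; group x transition-pair ANOVA for the 12
#' transition probabilities; group x scalp-region ANOVA per band for
#' regional omega; independent t-tests (Cohen's d, Wilcoxon fallback when
#' a Shapiro test rejects normality) per band for global omega; and
#' Spearman correlations between the symptom score and each feature.
#'
#' @param features tibble from [extract_features()].
#' @return List of tibbles: `anova` (all mixed ANOVAs, tagged by measure),
#'   `global_omega` (per-band group comparisons), `correlations`.
#' @export
stats_battery <- function(features) {
  an <- list()
  for (measure in c("duration", "occurrence", "contribution", "transition")) {
    long <- measure_long(features, measure)
    a <- mixed_anova(long, dv = "value", subject = "subject",
                     within = "level", between = "group")
    a$measure <- measure
    an[[measure]] <- a
  }
  bands <- band_key(default_bands()$name)
  for (b in bands) {
    long <- do.call(rbind, lapply(c("anterior", "posterior"), function(sc)
      tibble::tibble(subject = features$subject, group = features$group,
                     level = sc,
                     value = features[[paste0("omega_", sc, "_", b)]])))
    a <- mixed_anova(long, dv = "value", subject = "subject",
                     within = "level", between = "group")
    a$measure <- paste0("regional_omega_", b)
    an[[paste0("omega_", b)]] <- a
  }
  anova_tab <- do.call(rbind, an)

  glob <- do.call(rbind, lapply(bands, function(b) {
    x <- features[[paste0("omega_global_", b)]]
    hc <- x[features$group == "HC"]; scd <- x[features$group == "ScD"]
    normal <- tryCatch(
      stats::shapiro.test(hc)$p.value >= 0.05 &&
        stats::shapiro.test(scd)$p.value >= 0.05,
      error = function(e) TRUE)
    if (normal) {
      tt <- stats::t.test(scd, hc, var.equal = TRUE)
      tibble::tibble(band = b, test = "t",
                     statistic = unname(tt$statistic),
                     df = unname(tt$parameter), p = tt$p.value,
                     cohens_d = cohens_d(scd, hc),
                     mean_HC = mean(hc), mean_ScD = mean(scd))
    } else {
      wt <- wilcoxon_fallback(scd, hc)
      tibble::tibble(band = b, test = "wilcoxon",
                     statistic = wt$statistic, df = NA_real_, p = wt$p,
                     cohens_d = cohens_d(scd, hc),
                     mean_HC = mean(hc), mean_ScD = mean(scd))
    }
  }))

  corr <- NULL
  if (!all(is.na(features$score))) {
    fcols <- setdiff(names(features), c("subject", "group", "score"))
    corr <- do.call(rbind, lapply(fcols, function(cn) {
      sc <- spearman_corr(features[[cn]], features$score)
      tibble::tibble(feature = cn, rho = sc$rho, p = sc$p)
    }))
  }
  list(anova = anova_tab, global_omega = glob, correlations = corr)
}
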