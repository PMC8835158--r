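# Temporal-dynamics stage: global field power, GFP-peak topographies,
# polarity-invariant TAAHC clustering into four classes, backfitting,
# global explained variance, and the microstate parameters.

#' Global field power of an epoch set
#'
#' `GFP(t) = sqrt( sum_i (v_i(t) - vbar(t))^2 / n )` — the spatial standard
#' deviation (population form) of the scalp potential at each sample,
#' equivalently the root mean square over electrodes of the
#' average-referenced potential.
#'
#' @param ep an [eeg_epochs()] object (average-referenced).
#' @return Object of class `gfp_series`: list with `values` (epoch x
#'   sample matrix, microvolts) and `fs_hz`.
#' @export
compute_gfp <- function(ep) {
  stopifnot(inherits(ep, "eeg_epochs"))
  d <- dim(ep$epochs)
  flat <- matrix(ep$epochs, d[1] * d[2], d[3])
  centred <- flat - rowMeans(flat)
  values <- sqrt(rowMeans(centred^2))
  structure(list(values = matrix(values, d[1], d[2]), fs_hz = ep$fs_hz),
            class = "gfp_series")
}

#' Strict local maxima of a GFP series
#'
#' A peak is a sample strictly greater than both neighbours; epoch
#' boundary samples are never peaks.
#'
#' @param g a `gfp_series` (or a numeric vector for a single epoch).
#' @return A list (one element per epoch) of integer peak indices.
#' @export
find_gfp_peaks <- function(g) {
  vals <- if (inherits(g, "gfp_series")) g$values else matrix(g, nrow = 1)
  if (ncol(vals) < 3) stop("need at least 3 samples per epoch")
  lapply(seq_len(nrow(vals)), function(e) {
    v <- vals[e, ]
    n <- length(v)
    which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
  })
}

#' Microstate analysis band filter (2-20 Hz)
#'
#' Zero-phase FIR bandpass at the fixed 2-20 Hz microstate analysis band,
#' applied epoch-wise with reflection padding.
#'
#' @param ep an [eeg_epochs()] object.
#' @return The filtered `eeg_epochs`.
#' @export
microstate_bandpass <- function(ep) {
  stopifnot(inherits(ep, "eeg_epochs"))
  d <- dim(ep$epochs)
  nyq <- ep$fs_hz / 2
  ord <- fir_order(ep$fs_hz, 1, d[2])
  b <- fir_design(ord, c(2, 20) / nyq, "pass")
  for (e in seq_len(d[1]))
    ep$epochs[e, , ] <- apply_fir_zerophase(matrix(ep$epochs[e, , ], d[2], d[3]), b)
  ep
}

# absolute (or signed) spatial correlation between rows of maps (n x C,
# zero-mean rows) and prototype columns (C x k, zero-mean unit-norm)
spatial_corr <- function(maps, prototypes, absolute = TRUE) {
  maps <- maps - rowMeans(maps)
  norms <- sqrt(rowSums(maps^2))
  norms[norms == 0] <- Inf
  r <- (maps %*% prototypes) / norms
  if (absolute) abs(r) else r
}

# sign-invariant first principal direction of member maps, gfp-weighted
principal_map <- function(maps, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(maps))
  m <- maps - rowMeans(maps)
  nm <- sqrt(rowSums(m^2))
  ok <- nm > 0
  m <- m[ok, , drop = FALSE] / nm[ok]
  w <- weights[ok]
  if (nrow(m) == 0) return(NULL)
  if (nrow(m) == 1) {
    v <- m[1, ]
  } else {
    v <- eigen(crossprod(m * w), symmetric = TRUE)$vectors[, 1]
  }
  v <- v - mean(v)
  v / sqrt(sum(v^2))
}

#' Topographic atomize-and-agglomerate hierarchical clustering (TAAHC)
#'
#' Agglomerative clustering of scalp topographies. Every map starts as a
#' singleton cluster; at each step the cluster contributing least global
#' explained variance is atomized and each of its members reassigned to
#' the cluster whose prototype it matches best by absolute spatial
#' correlation. Cluster prototypes are the sign-invariant first principal
#' direction of the member maps, so map polarity is ignored throughout.
#'
#' @param maps n x channel matrix of topographies (rows).
#' @param n_clusters number of clusters to keep (default 4).
#' @param ignore_polarity if `FALSE`, signed correlation and mean-map
#'   prototypes are used instead.
#' @param weights optional per-map weights (typically GFP values) entering
#'   the explained-variance criterion and prototype extraction.
#' @param polish number of final full-reassignment refinement iterations
#'   (sign-invariant k-means steps; empty clusters are reseeded with the
#'   worst-fitting map). Agglomeration can merge but never split, so a few
#'   polish steps repair occasional early merges of correlated classes;
#'   set to 0 for the bare agglomerative result.
#' @return List with `prototypes` (channel x `n_clusters`, zero-mean
#'   unit-norm columns) and `assignment` (cluster index per map).
#' @export
taahc_cluster <- function(maps, n_clusters = 4, ignore_polarity = TRUE,
                          weights = NULL, polish = 20) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  nc <- ncol(maps)
  if (n < n_clusters) stop("fewer maps (", n, ") than clusters")
  if (is.null(weights)) weights <- rep(1, n)
  cmaps <- maps - rowMeans(maps)
  norms <- sqrt(rowSums(cmaps^2))
  norms[norms == 0] <- 1
  nmaps <- cmaps / norms
  w2 <- weights^2
  tot_w2 <- sum(w2)

  # prototype of a member set, warm-started at the previous prototype:
  # sign-invariant first principal direction via power iteration on the
  # weighted scatter (exact for the polarity-sensitive mean-map variant)
  proto_of <- function(members, v0 = NULL) {
    mk <- nmaps[members, , drop = FALSE] * weights[members]
    if (!ignore_polarity) {
      v <- colSums(mk)
    } else if (length(members) == 1) {
      v <- nmaps[members, ]
    } else {
      S <- crossprod(mk)
      v <- if (is.null(v0)) eigen(S, symmetric = TRUE)$vectors[, 1] else {
        for (i in 1:6) {
          v0 <- S %*% v0
          v0 <- v0 / sqrt(sum(v0^2))
        }
        v0[, 1]
      }
    }
    v <- v - mean(v)
    v / sqrt(sum(v^2))
  }

  members <- as.list(seq_len(n))
  P <- t(nmaps)                       # prototype per (singleton) cluster
  active <- rep(TRUE, n)
  contribs <- w2 / tot_w2             # singleton: |r| = 1 with itself

  while (sum(active) > n_clusters) {
    act <- which(active)
    worst <- act[which.min(contribs[act])]
    orphans <- members[[worst]]
    active[worst] <- FALSE
    act <- which(active)
    r <- abs(nmaps[orphans, , drop = FALSE] %*% P[, act, drop = FALSE])
    if (!ignore_polarity)
      r <- nmaps[orphans, , drop = FALSE] %*% P[, act, drop = FALSE]
    dest <- act[max.col(r, ties.method = "first")]
    for (k in unique(dest)) {
      members[[k]] <- c(members[[k]], orphans[dest == k])
      P[, k] <- proto_of(members[[k]], P[, k])
      rk <- nmaps[members[[k]], , drop = FALSE] %*% P[, k]
      contribs[k] <- sum(w2[members[[k]]] * rk^2) / tot_w2
    }
  }
  act <- which(active)
  prototypes <- P[, act, drop = FALSE]
  assignment <- integer(n)
  for (k in seq_along(act)) assignment[members[[act[k]]]] <- k
  members <- members[act]

  for (it in seq_len(polish)) {
    r <- spatial_corr(nmaps, prototypes, absolute = ignore_polarity)
    new_assign <- max.col(r, ties.method = "first")
    fit_r <- r[cbind(seq_len(n), new_assign)]
    for (k in seq_len(n_clusters)) {       # reseed empty clusters
      if (!any(new_assign == k)) {
        worst <- which.min(fit_r)
        new_assign[worst] <- k
        fit_r[worst] <- 1
      }
    }
    if (all(new_assign == assignment)) break
    assignment <- new_assign
    prototypes <- vapply(seq_len(n_clusters), function(k)
      proto_of(which(assignment == k)), numeric(ncol(nmaps)))
  }
  list(prototypes = prototypes, assignment = assignment)
}

#' Label prototypes with the canonical class identities A-D
#'
#' Finds the one-to-one assignment between prototypes and the four
#' canonical templates maximizing total absolute spatial correlation
#' (exhaustive over the 24 permutations), reorders the prototypes to
#' A, B, C, D, and orients each so its correlation with its template is
#' positive.
#'
#' @param prototypes channel x 4 matrix.
#' @param templates channel x 4 matrix of canonical maps (defaults to the
#'   analytic templates of the default montage geometry).
#' @return The relabelled prototype matrix with columns `A`-`D`.
#' @export
order_classes <- function(prototypes,
                          templates = canonical_templates(default_montage())) {
  prototypes <- as.matrix(prototypes)
  templates <- as.matrix(templates)
  if (ncol(prototypes) != 4 || ncol(templates) != 4)
    stop("order_classes expects 4 prototypes and 4 templates")
  r <- abs(stats::cor(prototypes, templates))
  perms <- permutations4()
  scores <- apply(perms, 1, function(p) sum(r[cbind(p, 1:4)]))
  best <- perms[which.max(scores), ]
  out <- prototypes[, best, drop = FALSE]
  for (j in 1:4) {
    if (stats::cor(out[, j], templates[, j]) < 0) out[, j] <- -out[, j]
  }
  colnames(out) <- c("A", "B", "C", "D")
  out
}

permutations4 <- function() {
  p <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  p <- as.matrix(p[apply(p, 1, function(r) length(unique(r)) == 4), ])
  dimnames(p) <- NULL
  p
}

#' Backfit prototypes onto epochs
#'
#' Each GFP peak is labelled by the prototype of highest absolute spatial
#' correlation; every other sample inherits the label of the nearest peak
#' within its epoch (ties to the earlier peak). Epochs without any GFP
#' peak fall back to per-sample labelling.
#'
#' @param ep an [eeg_epochs()] object (2-20 Hz filtered, average-referenced).
#' @param prototypes channel x class matrix of zero-mean unit-norm maps.
#' @param interpolate if `FALSE`, every sample is labelled by its own
#'   best-matching prototype instead of inheriting from the nearest GFP
#'   peak (this is the labelling that maximises GEV).
#' @return Integer matrix of labels, epoch x sample.
#' @export
backfit <- function(ep, prototypes, interpolate = TRUE) {
  stopifnot(inherits(ep, "eeg_epochs"))
  prototypes <- as.matrix(prototypes)
  d <- dim(ep$epochs)
  g <- compute_gfp(ep)
  peaks <- find_gfp_peaks(g)
  labels <- matrix(0L, d[1], d[2])
  for (e in seq_len(d[1])) {
    M <- matrix(ep$epochs[e, , ], d[2], d[3])
    pk <- peaks[[e]]
    if (!interpolate || length(pk) == 0) {
      r <- spatial_corr(M, prototypes)
      labels[e, ] <- max.col(r, ties.method = "first")
      next
    }
    r <- spatial_corr(M[pk, , drop = FALSE], prototypes)
    pk_lab <- max.col(r, ties.method = "first")
    # nearest peak per sample; exact midpoints resolve to the earlier peak
    idx <- findInterval(seq_len(d[2]), pk)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(pk))
    d_lo <- abs(seq_len(d[2]) - pk[lo])
    d_hi <- abs(pk[hi] - seq_len(d[2]))
    use_lo <- idx >= 1L & (idx >= length(pk) | d_lo <= d_hi)
    labels[e, ] <- pk_lab[ifelse(use_lo, lo, hi)]
  }
  labels
}

#' Global explained variance of a microstate segmentation
#'
#' `GEV = sum_t (GFP(t) * corr(v(t), p_label(t)))^2 / sum_t GFP(t)^2`,
#' summing over all samples of all epochs.
#'
#' @param ep an [eeg_epochs()] object.
#' @param labels integer epoch x sample label matrix (as from [backfit()]).
#' @param prototypes channel x class matrix.
#' @return GEV fraction in `[0, 1]`.
#' @export
compute_gev <- function(ep, labels, prototypes) {
  stopifnot(inherits(ep, "eeg_epochs"))
  prototypes <- as.matrix(prototypes)
  d <- dim(ep$epochs)
  g <- compute_gfp(ep)$values
  num <- 0
  for (e in seq_len(d[1])) {
    M <- matrix(ep$epochs[e, , ], d[2], d[3])
    r <- spatial_corr(M, prototypes, absolute = FALSE)
    rl <- r[cbind(seq_len(d[2]), labels[e, ])]
    num <- num + sum((g[e, ] * rl)^2)
  }
  num / sum(g^2)
}

#' Microstate parameters from a label sequence
#'
#' Per class: mean segment duration (ms, epoch-boundary-truncated segments
#' excluded), occurrence (complete segments per second of labelled data),
#' and contribution (percent of samples, truncated segments included).
#' Classes never observed as complete interior segments get `NA` duration
#' and occurrence 0.
#'
#' @param labels integer epoch x sample matrix (or vector for one epoch).
#' @param fs_hz sampling rate in Hz.
#' @param n_classes number of classes (default 4).
#' @return List of class `microstate_params`: `duration_ms`,
#'   `occurrence_per_s`, `contribution_pct` (each length `n_classes`) and
#'   `transitions` (from [transition_matrix()]).
#' @export
segment_stats <- function(labels, fs_hz, n_classes = 4) {
  labels <- if (is.matrix(labels)) labels else matrix(labels, nrow = 1)
  total_s <- length(labels) / fs_hz
  dur_sum <- numeric(n_classes)
  dur_n <- integer(n_classes)
  occ_n <- integer(n_classes)
  contrib <- numeric(n_classes)
  for (e in seq_len(nrow(labels))) {
    r <- rle(labels[e, ])
    k <- length(r$lengths)
    for (s in seq_len(k)) {
      cl <- r$values[s]
      contrib[cl] <- contrib[cl] + r$lengths[s]
      if (s > 1 && s < k) {          # complete interior segment
        dur_sum[cl] <- dur_sum[cl] + r$lengths[s]
        dur_n[cl] <- dur_n[cl] + 1L
        occ_n[cl] <- occ_n[cl] + 1L
      }
    }
  }
  duration_ms <- ifelse(dur_n > 0, dur_sum / dur_n / fs_hz * 1000, NA_real_)
  cls <- c("A", "B", "C", "D", LETTERS[5:26])[seq_len(n_classes)]
  structure(list(
    duration_ms = stats::setNames(duration_ms, cls),
    occurrence_per_s = stats::setNames(occ_n / total_s, cls),
    contribution_pct = stats::setNames(contrib / length(labels) * 100, cls),
    transitions = transition_matrix(labels, n_classes)),
    class = "microstate_params")
}

#' Empirical microstate transition-probability matrix
#'
#' Counts consecutive distinct-class segment pairs within epochs (never
#' across epoch boundaries) and row-normalises. The diagonal is zero by
#' construction; a class with no outgoing transitions keeps an all-zero
#' row.
#'
#' @param labels integer epoch x sample matrix (or vector).
#' @param n_classes number of classes (default 4).
#' @return `n_classes` x `n_classes` matrix with rows summing to 1 (or 0).
#' @export
transition_matrix <- function(labels, n_classes = 4) {
  labels <- if (is.matrix(labels)) labels else matrix(labels, nrow = 1)
  counts <- matrix(0, n_classes, n_classes)
  for (e in seq_len(nrow(labels))) {
    seg <- rle(labels[e, ])$values
    if (length(seg) > 1) {
      from <- seg[-length(seg)]
      to <- seg[-1]
      for (i in seq_along(from))
        counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
    }
  }
  rs <- rowSums(counts)
  out <- counts / ifelse(rs > 0, rs, 1)
  cls <- c("A", "B", "C", "D", LETTERS[5:26])[seq_len(n_classes)]
  dimnames(out) <- list(from = cls, to = cls)
  out
}

#' Extract GFP-peak topographies for clustering
#'
#' Collects the maps at GFP peaks across all epochs, with their GFP values
#' as weights, optionally subsampling uniformly (seeded) to at most
#' `max_maps` maps for tractability of the agglomerative start.
#'
#' @param ep an [eeg_epochs()] object.
#' @param max_maps subsampling cap (default 1000).
#' @param seed seed for the uniform subsample.
#' @return List with `maps` (n x channel) and `gfp` (weights).
#' @export
gfp_peak_maps <- function(ep, max_maps = 1000, seed = 1L) {
  stopifnot(inherits(ep, "eeg_epochs"))
  g <- compute_gfp(ep)
  peaks <- find_gfp_peaks(g)
  d <- dim(ep$epochs)
  maps <- do.call(rbind, lapply(seq_len(d[1]), function(e)
    matrix(ep$epochs[e, , ], d[2], d[3])[peaks[[e]], , drop = FALSE]))
  gfp <- unlist(lapply(seq_len(d[1]), function(e) g$values[e, peaks[[e]]]))
  if (nrow(maps) > max_maps) {
    set.seed(seed)
    keep <- sort(sample.int(nrow(maps), max_maps))
    maps <- maps[keep, , drop = FALSE]
    gfp <- gfp[keep]
  }
  list(maps = maps, gfp = gfp)
}

#' Fit a four-class microstate model to one subject's epochs
#'
#' Filters to the 2-20 Hz analysis band, clusters the GFP-peak maps with
#' TAAHC, labels the prototypes A-D against the canonical templates,
#' backfits, and computes GEV and the microstate parameters.
#'
#' @param ep preprocessed (average-referenced) [eeg_epochs()].
#' @param n_clusters number of classes (default 4).
#' @param max_maps GFP-peak subsampling cap.
#' @param prototypes optional fixed prototypes (e.g. group-level maps); if
#'   supplied, clustering is skipped and the maps are only backfitted.
#' @param seed seed for peak subsampling.
#' @return Object of class `microstate_model`: `prototypes`, `labels`,
#'   `gev`, `params`.
#' @export
microstate_model <- function(ep, n_clusters = 4, max_maps = 1000,
                             prototypes = NULL, seed = 1L) {
  stopifnot(inherits(ep, "eeg_epochs"))
  epf <- microstate_bandpass(ep)
  if (is.null(prototypes)) {
    pk <- gfp_peak_maps(epf, max_maps = max_maps, seed = seed)
    fit <- taahc_cluster(pk$maps, n_clusters = n_clusters, weights = pk$gfp)
    prototypes <- if (n_clusters == 4)
      order_classes(fit$prototypes,
                    canonical_templates(ep$montage)) else fit$prototypes
  }
  labels <- backfit(epf, prototypes)
  structure(list(prototypes = prototypes, labels = labels,
                 gev = compute_gev(epf, labels, prototypes),
                 params = segment_stats(labels, ep$fs_hz,
                                        ncol(prototypes))),
            class = "microstate_model")
}

#' @export
print.microstate_model <- function(x, ...) {
  cat("<microstate_model> ", ncol(x$prototypes), " classes, GEV = ",
      round(x$gev, 3), "\n", sep = "")
  print(round(rbind(duration_ms = x$params$duration_ms,
                    occurrence_per_s = x$params$occurrence_per_s,
                    contribution_pct = x$params$contribution_pct), 2))
  invisible(x)
}
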