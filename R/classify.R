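# Two-group classification: z-scored features, linear and Gaussian-RBF
# SVM, hyperparameters by grid search inside nested cross-validation
# (leave-one-out outer loop, 5-fold inner loop), accuracy and ROC/AUC from
# pooled out-of-fold decision values.

#' Nested-CV SVM configuration
#'
#' @param kernels character subset of `c("linear", "rbf")`.
#' @param C_grid log-spaced cost grid (default `10^(-2:2)`).
#' @param gamma_grid log-spaced RBF width grid (default `10^(-3:1)`).
#' @param inner_folds number of inner CV folds (default 5).
#' @param seed integer seed controlling inner fold assignment.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(kernels = c("linear", "rbf"),
                              C_grid = 10^(-2:2),
                              gamma_grid = 10^(-3:1),
                              inner_folds = 5, seed = 1L) {
  kernels <- match.arg(kernels, c("linear", "rbf"), several.ok = TRUE)
  if (length(C_grid) == 0 || any(C_grid <= 0))
    stop("C_grid must be non-empty and positive")
  if (length(gamma_grid) == 0 || any(gamma_grid <= 0))
    stop("gamma_grid must be non-empty and positive")
  if (inner_folds < 2) stop("inner_folds must be at least 2")
  structure(list(kernels = kernels, C_grid = C_grid,
                 gamma_grid = gamma_grid,
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Standardise features on training statistics
#'
#' Column means and SDs are fitted on the training rows only and applied
#' to both sets; zero-variance training columns are dropped with a
#' warning.
#'
#' @param train_rows numeric matrix / data frame of training rows.
#' @param apply_rows rows to transform with the training statistics
#'   (default: the training rows themselves).
#' @return List with `train`, `apply`, `center`, `scale`, `dropped`.
#' @export
zscore_features <- function(train_rows, apply_rows = train_rows) {
  train_rows <- as.matrix(train_rows)
  apply_rows <- as.matrix(apply_rows)
  if (nrow(train_rows) < 2) stop("need at least 2 training rows")
  ctr <- colMeans(train_rows)
  scl <- apply(train_rows, 2, stats::sd)
  dropped <- names(which(scl == 0))
  if (length(dropped) > 0) {
    warning("dropping constant feature(s): ", paste(dropped, collapse = ", "))
    keep <- scl > 0
    train_rows <- train_rows[, keep, drop = FALSE]
    apply_rows <- apply_rows[, keep, drop = FALSE]
    ctr <- ctr[keep]; scl <- scl[keep]
  }
  list(train = sweep(sweep(train_rows, 2, ctr), 2, scl, "/"),
       apply = sweep(sweep(apply_rows, 2, ctr), 2, scl, "/"),
       center = ctr, scale = scl, dropped = dropped)
}

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney probability that a positive's score exceeds a
#' negative's, ties counted one half — identical to trapezoidal
#' integration of the ROC curve.
#'
#' @param labels two-level factor (second level = positive class) or
#'   logical vector (`TRUE` = positive).
#' @param scores numeric decision scores, higher favouring the positive
#'   class.
#' @return List with `roc` (tibble of `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  pos <- if (is.logical(labels)) labels else {
    f <- factor(labels)
    if (nlevels(f) != 2) stop("labels must have exactly two levels")
    f == levels(f)[2]
  }
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)   # average ranks handle ties as 1/2
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  keep <- c(diff(scores[ord]) != 0, TRUE)   # one point per threshold
  roc <- tibble::tibble(fpr = c(0, fp[keep] / n_neg),
                        tpr = c(0, tp[keep] / n_pos))
  list(roc = roc, auc = auc)
}

# orient e1071 decision values so that higher favours `positive`
oriented_decision <- function(pred, positive) {
  dv <- attr(pred, "decision.values")
  sides <- strsplit(colnames(dv)[1], "/")[[1]]
  if (sides[1] == positive) dv[, 1] else -dv[, 1]
}

# stratified fold assignment, deterministic given seed
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

svm_grid <- function(config) {
  rows <- list()
  for (kern in config$kernels) {
    if (kern == "linear") {
      rows[[length(rows) + 1]] <-
        data.frame(kernel = "linear", C = config$C_grid, gamma = NA_real_)
    } else {
      rows[[length(rows) + 1]] <-
        expand.grid(kernel = "rbf", C = config$C_grid,
                    gamma = config$gamma_grid,
                    stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

fit_svm <- function(x, y, kernel, C, gamma) {
  if (kernel == "linear") {
    e1071::svm(x, y, kernel = "linear", cost = C, scale = FALSE)
  } else {
    e1071::svm(x, y, kernel = "radial", cost = C, gamma = gamma,
               scale = FALSE)
  }
}

#' Nested cross-validated SVM classification
#'
#' Outer leave-one-out loop: for each held-out subject, a grid search over
#' hyperparameters is run by stratified `inner_folds`-fold CV on the
#' remaining subjects (standardisation fitted within each inner training
#' fold), the best configuration per kernel is refit on all remaining
#' subjects, and the held-out subject's prediction and decision value are
#' recorded. The held-out subject never enters standardisation or grid
#' search. Accuracy and AUC come from the pooled out-of-fold results.
#'
#' @param table feature table (tibble / data frame) with a `group` column
#'   (two levels) and the feature columns.
#' @param feature_set character vector of feature column names.
#' @param config a [classifier_config()].
#' @return Object of class `classification_report`: `summary` (tibble of
#'   kernel, accuracy, auc, n), `scores` (per-subject out-of-fold decision
#'   values), `chosen` (hyperparameters per outer fold).
#' @export
nested_cv_svm <- function(table, feature_set, config = classifier_config()) {
  table <- as.data.frame(table)
  if (!all(feature_set %in% names(table)))
    stop("missing feature columns: ",
         paste(setdiff(feature_set, names(table)), collapse = ", "))
  y <- factor(table$group)
  if (nlevels(y) != 2) stop("group must have exactly two levels")
  if (min(table(y)) < 2) stop("need at least 2 subjects per class")
  X <- as.matrix(table[, feature_set, drop = FALSE])
  if (any(!is.finite(X))) stop("features must be finite")
  n <- nrow(X)
  positive <- levels(y)[2]
  grid <- svm_grid(config)

  res <- list()
  chosen <- list()
  dec_by_kernel <- list()
  pred_by_kernel <- list()
  for (kern in unique(grid$kernel)) {
    g <- grid[grid$kernel == kern, , drop = FALSE]
    dec <- rep(NA_real_, n)
    pred <- rep(NA_character_, n)
    pars <- vector("list", n)
    for (i in seq_len(n)) {
      tr <- setdiff(seq_len(n), i)
      if (nlevels(droplevels(y[tr])) < 2) {
        message("outer fold ", i, " skipped: single-class training set")
        next
      }
      folds <- stratified_folds(y[tr], config$inner_folds,
                                seed = config$seed + 1000L * i)
      acc <- numeric(nrow(g))
      for (ci in seq_len(nrow(g))) {
        hits <- 0L; tot <- 0L
        for (f in seq_len(config$inner_folds)) {
          itr <- tr[folds != f]; ite <- tr[folds == f]
          if (length(ite) == 0 || nlevels(droplevels(y[itr])) < 2) next
          z <- suppressWarnings(
            zscore_features(X[itr, , drop = FALSE], X[ite, , drop = FALSE]))
          m <- fit_svm(z$train, droplevels(y[itr]), kern, g$C[ci], g$gamma[ci])
          p <- predict(m, z$apply)
          hits <- hits + sum(p == y[ite]); tot <- tot + length(ite)
        }
        acc[ci] <- if (tot > 0) hits / tot else 0
      }
      best <- which.max(acc)
      pars[[i]] <- list(C = g$C[best], gamma = g$gamma[best],
                        inner_accuracy = acc[best])
      z <- suppressWarnings(
        zscore_features(X[tr, , drop = FALSE], X[i, , drop = FALSE]))
      m <- fit_svm(z$train, y[tr], kern, g$C[best], g$gamma[best])
      p <- predict(m, rbind(z$apply, z$train), decision.values = TRUE)
      dv <- oriented_decision(p, positive)
      pred[i] <- as.character(p[1])
      # calibrate against the fold's own training scores: decision values
      # from different outer folds are not on a common scale (leave-one-out
      # training sets are class-imbalanced), so the held-out score is taken
      # relative to the midpoint of the training class means
      mid <- (mean(dv[-1][y[tr] == positive]) +
                mean(dv[-1][y[tr] != positive])) / 2
      dec[i] <- dv[1] - mid
    }
    ok <- !is.na(dec)
    ra <- roc_auc(y[ok] == positive, dec[ok])
    res[[kern]] <- tibble::tibble(
      kernel = kern,
      accuracy = mean(pred[ok] == as.character(y)[ok]),
      auc = ra$auc, n = sum(ok))
    chosen[[kern]] <- pars
    dec_by_kernel[[kern]] <- dec
    pred_by_kernel[[kern]] <- pred
  }
  kerns <- names(res)
  structure(list(
    summary = do.call(rbind, res),
    scores = tibble::tibble(
      subject = rep(seq_len(n), length(kerns)),
      truth = rep(as.character(y), length(kerns)),
      kernel = rep(kerns, each = n),
      decision = unlist(dec_by_kernel[kerns], use.names = FALSE),
      predicted = unlist(pred_by_kernel[kerns], use.names = FALSE)),
    chosen = chosen,
    positive = positive),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report> positive class: ", x$positive, "\n", sep = "")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' Default feature sets for group discrimination
#'
#' Mirrors the convention of taking the discriminative microstate
#' indicators (class-B occurrence, class-C duration and contribution) and
#' the spatial-complexity indicators (anterior/posterior omega in theta,
#' beta-2 and gamma; global omega in beta-2 and gamma), plus their union.
#'
#' @return Named list of character vectors: `microstate`, `omega`,
#'   `combined`.
#' @export
default_feature_sets <- function() {
  micro <- c("occurrence_B", "duration_C", "contribution_C")
  om <- c("omega_anterior_theta", "omega_posterior_theta",
          "omega_anterior_beta2", "omega_posterior_beta2",
          "omega_anterior_gamma", "omega_posterior_gamma",
          "omega_global_beta2", "omega_global_gamma")
  list(microstate = micro, omega = om, combined = c(micro, om))
}
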