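# Group-statistics battery: two-way mixed repeated-measures ANOVA with
# Mauchly sphericity check and Greenhouse-Geisser correction, Bonferroni
# post hoc t-tests with Cohen's d, Spearman rank correlation, and a
# Wilcoxon rank-sum fallback for non-normal data.

#' Two-way mixed repeated-measures ANOVA
#'
#' One between-subject factor (e.g. group) crossed with one
#' within-subject factor (e.g. microstate class, scalp region). Built on
#' the multivariate linear-model route (`car::Anova` with an
#' intra-subject design), which supplies the Mauchly sphericity test and
#' Greenhouse-Geisser (GG) epsilon. GG-corrected p-values and degrees of
#' freedom are reported for within-subject effects whenever the Mauchly
#' test rejects sphericity at `gg_alpha`. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data long-format data frame.
#' @param dv name of the numeric response column.
#' @param subject name of the subject-identifier column.
#' @param within name of the within-subject factor column; every subject
#'   must have exactly one observation per level.
#' @param between name of the between-subject factor column.
#' @param gg_alpha Mauchly significance threshold for applying GG
#'   (default 0.05).
#' @return A tibble with one row per effect (`between`, `within`,
#'   `between:within`): `F`, `df1`, `df2`, `p`, `partial_eta_sq`,
#'   `gg_applied`, `gg_epsilon`, `mauchly_p`.
#' @export
mixed_anova <- function(data, dv, subject, within, between,
                        gg_alpha = 0.05) {
  data <- as.data.frame(data)
  for (col in c(dv, subject, within, between))
    if (!col %in% names(data)) stop("column '", col, "' not found")
  data[[subject]] <- factor(data[[subject]])
  data[[within]] <- factor(data[[within]])
  data[[between]] <- factor(data[[between]])
  lv <- levels(data[[within]])
  tab <- table(data[[subject]], data[[within]])
  if (any(tab != 1))
    stop("every subject needs exactly one observation per within level")

  Y <- tapply(data[[dv]], list(data[[subject]], data[[within]]), identity)
  Y <- matrix(unlist(Y), nrow(Y), ncol(Y),
              dimnames = dimnames(Y))[, lv, drop = FALSE]
  grp <- data[[between]][match(rownames(Y), as.character(data[[subject]]))]
  grp <- droplevels(grp)
  # type-III tests require sum-to-zero coding of the between factor
  mod <- stats::lm(Y ~ grp, contrasts = list(grp = "contr.sum"))
  idata <- data.frame(W = factor(lv, levels = lv))
  an <- car::Anova(mod, idata = idata, idesign = ~W, type = 3)
  s <- suppressWarnings(summary(an, multivariate = FALSE))
  uni <- s$univariate.tests

  eff_rows <- c(between = "grp", within = "W", interaction = "grp:W")
  sph <- s$sphericity.tests
  adj <- s$pval.adjustments
  out <- lapply(names(eff_rows), function(e) {
    rn <- eff_rows[[e]]
    ss <- uni[rn, "Sum Sq"]; ess <- uni[rn, "Error SS"]
    df1 <- uni[rn, "num Df"]; df2 <- uni[rn, "den Df"]
    Fv <- uni[rn, "F value"]; p <- uni[rn, "Pr(>F)"]
    gg_eps <- NA_real_; mau_p <- NA_real_; gg_applied <- FALSE
    if (e != "between" && length(lv) > 2 &&
        !is.null(sph) && rn %in% rownames(sph)) {
      mau_p <- sph[rn, "p-value"]
      gg_eps <- adj[rn, "GG eps"]
      if (is.finite(mau_p) && mau_p < gg_alpha) {
        gg_applied <- TRUE
        p <- adj[rn, "Pr(>F[GG])"]
        df1 <- df1 * gg_eps
        df2 <- df2 * gg_eps
      }
    }
    tibble::tibble(
      effect = switch(e, between = between, within = within,
                      interaction = paste0(between, ":", within)),
      F = Fv, df1 = df1, df2 = df2, p = p,
      partial_eta_sq = ss / (ss + ess),
      gg_applied = gg_applied, gg_epsilon = gg_eps, mauchly_p = mau_p)
  })
  do.call(rbind, out)
}

#' Cohen's d for two independent samples (pooled SD)
#'
#' @param x,y numeric vectors.
#' @return `(mean(x) - mean(y)) / s_pooled`.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  if (sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

#' Post hoc two-sample t-tests with Bonferroni correction
#'
#' @param samples named list of numeric vectors.
#' @param comparisons list of length-2 character vectors naming the pairs
#'   to compare; defaults to all pairs.
#' @param correction `"bonferroni"` (p_adj = min(1, m p)) or `"none"`.
#' @param var_equal use the pooled-variance t statistic (default `TRUE`,
#'   matching the pooled-SD Cohen's d).
#' @return A tibble: `comparison`, `t`, `df`, `p`, `p_adj`, `cohens_d`.
#' @export
posthoc_tests <- function(samples, comparisons = NULL,
                          correction = c("bonferroni", "none"),
                          var_equal = TRUE) {
  correction <- match.arg(correction)
  if (is.null(comparisons)) {
    nm <- names(samples)
    comparisons <- utils::combn(nm, 2, simplify = FALSE)
  }
  rows <- lapply(comparisons, function(cp) {
    x <- samples[[cp[1]]]; y <- samples[[cp[2]]]
    if (stats::sd(c(x, y)) == 0) {
      tt <- list(statistic = c(t = 0),
                 parameter = c(df = length(x) + length(y) - 2),
                 p.value = 1)
    } else {
      tt <- stats::t.test(x, y, var.equal = var_equal)
    }
    tibble::tibble(comparison = paste(cp, collapse = " vs "),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value, cohens_d = cohens_d(x, y))
  })
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$p_adj <- if (correction == "bonferroni") pmin(1, m * out$p) else out$p
  out[, c("comparison", "t", "df", "p", "p_adj", "cohens_d")]
}

#' Spearman rank correlation
#'
#' Pearson correlation of the (average-tie) ranks, with the asymptotic
#' t-approximation p-value.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return A list with `rho` and `p`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Wilcoxon rank-sum test (fallback for non-normal data)
#'
#' Exact enumeration for small tie-free samples (both sizes below 25),
#' otherwise the tie-corrected normal approximation with continuity
#' correction.
#'
#' @param x,y numeric vectors.
#' @return A list with `statistic` (rank-sum W) and `p` (two-sided).
#' @export
wilcoxon_fallback <- function(x, y) {
  exact <- length(x) < 25 && length(y) < 25
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}
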