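# mixed repeated-measures ANOVA, post hoc tests, correlations, Wilcoxon

# balanced 2-group x k-level mixed design generator
mixed_data <- function(n_per_group = 6, k = 3, group_shift = 0,
                       level_shift = NULL, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  if (is.null(level_shift)) level_shift <- rep(0, k)
  d <- expand.grid(subject = sprintf("s%02d", 1:n),
                   level = paste0("L", 1:k))
  d$group <- rep(rep(c("g1", "g2"), each = n_per_group), k)
  subj_re <- rnorm(n, sd = 0.8)[as.integer(factor(d$subject))]
  d$value <- subj_re + rnorm(nrow(d)) +
    level_shift[as.integer(factor(d$level))] +
    group_shift * (d$group == "g2")
  d
}

test_that("mixed ANOVA F and partial eta^2 match a sums-of-squares oracle", {
  d <- mixed_data(5, 3, group_shift = 1, level_shift = c(0, 0.5, 1), seed = 2)
  got <- mixed_anova(d, "value", "subject", "level", "group")

  # hand computation for the balanced two-way mixed design
  a <- 2; np <- 5; k <- 3
  cell <- tapply(d$value, list(d$group, d$level), mean)
  gm <- mean(d$value)
  subj_m <- tapply(d$value, d$subject, mean)
  grp_m <- rowMeans(cell)
  lev_m <- colMeans(cell)
  ss_group <- np * k * sum((grp_m - gm)^2)
  ss_subj <- k * sum((subj_m - gm)^2)
  ss_err_b <- ss_subj - ss_group
  ss_level <- a * np * sum((lev_m - gm)^2)
  ss_int <- np * sum((sweep(sweep(cell, 1, grp_m), 2, lev_m) + gm)^2)
  ss_tot <- sum((d$value - gm)^2)
  ss_err_w <- ss_tot - ss_subj - ss_level - ss_int
  F_group <- (ss_group / (a - 1)) / (ss_err_b / (a * np - a))
  F_level <- (ss_level / (k - 1)) / (ss_err_w / ((a * np - a) * (k - 1)))
  F_int <- (ss_int / ((a - 1) * (k - 1))) /
    (ss_err_w / ((a * np - a) * (k - 1)))

  expect_equal(got$F[got$effect == "group"], F_group, tolerance = 1e-8)
  expect_equal(got$F[got$effect == "level"], F_level, tolerance = 1e-8)
  expect_equal(got$F[got$effect == "group:level"], F_int, tolerance = 1e-8)
  expect_equal(got$partial_eta_sq[got$effect == "group"],
               ss_group / (ss_group + ss_err_b), tolerance = 1e-8)
  expect_equal(got$partial_eta_sq[got$effect == "level"],
               ss_level / (ss_level + ss_err_w), tolerance = 1e-8)
  expect_true(all(got$F >= 0))
  expect_true(all(got$p >= 0 & got$p <= 1))
})

test_that("mixed ANOVA validates completeness of the within factor", {
  d <- mixed_data(4, 3)
  expect_error(mixed_anova(d[-1, ], "value", "subject", "level", "group"),
               "exactly one observation")
  expect_error(mixed_anova(d, "value", "subject", "nope", "group"),
               "not found")
})

test_that("Greenhouse-Geisser correction engages when sphericity fails", {
  set.seed(4)
  n <- 16; k <- 4
  # strongly heterogeneous level variances/covariances violate sphericity
  base <- rnorm(n, sd = 2)
  Y <- cbind(base + rnorm(n, sd = 0.05), base + rnorm(n, sd = 0.05),
             rnorm(n, sd = 4), rnorm(n, sd = 0.2))
  d <- data.frame(subject = rep(sprintf("s%02d", 1:n), k),
                  level = rep(paste0("L", 1:k), each = n),
                  group = rep(rep(c("g1", "g2"), each = n / 2), k),
                  value = as.vector(Y))
  got <- mixed_anova(d, "value", "subject", "level", "group")
  wr <- got[got$effect == "level", ]
  expect_lt(wr$mauchly_p, 0.05)
  expect_true(wr$gg_applied)
  expect_lt(wr$gg_epsilon, 1)
  expect_lt(wr$df1, k - 1)          # corrected degrees of freedom
})

test_that("post hoc t-tests report Bonferroni-capped p and pooled-SD d", {
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  r <- posthoc_tests(same)
  expect_equal(r$t, 0)
  expect_equal(r$cohens_d, 0)
  s <- 1 / sqrt(2)                       # pooled SD exactly 1
  x <- c(1 - s, 1 + s)                   # mean 1
  y <- c(-s, s)                          # mean 0
  expect_equal(cohens_d(x, y), 1, tolerance = 1e-12)
  set.seed(5)
  smp <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8), d = rnorm(8))
  cmp <- list(c("a", "b"), c("a", "c"), c("a", "d"), c("b", "c"))
  r4 <- posthoc_tests(smp, cmp)
  expect_equal(nrow(r4), 4)
  expect_equal(r4$p_adj, pmin(1, 4 * r4$p))
  big <- which(r4$p >= 0.3)
  if (length(big)) expect_true(all(r4$p_adj[big] == 1))
})

test_that("Spearman correlation equals rank-then-Pearson, ties averaged", {
  expect_equal(spearman_corr(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_corr(1:10, -(1:10))$rho, -1)
  set.seed(6)
  x <- sample(1:5, 30, replace = TRUE)   # heavy ties
  y <- x + sample(0:2, 30, replace = TRUE)
  got <- spearman_corr(x, y)$rho
  expect_equal(got, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_error(spearman_corr(1:2, 1:2), "length")
})

test_that("the Wilcoxon fallback behaves at both extremes", {
  x <- c(1.2, 0.8, 1.0, 1.4, 0.9)
  r <- wilcoxon_fallback(x, x)
  expect_gte(r$p, 0.9)
  set.seed(7)
  a <- rnorm(10); b <- rnorm(10) + 50
  r2 <- wilcoxon_fallback(a, b)
  expect_lt(r2$p, 0.001)
  # rank-sum oracle: W = #{(i, j): a_i > b_j} for tie-free samples
  oracle <- sum(outer(a, b, ">"))
  expect_equal(r2$statistic, oracle)
})
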