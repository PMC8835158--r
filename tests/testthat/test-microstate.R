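# GFP, peaks, TAAHC, class ordering, backfitting, GEV, parameters

test_that("GFP matches its defining formula", {
  const <- as_epochs(matrix(7, 10, 4), 100)
  expect_equal(max(compute_gfp(const)$values), 0)
  two <- as_epochs(matrix(c(1, -1), 1, 2), 100, tiny_montage(2))
  expect_equal(as.vector(compute_gfp(two)$values), 1)
  set.seed(1)
  mat <- matrix(rnorm(50 * 30), 50, 30)
  ep <- as_epochs(mat, 100, default_montage())
  g <- compute_gfp(ep)$values[1, ]
  oracle <- apply(mat, 1, function(v) sqrt(sum((v - mean(v))^2) / length(v)))
  expect_equal(g, oracle, tolerance = 1e-12)
})

test_that("GFP peaks are strict interior local maxima", {
  expect_equal(find_gfp_peaks(1:10)[[1]], integer(0))
  expect_equal(find_gfp_peaks(c(1, 3, 1, 3, 1))[[1]], c(2L, 4L))
  set.seed(2)
  v <- abs(sin(seq(0, 20, length.out = 300))) + rnorm(300, sd = 0.05)
  got <- find_gfp_peaks(v)[[1]]
  oracle <- which(vapply(2:299, function(i)
    v[i] > v[i - 1] && v[i] > v[i + 1], TRUE)) + 1L
  expect_equal(got, oracle)
})

test_that("microstate band filter passes 10 Hz and rejects 1 and 30 Hz", {
  mk <- function(f) {
    t <- seq(0, 2 - 1 / 250, by = 1 / 250)
    as_epochs(matrix(sin(2 * pi * f * t), ncol = 4, nrow = 500), 250)
  }
  amp <- function(ep) mid_amplitude(ep$epochs[1, , 1])
  expect_gt(amp(microstate_bandpass(mk(10))), 10^(-1 / 20))  # within 1 dB
  expect_lt(amp(microstate_bandpass(mk(30))), 10^(-20 / 20)) # >= 20 dB down
  expect_lt(amp(microstate_bandpass(mk(1))), 10^(-20 / 20))
})

test_that("TAAHC recovers orthogonal prototypes exactly and ignores polarity", {
  set.seed(3)
  proto <- qr.Q(qr(matrix(rnorm(30 * 5), 30, 5)))[, 2:5]  # orthogonal
  proto <- apply(proto, 2, function(v) { v <- v - mean(v); v / sqrt(sum(v^2)) })
  signs <- sample(c(-1, 1), 80, replace = TRUE)
  cls <- rep(1:4, each = 20)
  maps <- t(proto[, cls]) * signs
  fit <- taahc_cluster(maps, 4)
  r <- abs(cor(fit$prototypes, proto))
  expect_equal(apply(r, 2, max), rep(1, 4), tolerance = 1e-6)
  # identical clustering when every map's sign is flipped
  fit2 <- taahc_cluster(-maps, 4)
  expect_equal(fit2$assignment, fit$assignment)
  expect_equal(abs(diag(cor(fit2$prototypes, fit$prototypes))), rep(1, 4),
               tolerance = 1e-6)
  expect_error(taahc_cluster(maps[1:3, ], 4), "fewer maps")
})

test_that("TAAHC recovers noisy prototypes to |r| >= 0.95", {
  set.seed(4)
  proto <- make_prototype_maps(default_montage(), seed = 6)
  cls <- rep(1:4, each = 15)
  maps <- t(proto[, cls]) + matrix(rnorm(60 * 30, sd = 0.25 / sqrt(30)), 60)
  maps <- maps * sample(c(-1, 1), 60, replace = TRUE)
  fit <- taahc_cluster(maps, 4)
  r <- abs(cor(fit$prototypes, proto))
  expect_true(all(apply(r, 2, max) >= 0.95))
})

test_that("class ordering matches an exhaustive assignment search", {
  tmpl <- canonical_templates(default_montage())
  shuffled <- tmpl[, c(3, 1, 4, 2)]
  out <- order_classes(shuffled, tmpl)
  expect_equal(unname(abs(diag(cor(out, tmpl)))), rep(1, 4), tolerance = 1e-9)
  out2 <- order_classes(-shuffled, tmpl)
  expect_equal(unname(out2), unname(out), tolerance = 1e-9)  # sign oriented
  # random prototypes vs independent brute force over the 24 permutations
  set.seed(5)
  rnd <- apply(matrix(rnorm(30 * 4), 30), 2,
               function(v) { v <- v - mean(v); v / sqrt(sum(v^2)) })
  got <- order_classes(rnd, tmpl)
  r <- abs(cor(rnd, tmpl))
  perms <- rbind()
  for (a in 1:4) for (b in 1:4) for (cc in 1:4) for (d in 1:4)
    if (length(unique(c(a, b, cc, d))) == 4)
      perms <- rbind(perms, c(a, b, cc, d))
  scores <- apply(perms, 1, function(p) r[p[1], 1] + r[p[2], 2] +
                    r[p[3], 3] + r[p[4], 4])
  best <- perms[which.max(scores), ]
  expect_equal(abs(cor(got[, "B"], rnd[, best[2]])), 1, tolerance = 1e-9)
})

test_that("backfitting labels peaks by max |r| and is polarity-invariant", {
  set.seed(6)
  proto <- make_prototype_maps(default_montage(), seed = 2)
  mat <- matrix(rnorm(200 * 30), 200, 30)
  ep <- rereference_average(as_epochs(mat, 100, default_montage()))
  labs <- backfit(ep, proto)
  # per-peak brute-force correlation oracle
  peaks <- find_gfp_peaks(compute_gfp(ep))[[1]]
  for (pk in peaks[1:20]) {
    v <- ep$epochs[1, pk, ]
    rr <- vapply(1:4, function(k) abs(cor(v, proto[, k])), 0)
    expect_equal(labs[1, pk], which.max(rr))
  }
  ep_flip <- ep
  ep_flip$epochs <- -ep_flip$epochs
  expect_equal(backfit(ep_flip, proto), labs)
  # non-peak samples inherit the nearest peak's label
  expect_true(all(labs[1, 1:peaks[1]] == labs[1, peaks[1]]))
})

test_that("GEV is exact on pure prototypes, zero on orthogonal labels", {
  proto <- make_prototype_maps(default_montage(), seed = 2)
  lab <- rep(1:4, each = 25)
  mat <- t(proto[, lab]) * rnorm(100, sd = 3)
  ep <- as_epochs(mat, 100, default_montage())
  expect_equal(compute_gev(ep, matrix(lab, 1), proto), 1, tolerance = 1e-9)
  # orthogonal complement labels explain nothing
  ortho <- qr.Q(qr(cbind(proto, matrix(rnorm(30 * 4), 30))))[, 5:8]
  ortho <- apply(ortho, 2, function(v) { v <- v - mean(v); v / sqrt(sum(v^2)) })
  data_p <- t(proto[, rep(1, 100)])
  epo <- as_epochs(data_p, 100, default_montage())
  gev0 <- compute_gev(epo, matrix(rep(1, 100), 1), ortho)
  expect_lt(gev0, 0.05)
  # direct-summation oracle on random data/labels
  set.seed(7)
  mat <- matrix(rnorm(60 * 30), 60, 30)
  epr <- rereference_average(as_epochs(mat, 100, default_montage()))
  labr <- matrix(sample(1:4, 60, replace = TRUE), 1)
  got <- compute_gev(epr, labr, proto)
  g <- compute_gfp(epr)$values[1, ]
  num <- den <- 0
  for (t in 1:60) {
    v <- epr$epochs[1, t, ]
    num <- num + (g[t] * cor(v, proto[, labr[1, t]]))^2
    den <- den + g[t]^2
  }
  expect_equal(got, num / den, tolerance = 1e-12)
})

test_that("segment statistics follow their definitions", {
  lab <- matrix(rep(c(1, 2, 1, 2), each = 10), 1)  # one 40-sample epoch
  st <- segment_stats(lab, 100)
  expect_equal(unname(st$contribution_pct[1:2]), c(50, 50))
  expect_equal(unname(st$duration_ms[1:2]), c(100, 100))  # interior segments
  expect_equal(sum(st$contribution_pct), 100, tolerance = 1e-6)
  # 5 complete A-segments within 1 s -> occurrence 5 /s
  lab2 <- matrix(c(2, rep(c(1, 1, 2, 2), 5), rep(2, 79)), 1)
  st2 <- segment_stats(lab2, 100)
  expect_equal(unname(st2$occurrence_per_s[1]), 5)
})

test_that("recovered mean lifetimes match the planted 80 ms", {
  pa <- microstate_gen_params(mean_duration_ms = 80, seed = 12)
  lab <- sample_state_sequence(pa, 200, 250)
  labm <- matrix(lab, nrow = 10, byrow = TRUE)
  st <- segment_stats(labm, 250)
  seg_count <- sum(rle(lab)$lengths > 0)
  expect_gt(seg_count, 1000)
  expect_true(all(abs(st$duration_ms - 80) < 5))
})

test_that("transition matrices match a pair-counting oracle", {
  lab <- matrix(rep(c(1, 2, 1, 2), each = 5), 1)
  tm <- transition_matrix(lab)
  expect_equal(tm["A", "B"], 1)
  expect_equal(tm["B", "A"], 1)
  expect_equal(sum(tm), 2)
  expect_equal(sum(row(tm) != col(tm)), 12)  # informative cells for 4 classes
  set.seed(8)
  pa <- microstate_gen_params(seed = 13)
  labs <- matrix(sample_state_sequence(pa, 100, 250), nrow = 5, byrow = TRUE)
  got <- transition_matrix(labs)
  counts <- matrix(0, 4, 4)
  for (e in 1:5) {
    seg <- rle(labs[e, ])$values
    for (i in seq_len(length(seg) - 1))
      counts[seg[i], seg[i + 1]] <- counts[seg[i], seg[i + 1]] + 1
  }
  oracle <- counts / rowSums(counts)
  expect_equal(unname(unclass(got)), oracle, tolerance = 1e-12)
  expect_true(all(abs(rowSums(got) - 1) < 1e-9))
  expect_true(all(diag(got) == 0))
})

test_that("microstate statistics are invariant to sign and scale", {
  m <- default_montage()
  p <- make_prototype_maps(m, seed = 2)
  pa <- microstate_gen_params(snr = 20, seed = 3)
  lab <- sample_state_sequence(pa, 8, 250)
  rec <- synthesize_recording(p, lab, pa, m)
  ep <- rereference_average(epoch_recording(rec, 2))
  base <- backfit(ep, p)
  for (f in c(-1, 3.7)) {
    ep2 <- ep
    ep2$epochs <- ep2$epochs * f
    expect_equal(backfit(ep2, p), base)
  }
})

test_that("a noise-free four-class model attains GEV >= 0.99", {
  m <- default_montage()
  p <- make_prototype_maps(m, seed = 4)
  pa <- microstate_gen_params(snr = Inf, seed = 5)
  lab <- sample_state_sequence(pa, 10, 250)
  rec <- synthesize_recording(p, lab, pa, m)
  ep <- rereference_average(epoch_recording(rec, 2))
  # per-sample labelling measures the model's explanatory ceiling
  labs <- backfit(ep, p, interpolate = FALSE)
  expect_gte(compute_gev(ep, labs, p), 0.99)
})
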