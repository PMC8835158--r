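# synthetic-EEG generator: prototypes, semi-Markov sequences, recordings,
# synchronized mixtures, cohorts

test_that("prototype maps are zero-mean, unit-norm, distinct, deterministic", {
  m <- default_montage()
  p1 <- make_prototype_maps(m, seed = 7)
  expect_equal(colnames(p1), c("A", "B", "C", "D"))
  expect_equal(unname(colMeans(p1)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(sqrt(colSums(p1^2))), rep(1, 4), tolerance = 1e-12)
  # direct pairwise-correlation oracle
  for (i in 1:3) for (j in (i + 1):4)
    expect_lt(abs(cor(p1[, i], p1[, j])), 0.8)
  expect_identical(p1, make_prototype_maps(m, seed = 7))
  expect_false(identical(p1, make_prototype_maps(m, seed = 8)))
  expect_error(make_prototype_maps(tiny_montage(3)), "at least 4")
})

test_that("state sequences follow forced cycles and never repeat a class", {
  P <- matrix(0, 4, 4)
  P[1, 2] <- 1; P[2, 1] <- 1; P[3, 4] <- 1; P[4, 3] <- 1
  pa <- microstate_gen_params(mean_duration_ms = 80, transition_matrix = P,
                              seed = 1)
  lab <- sample_state_sequence(pa, 20, 250)
  seg <- rle(lab)$values
  expect_true(all(seg %in% c(1, 2)) || all(seg %in% c(3, 4)))
  expect_true(all(diff(seg) != 0))  # alternating
  bad <- microstate_gen_params(seed = 1)
  bad$transition_matrix[1, ] <- c(0, 2, 0, 0)
  expect_error(sample_state_sequence(bad, 1, 100), "sum to 1")
})

test_that("segment lifetimes and transitions match the planted model", {
  pa <- microstate_gen_params(mean_duration_ms = 80, seed = 42)
  lab <- sample_state_sequence(pa, 200, 250)
  seg <- rle(lab)
  expect_gt(length(seg$lengths), 1000)
  emp_ms <- mean(seg$lengths[-c(1, length(seg$lengths))]) / 250 * 1000
  expect_lt(abs(emp_ms - 80), 5)
  # counting oracle for transition frequencies, 500 s
  P <- matrix(c(0, .5, .3, .2,
                .4, 0, .4, .2,
                .3, .3, 0, .4,
                .2, .5, .3, 0), 4, 4, byrow = TRUE)
  pa2 <- microstate_gen_params(mean_duration_ms = 60, transition_matrix = P,
                               seed = 11)
  seg2 <- rle(sample_state_sequence(pa2, 500, 250))$values
  emp <- matrix(0, 4, 4)
  for (i in seq_len(length(seg2) - 1))
    emp[seg2[i], seg2[i + 1]] <- emp[seg2[i], seg2[i + 1]] + 1
  emp <- emp / rowSums(emp)
  expect_lt(max(abs(emp - P)), 0.05)
})

test_that("noise-free recordings carry the planted label at every GFP peak", {
  m <- default_montage()
  p <- make_prototype_maps(m, seed = 3)
  pa <- microstate_gen_params(snr = Inf, seed = 5)
  lab <- sample_state_sequence(pa, 10, 250)
  rec <- synthesize_recording(p, lab, pa, m)
  ep <- rereference_average(epoch_recording(rec, 2))
  peaks <- find_gfp_peaks(compute_gfp(ep))
  labm <- matrix(lab[seq_len(5 * 500)], 5, 500, byrow = TRUE)
  fitted <- backfit(ep, p)
  for (e in 1:5)
    expect_equal(fitted[e, peaks[[e]]], labm[e, peaks[[e]]])
})

test_that("recordings are deterministic and degrade gracefully to noise", {
  m <- default_montage()
  p <- make_prototype_maps(m, seed = 3)
  pa <- microstate_gen_params(snr = 10, seed = 5)
  lab <- sample_state_sequence(pa, 4, 250)
  r1 <- synthesize_recording(p, lab, pa, m)
  r2 <- synthesize_recording(p, lab, pa, m)
  expect_identical(r1$data, r2$data)
  # zero prototype amplitude: output is the bare noise process
  r0 <- synthesize_recording(p, lab, pa, m, amplitude_uV = 0)
  expect_gt(sd(r0$data), 0.5)
  expect_lt(abs(mean(r0$data)), 0.1)
})

test_that("synchronized mixtures have omega tracking the mode structure", {
  band_om <- function(rec, band = c(8, 12)) {
    sp <- cross_spectra(epoch_recording(rec, 2), "global", max_freq_hz = 13)
    band_omega(sp, list(low_hz = band[1], high_hz = band[2]))
  }
  # single common source: omega = 1
  r1 <- synthesize_synchronized(sync_gen_params(7, 1, seed = 2,
                                                duration_s = 30))
  expect_lt(abs(band_om(r1) - 1), 0.05)
  # as many equally weighted modes as channels: omega within 10% of K
  rK <- synthesize_synchronized(sync_gen_params(7, 7, seed = 2,
                                                duration_s = 240))
  expect_lt(abs(band_om(rK) - 7) / 7, 0.10)
  # monotonicity in the mode count, 20 seed replicates
  deltas <- vapply(1:20, function(s) {
    o2 <- band_om(synthesize_synchronized(
      sync_gen_params(7, 2, seed = s, duration_s = 20)))
    o6 <- band_om(synthesize_synchronized(
      sync_gen_params(7, 6, seed = s, duration_s = 20)))
    o6 - o2
  }, 0)
  expect_true(all(deltas > 0))
  expect_error(sync_gen_params(4, 6), "exceed")
})

test_that("cohorts are deterministic with sane scores and ground truth", {
  spec <- cohort_spec(n_per_group = c(2, 2), duration_s = 8, seed = 9)
  c1 <- make_cohort(spec)
  c2 <- make_cohort(spec)
  expect_identical(c1$subjects[[3]]$recording$data,
                   c2$subjects[[3]]$recording$data)
  groups <- vapply(c1$subjects, `[[`, 0, "group")
  scores <- vapply(c1$subjects, `[[`, 0, "score")
  expect_equal(groups, c(1, 1, 2, 2))
  expect_true(all(scores[groups == 1] >= 1 & scores[groups == 1] <= 13))
  expect_true(all(scores[groups == 2] >= 14 & scores[groups == 2] <= 27))
  tr <- c1$subjects[[3]]$truth
  expect_equal(tr$rates[2] / exp(0), tr$rates[2])  # truth stored
  expect_named(tr$sync, default_bands()$name)
  # group-2 planted effects visible in the stored ground truth
  expect_gt(mean(vapply(c1$subjects[3:4], function(s) s$truth$sync["beta-2"], 0)),
            mean(vapply(c1$subjects[1:2], function(s) s$truth$sync["beta-2"], 0)))
})

test_that("recordings round-trip through the flat-matrix + sidecar format", {
  m <- default_montage()
  p <- make_prototype_maps(m, seed = 3)
  pa <- microstate_gen_params(snr = 10, seed = 5)
  rec <- synthesize_recording(p, sample_state_sequence(pa, 2, 250), pa, m)
  path <- file.path(tempdir(), "rec.txt")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$data, rec$data, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$fs_hz, rec$fs_hz)
  expect_equal(back$montage$names, rec$montage$names)
  expect_equal(back$montage$anterior_set, rec$montage$anterior_set)
  unlink(c(path, paste0(path, ".json")))
})
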