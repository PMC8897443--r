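test_that("dF/F z-scoring normalizes by the pre-onset baseline", {
  fr <- 10
  f <- c(rnorm(fr, 0, 1e-9), rep(0, 2 * fr))  # 1 s baseline ~0, flat after
  z <- dff_zscore(f, fr, onset_s = 1)
  expect_false(z$degenerate)

  # hand case: baseline mean 10, sd 2, one post frame at 14 -> z = 2
  base <- c(8, 12, 8, 12, 8, 12, 8, 12, 8, 12)  # mean 10, sd ~2.11 (sample)
  f2 <- c(base, rep(14, 2 * fr))
  z2 <- dff_zscore(f2, fr, onset_s = 1)
  expect_equal(z2$z[z2$onset_index], (14 - 10) / sd(base))

  # shift invariance
  z3 <- dff_zscore(f2 + 100, fr, onset_s = 1)
  expect_equal(z3$z, z2$z)

  # zero baseline variance flags degenerate
  z4 <- dff_zscore(c(rep(5, fr), rep(9, 2 * fr)), fr, onset_s = 1)
  expect_true(z4$degenerate)
  expect_true(all(is.na(z4$z)))
  expect_true(is.na(trial_response(z4, fr)))

  expect_error(dff_zscore(rep(1, 5), fr, onset_s = 0.1), "pre-onset")
})

test_that("trial response is the mean over the 2-s post-onset window", {
  expect_equal(trial_response(c(1, 2, 3)), 2)
  expect_equal(trial_response(rep(0, 10)), 0)
  fr <- 5
  base <- rep(c(0, 2), length.out = fr)
  f <- c(base, rep(3, 2 * fr), rep(99, fr))
  z <- dff_zscore(f, fr, onset_s = 1, post_s = 3)
  # only the first 2 s after onset contribute
  expect_equal(trial_response(z, fr), (3 - mean(base)) / sd(base))
})

test_that("responsiveness test applies Holm over per-frequency t-tests", {
  set.seed(1)
  # single-frequency case reduces to an uncorrected t-test
  r <- matrix(rnorm(20, 1, 1), 1, 20)
  mat1 <- trial_response_matrix(r, 1000)
  expect_equal(attr(is_responsive(mat1), "p_corrected"),
               t.test(r[1, ], mu = 0)$p.value)

  # one frequency at 5 sigma / sqrt(n): overwhelming power
  n <- 25
  resp <- matrix(rnorm(12 * n, 0, 1), 12, n)
  resp[4, ] <- resp[4, ] + 5 / sqrt(n) * 3  # 3x the 5-sigma detection bar
  mat <- trial_response_matrix(resp, default_frequencies())
  expect_true(as.logical(is_responsive(mat)))

  # zero-variance rows
  flat0 <- trial_response_matrix(matrix(0, 2, 5), c(100, 200))
  expect_false(as.logical(is_responsive(flat0)))
  flat1 <- trial_response_matrix(rbind(rep(1, 5), rep(0, 5)), c(100, 200))
  expect_true(as.logical(is_responsive(flat1)))
})

test_that("FRF takes per-frequency means with lowest-frequency tie-break", {
  m <- matrix(0, 3, 4)
  m[2, ] <- 5
  frf <- frequency_response_function(trial_response_matrix(m, c(100, 200, 400)))
  expect_equal(frf$best_frequency, 200)
  expect_equal(frf$mean_response, c(0, 5, 0))

  ties <- frequency_response_function(
    trial_response_matrix(matrix(1, 3, 4), c(100, 200, 400)))
  expect_equal(ties$best_frequency, 100)

  # brute-force argmax oracle on random matrices
  set.seed(7)
  for (i in 1:10) {
    r <- matrix(rnorm(60), 6, 10)
    freqs <- sort(runif(6, 1000, 30000))
    frf <- frequency_response_function(trial_response_matrix(r, freqs))
    means <- sapply(1:6, function(k) mean(r[k, ]))
    expect_equal(frf$mean_response, means)
    expect_equal(frf$best_frequency, freqs[which(means == max(means))[1]])
  }
})

test_that("sparseness matches the normalized ratio formula", {
  expect_equal(sparseness(rep(3, 8)), 0)
  expect_equal(sparseness(c(7, rep(0, 11))), 1)   # one-hot, N = 12
  expect_equal(sparseness(c(2, 1, 1)), 1 / 6)
  expect_true(is.na(sparseness(rep(0, 5))))
  # permutation invariance
  set.seed(5)
  r <- rexp(9)
  expect_equal(sparseness(r), sparseness(sample(r)))
  # negative responses are kept; S may exceed 1
  expect_gt(sparseness(c(1, -1, 0.1)), 1)
})

test_that("Z_diff matches the closed form and its invariances", {
  expect_equal(zdiff(c(2, 4), c(1, 3)), 1 / sqrt(2))
  expect_equal(zdiff(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_true(is.na(zdiff(c(1, 1), c(0, 2))))

  set.seed(8)
  a <- rnorm(20); b <- rnorm(20, 1)
  z <- zdiff(a, b)
  expect_equal(zdiff(3 * a + 5, 3 * b + 5), z)
})

test_that("Z_diff permutation significance is deterministic and powered", {
  set.seed(10)
  a <- rnorm(25); b <- rnorm(25)
  r1 <- zdiff_significance(a, b, seed = 99)
  r2 <- zdiff_significance(a, b, seed = 99)
  expect_identical(r1, r2)
  expect_length(r1$null_scores, 250)
  expect_identical(r1$significant, unname(r1$zdiff > r1$null_95th))

  # 3 pooled-SD separation at n = 25 is detected in every seed tried
  for (s in 1:20) {
    set.seed(s)
    hi <- rnorm(25, 3); lo <- rnorm(25, 0)
    expect_true(zdiff_significance(hi, lo, seed = s)$significant)
  }
})

test_that("frequency interpolation is linear on the log2 axis", {
  frf <- list(mean_response = c(1, 3, 2), frequencies = c(4000, 8000, 16000))
  expect_equal(interpolate_at_frequency(frf, 8000), 3)
  # log2 midpoint of 4 and 8 kHz
  expect_equal(interpolate_at_frequency(frf, 4000 * sqrt(2)), 2)
  # dense-grid oracle: piecewise-linear in octaves
  for (target in c(5000, 6500, 9000, 15000)) {
    f <- log2(c(4000, 8000, 16000)); y <- c(1, 3, 2)
    t2 <- log2(target)
    seg <- if (t2 <= f[2]) 1 else 2
    w <- (t2 - f[seg]) / (f[seg + 1] - f[seg])
    expect_equal(interpolate_at_frequency(frf, target),
                 (1 - w) * y[seg] + w * y[seg + 1], tolerance = 1e-12)
  }
  expect_error(interpolate_at_frequency(frf, 1000))
})

test_that("per-repeat CS responses interpolate between flanking tones", {
  r <- rbind(c(1, 2, 3), c(5, 6, 7))
  mat <- trial_response_matrix(r, c(10000, 20000))
  expect_equal(responses_at_frequency(mat, 10000), c(1, 2, 3))
  mid <- responses_at_frequency(mat, 10000 * sqrt(2))
  expect_equal(mid, (r[1, ] + r[2, ]) / 2)
})

test_that("FRF normalization and percent change behave as documented", {
  frf <- structure(list(mean_response = c(1, 4, 2), frequencies = c(1, 2, 3),
                        best_frequency = 2, sparseness = 0.3),
                   class = "frequency_response_function")
  nf <- normalize_frf(frf)
  expect_equal(max(nf$mean_response), 1)
  expect_equal(normalize_frf(c(2, 8, 4)), normalize_frf(c(1, 4, 2)))
  expect_equal(normalize_frf(rep(2, 5)), rep(1, 5))

  expect_equal(frf_percent_change(c(0.5, 1), c(0.75, 1)), c(50, 0))
  expect_true(is.na(frf_percent_change(c(0, 1), c(0.5, 1))[1]))
  # relative measure: swapping pre and post is not a sign flip
  expect_false(isTRUE(all.equal(frf_percent_change(c(0.5, 1), c(0.75, 1)),
                                -frf_percent_change(c(0.75, 1), c(0.5, 1)))))
})

test_that("best-frequency octave distance uses the CS+ reference", {
  expect_equal(bf_distance_octaves(15000), 0)
  expect_equal(bf_distance_octaves(30000), 1)
  expect_equal(bf_distance_octaves(11400), abs(log2(11400 / 15000)))
  expect_equal(round(bf_distance_octaves(11400), 2), 0.40)
})

test_that("BF-bin resampling flattens the best-frequency histogram", {
  set.seed(6)
  bf <- 2^runif(300, log2(5000), log2(32000))
  idx <- resample_by_bf_bin(bf, n_bins = 12, per_bin = 40, seed = 3)
  edges <- seq(log2(min(bf)), log2(max(bf)), length.out = 13)
  counts <- table(findInterval(log2(bf[idx]), edges,
                               rightmost.closed = TRUE, all.inside = TRUE))
  expect_true(all(counts == 40))
  expect_identical(idx, resample_by_bf_bin(bf, n_bins = 12, per_bin = 40, seed = 3))
  expect_warning(resample_by_bf_bin(c(5000, 5100, 32000), n_bins = 12, seed = 1),
                 "empty")
})

test_that("vectorized session statistics agree with the per-neuron operations", {
  co <- generate_cohort(small_cohort(seed = 21))
  stats <- session_neuron_stats(co, "m01", 1, n_shuffles = 0)
  cfg <- co$config
  arr <- co$mice[["m01"]]$sessions[[1]]
  for (i in c(1, 7, 30)) {
    mat <- trial_response_matrix(arr[i, , ], cfg$frequencies)
    frf <- frequency_response_function(mat)
    expect_equal(stats$responsive[i], as.logical(is_responsive(mat)))
    expect_equal(stats$bf_hz[i], frf$best_frequency)
    expect_equal(stats$sparseness[i], frf$sparseness)
    expect_equal(stats$zdiff[i],
                 zdiff(responses_at_frequency(mat, cfg$cs_plus_hz),
                       responses_at_frequency(mat, cfg$cs_minus_hz)))
  }
})
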