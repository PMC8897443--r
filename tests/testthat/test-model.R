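test_that("circular distance wraps the frequency channels", {
  expect_equal(circular_distance(1, 10, 10), 1)
  expect_equal(circular_distance(4, 4, 10), 0)
  expect_equal(circular_distance(3, 8, 10), 5)
  expect_equal(circular_distance(2, 9, 10), 3)
})

test_that("tuning matrices follow the printed Gaussian with rectified inhibition", {
  t_mgb <- tuning_matrix(0.8, 0, 1, 10)
  expect_equal(unname(diag(t_mgb)), rep(1, 10))
  expect_equal(t_mgb[1, 2], exp(-1 / 1.6))

  t_ctx <- tuning_matrix(3, 0.9, 1 / 1.8, 10)
  expect_equal(t_ctx[1, 1], 0.1 / 1.8, tolerance = 1e-12)
  # sigma = 3 with I = 0.9: off-diagonal terms rectify to zero
  expect_true(all(t_ctx[row(t_ctx) != col(t_ctx)] == 0))

  expect_true(all(tuning_matrix(3, 1, 1, 10) == 0))
  expect_error(tuning_matrix(0, 0.9), "positive")
})

test_that("forward pass adds channel-matched cortical feedback", {
  p <- circuit_params()
  st <- circuit_state(p)
  s <- tone_stimulus(3)
  x_off <- circuit_forward(p, st, s, ac_off = TRUE)
  t_mgb <- tuning_matrix(p$sigma_mgb, 0, 1, 10)
  expect_equal(x_off$x_mgb, drop(t_mgb %*% s))
  expect_equal(x_off$x_ctx, rep(0, 10))

  # broad cortex spreads activity to the CS- channel
  st10 <- st; st10$sigma_ctx <- 10
  x3 <- circuit_forward(p, st, s)
  x10 <- circuit_forward(p, st10, s)
  expect_gt(x10$x_ctx[p$cs_minus_channel], x3$x_ctx[p$cs_minus_channel])

  # fixed-point option agrees with the single pass to first order
  xr <- circuit_forward(p, st, s, recurrent = TRUE)
  expect_equal(xr$x_mgb, x3$x_mgb, tolerance = 0.05)
})

test_that("Delta rule gates on the shock and clips at the bounds", {
  p <- circuit_params()
  st <- circuit_state(p)
  x <- list(x_mgb = rep(1, 10), x_ctx = rep(0.5, 10))
  st0 <- delta_update(p, st, x$x_mgb, x$x_ctx, shock = 0)
  expect_equal(st0$w_mgb, st$w_mgb)

  st1 <- delta_update(p, st, x$x_mgb, x$x_ctx, shock = 1)
  expect_equal(st1$w_mgb, rep(0.2, 10))

  for (i in 1:10) st <- delta_update(p, st, x$x_mgb, x$x_ctx, shock = 1)
  expect_equal(st$w_mgb, rep(1, 10))     # 0.1 + 10 * 0.1, clipped at 1
  expect_true(all(st$w_ctx <= 1 & st$w_ctx >= 0))
})

test_that("freezing response self-normalizes and is monotone in the weights", {
  p <- circuit_params()
  st <- circuit_state(p)
  st$w_mgb <- rep(1, 10); st$w_ctx <- rep(1, 10)
  expect_equal(freezing_response(p, st, tone_stimulus(3)), 1)
  st$w_mgb <- rep(0, 10); st$w_ctx <- rep(0, 10)
  expect_equal(freezing_response(p, st, tone_stimulus(3)), 0)

  set.seed(2)
  st$w_mgb <- runif(10, 0, 0.5); st$w_ctx <- runif(10, 0, 0.5)
  f0 <- freezing_response(p, st, tone_stimulus(3))
  st2 <- st; st2$w_mgb[3] <- st2$w_mgb[3] + 0.3
  expect_gte(freezing_response(p, st2, tone_stimulus(3)), f0)

  expect_equal(model_learning_specificity(p, circuit_state(p)), 0)
})

test_that("narrow cortical tuning yields higher specificity than broad, deterministically", {
  p3 <- circuit_params(sigma_ctx_init = 3, n_drift_steps = 0, drift_amplitude = 0)
  p10 <- circuit_params(sigma_ctx_init = 10, n_drift_steps = 0, drift_amplitude = 0)
  ls3 <- run_experiment(p3, "control")$ls_at_conditioning
  ls10 <- run_experiment(p10, "control")$ls_at_conditioning
  expect_gt(ls3, ls10)
  expect_true(ls3 >= -1 && ls3 <= 1)
  # repeat runs are bit-identical (no stochastic element without drift)
  expect_identical(ls3, run_experiment(p3, "control")$ls_at_conditioning)
})

test_that("manipulations reproduce the circuit-level effects", {
  for (sig in c(3, 10)) {
    p <- circuit_params(sigma_ctx_init = sig, n_drift_steps = 0,
                        drift_amplitude = 0)
    ctrl <- run_experiment(p, "control")$ls_at_conditioning
    red <- run_experiment(p, "reduced_inhibition")$ls_at_conditioning
    acc <- run_experiment(p, "ac_off_conditioning")$ls_at_conditioning
    rec <- run_experiment(p, "ac_off_recall")$ls_at_conditioning
    expect_lt(red, ctrl)      # disinhibition generalizes the fear response
    expect_lt(acc, ctrl)      # silencing cortex during learning reduces LS
    # recall inactivation barely moves LS: an order below the other effects
    expect_lt(abs(rec - ctrl), 0.5 * abs(red - ctrl))
  }
  expect_error(run_experiment(circuit_params(), "nonsense"))
})

test_that("cortex silent by inhibition makes ac_off manipulations exact no-ops", {
  p <- circuit_params(inhibition_ctx = 1, n_drift_steps = 0, drift_amplitude = 0)
  ctrl <- run_experiment(p, "control")
  off_c <- run_experiment(p, "ac_off_conditioning")
  off_r <- run_experiment(p, "ac_off_recall")
  expect_identical(ctrl$ls_at_conditioning, off_c$ls_at_conditioning)
  expect_identical(ctrl$ls_at_conditioning, off_r$ls_at_conditioning)
})

test_that("tuning width drifts as a bounded symmetric random walk", {
  p <- circuit_params(sigma_ctx_init = 20)
  st <- circuit_state(p)
  set.seed(1)
  for (i in 1:200) {
    st <- drift_step(p, st)
    expect_lte(st$sigma_ctx, 20)
    expect_gte(st$sigma_ctx, 4)
  }
  # interior steps have mean displacement ~0
  p2 <- circuit_params(sigma_ctx_init = 12)
  st2 <- circuit_state(p2)
  set.seed(2)
  steps <- replicate(5000, {
    before <- st2$sigma_ctx
    st2 <<- drift_step(p2, st2)
    st2$sigma_ctx - before
  })
  expect_lt(abs(mean(steps)), 0.01)

  # zero amplitude leaves the state untouched (no bound clipping either)
  p0 <- circuit_params(sigma_ctx_init = 3, drift_amplitude = 0)
  expect_identical(drift_step(p0, circuit_state(p0))$sigma_ctx, 3)
})

test_that("weights stay in bounds through arbitrary protocols", {
  set.seed(3)
  p <- circuit_params(n_drift_steps = 50)
  for (m in c("control", "reduced_inhibition", "ac_off_conditioning")) {
    res <- run_experiment(p, m, seed = 11)
    expect_true(all(res$state$w_mgb >= 0 & res$state$w_mgb <= 1))
    expect_true(all(res$state$w_ctx >= 0 & res$state$w_ctx <= 1))
  }
})

test_that("drift erodes the tuning-specificity correlation", {
  p <- circuit_params(n_drift_steps = 3000)
  tc <- tuning_ls_correlation_over_time(p, n_subjects = 12, seed = 5)
  expect_gte(abs(tc$r_t0), 0.8)
  expect_lt(abs(tc$r_after_drift), abs(tc$r_t0))

  p0 <- circuit_params(n_drift_steps = 100, drift_amplitude = 0)
  tc0 <- tuning_ls_correlation_over_time(p0, n_subjects = 8, seed = 5)
  expect_equal(tc0$r_t0, tc0$r_after_drift)
})
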