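# heterogeneous per-neuron class shifts (zero-mean across neurons), so the
# decoder must learn which neuron carries which sign
make_pop <- function(n_trials = 40, n_neurons = 20, sep = 0, seed = 1) {
  set.seed(seed)
  y <- rep(c("CS+", "CS-"), each = n_trials / 2)
  x <- matrix(rnorm(n_trials * n_neurons), n_trials, n_neurons)
  shift <- sep * rnorm(n_neurons)
  x[y == "CS+", ] <- sweep(x[y == "CS+", , drop = FALSE], 2, shift, "+")
  colnames(x) <- paste0("n", seq_len(n_neurons))
  population_trials(x, y)
}

test_that("separable populations decode near perfectly, renaming classes is neutral", {
  pop <- make_pop(sep = 4, seed = 2)
  expect_gte(svm_cv_performance(pop, seed = 1), 0.99)

  renamed <- population_trials(pop$x, factor(pop$y, labels = c("B", "A")))
  expect_equal(svm_cv_performance(renamed, seed = 1),
               svm_cv_performance(pop, seed = 1))

  expect_error(population_trials(pop$x, rep("CS+", nrow(pop$x))), "2 classes")
  expect_error(svm_cv_performance(make_pop(n_trials = 10), folds = 10),
               "at least")
})

test_that("label-shuffled populations decode at chance", {
  accs <- sapply(1:15, function(s) {
    pop <- make_pop(n_trials = 50, n_neurons = 30, sep = 3, seed = s)
    set.seed(s + 100)
    shuf <- population_trials(pop$x, sample(pop$y))
    svm_cv_performance(shuf, folds = 5, seed = s)
  })
  expect_lt(abs(mean(accs) - 0.5), 0.06)
})

test_that("min-count neuron resampling matches counts across mice", {
  pops <- list(a = make_pop(n_neurons = 12, seed = 1),
               b = make_pop(n_neurons = 30, seed = 2),
               c = make_pop(n_neurons = 19, seed = 3))
  res <- resampled_metric(pops, function(p) ncol(p$x), n_resamples = 5, seed = 9)
  expect_equal(res$mean, rep(12, 3))
  expect_equal(res$sd, rep(0, 3))
  expect_equal(unique(res$n_neurons_used), 12)

  r1 <- resampled_metric(pops, function(p) mean(p$x), n_resamples = 10, seed = 4)
  r2 <- resampled_metric(pops, function(p) mean(p$x), n_resamples = 10, seed = 4)
  expect_identical(r1, r2)
})

test_that("cross-session transfer shows no deficit on identical data and chance on scrambled neurons", {
  pop <- make_pop(n_trials = 60, n_neurons = 25, sep = 1.2, seed = 5)
  same <- cross_session_svm(pop, pop, colnames(pop$x), seed = 1)
  expect_lt(abs(same$deficit), 0.12)
  expect_gt(same$test_perf, 0.85)

  # permuting feature columns decorrelates the frozen decoder
  defs <- sapply(1:10, function(s) {
    pop <- make_pop(n_trials = 60, n_neurons = 25, sep = 1.2, seed = s)
    set.seed(s)
    scr <- population_trials(pop$x[, sample.int(ncol(pop$x))], pop$y)
    colnames(scr$x) <- colnames(pop$x)
    cross_session_svm(pop, scr, colnames(pop$x), seed = s)$test_perf
  })
  expect_lt(abs(mean(defs) - 0.5), 0.1)

  expect_error(cross_session_svm(pop, pop, c("nope")), "present in both")
})

test_that("cross-session deficit grows with programmed drift", {
  rates <- c(0.02, 0.08, 0.2)
  res <- sapply(rates, function(dr) {
    out <- sapply(1:5, function(seed) {
      cfg <- cohort_config(n_conditioned = 3, n_pseudo = 0,
                           neurons_per_mouse = c(50, 50), n_sessions = 4,
                           drift_rate = dr, seed = seed,
                           discriminability_gradient = rep(0.7, 3))
      co <- generate_cohort(cfg)
      mean(sapply(names(co$mice), function(mid) {
        tr <- cohort_population(co, mid, 1)
        te <- cohort_population(co, mid, 4)
        cross_session_svm(tr, te, colnames(tr$x), seed = seed)$deficit
      }))
    })
    mean(out)
  })
  expect_true(all(diff(res) > 0))
})

test_that("Z_diff similarity behaves as a Pearson correlation over tracked neurons", {
  z <- setNames(runif(10, 0, 3), paste0("n", 1:10))
  expect_equal(zdiff_similarity(z, z), 1)
  expect_error(zdiff_similarity(z[1:2], z[1:2]), ">= 3")

  set.seed(12)
  rs <- sapply(1:10, function(s) {
    set.seed(s)
    a <- setNames(rnorm(200), paste0("n", 1:200))
    b <- setNames(rnorm(200), paste0("n", 1:200))
    zdiff_similarity(a, b)
  })
  expect_true(mean(abs(rs) < 0.15) >= 0.9)
})

test_that("Z_diff similarity declines with session gap on drifting cohorts", {
  sims <- sapply(1:5, function(seed) {
    cfg <- cohort_config(n_conditioned = 3, n_pseudo = 0,
                         neurons_per_mouse = c(50, 50), n_sessions = 5,
                         drift_rate = 0.12, seed = seed,
                         discriminability_gradient = rep(0.7, 3))
    co <- generate_cohort(cfg)
    gap <- function(s2) mean(sapply(names(co$mice), function(mid) {
      a <- session_neuron_stats(co, mid, 1, n_shuffles = 0)
      b <- session_neuron_stats(co, mid, s2, n_shuffles = 0)
      zdiff_similarity(setNames(a$zdiff, a$neuron_id),
                       setNames(b$zdiff, b$neuron_id))
    }))
    c(gap(2), gap(5))
  })
  expect_gt(mean(sims[1, ]), mean(sims[2, ]))
})
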