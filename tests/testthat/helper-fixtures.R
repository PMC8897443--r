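# Small cohort configurations used across test files. Sizes are reduced
# relative to the generator defaults so the suite stays fast; the defaults
# themselves are exercised in the cohort tests.

small_cohort <- function(seed = 1, ...) {
  cohort_config(n_conditioned = 4, n_pseudo = 2,
                neurons_per_mouse = c(30, 30),
                repeats_per_frequency = 20, n_sessions = 2,
                discriminability_gradient = seq(0.2, 0.8, length.out = 4),
                seed = seed, ...)
}

rotation_transform <- function(degrees, shift = c(0, 0)) {
  th <- degrees * pi / 180
  transform_model(matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2), shift)
}

# independent percentile oracle: linear interpolation between order
# statistics at position h = (n - 1) * p + 1
percentile_oracle <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}
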