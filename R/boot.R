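#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties (base `cor` with
#' `method = "spearman"`). Invariant to strictly monotone transforms of
#' either variable.
#'
#' @param x,y Equal-length numeric vectors.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  stats::cor(x, y, method = "spearman")
}

#' Bootstrap confidence interval for a rank correlation
#'
#' Resamples the (x, y) pairs jointly with replacement `n_boot` times and
#' takes the 2.5th and 97.5th percentiles of the bootstrap correlation
#' distribution as the 95% CI. The correlation computed inside the
#' bootstrap defaults to Spearman for consistency with the point estimate;
#' `boot_method = "pearson"` computes Pearson correlations on the
#' resampled data instead. Degenerate resamples (constant x or y) are
#' dropped and counted.
#'
#' @param x,y Paired numeric vectors, `n >= 4`.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Optional integer seed.
#' @param boot_method Correlation flavor inside the bootstrap
#'   (`"spearman"` or `"pearson"`).
#' @param conf Confidence level (default 0.95).
#' @return A list of class `boot_corr`: `r_point` (Spearman point
#'   estimate), `ci_low`, `ci_high`, `boot_distribution`, `n_dropped`.
#' @export
bootstrap_corr_ci <- function(x, y, n_boot = 1000, seed = NULL,
                              boot_method = c("spearman", "pearson"),
                              conf = 0.95) {
  boot_method <- match.arg(boot_method)
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 4L) stop("bootstrap_corr_ci() needs n >= 4")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) return(NA_real_)
    stats::cor(x[idx], y[idx], method = boot_method)
  }, numeric(1))
  dropped <- sum(is.na(boot))
  boot <- boot[!is.na(boot)]
  qs <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)
  structure(list(r_point = spearman(x, y),
                 ci_low = qs[1], ci_high = qs[2],
                 boot_distribution = boot,
                 n_dropped = dropped),
            class = "boot_corr")
}

#' Bootstrap test for a difference between two correlations
#'
#' Compares the correlation of dataset A with that of dataset B by
#' subtracting their bootstrap r distributions: the difference is
#' significant when the 95% CI of the delta distribution excludes zero.
#' When both datasets measure the same subjects (`paired = TRUE`, the
#' default), the same resample indices drive both correlations in each
#' replicate, matching a comparison of two readouts over one cohort;
#' otherwise the two bootstrap distributions are drawn independently.
#'
#' @param xa,ya Paired vectors for dataset A.
#' @param xb,yb Paired vectors for dataset B.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Optional integer seed.
#' @param paired Share resample indices between A and B (requires equal n).
#' @param boot_method Correlation flavor inside the bootstrap.
#' @return A list of class `corr_difference`: `delta_r` (difference of
#'   point estimates), `ci_low`, `ci_high`, `p` (two-sided), and
#'   `delta_distribution`.
#' @export
corr_difference_test <- function(xa, ya, xb, yb, n_boot = 1000, seed = NULL,
                                 paired = TRUE,
                                 boot_method = c("spearman", "pearson")) {
  boot_method <- match.arg(boot_method)
  na <- length(xa); nb <- length(xb)
  stopifnot(length(ya) == na, length(yb) == nb)
  if (na < 4L || nb < 4L) stop("corr_difference_test() needs n >= 4 in both")
  if (paired && na != nb) stop("paired bootstrap requires equal sample sizes")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  one_r <- function(x, y, idx) {
    if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) return(NA_real_)
    stats::cor(x[idx], y[idx], method = boot_method)
  }
  delta <- vapply(seq_len(n_boot), function(b) {
    if (paired) {
      idx <- sample.int(na, na, replace = TRUE)
      one_r(xa, ya, idx) - one_r(xb, yb, idx)
    } else {
      one_r(xa, ya, sample.int(na, na, replace = TRUE)) -
        one_r(xb, yb, sample.int(nb, nb, replace = TRUE))
    }
  }, numeric(1))
  delta <- delta[!is.na(delta)]
  qs <- stats::quantile(delta, c(0.025, 0.975), names = FALSE, type = 7)
  p <- 2 * min(mean(delta <= 0), mean(delta >= 0))
  structure(list(delta_r = spearman(xa, ya) - spearman(xb, yb),
                 ci_low = qs[1], ci_high = qs[2],
                 p = min(p, 1),
                 delta_distribution = delta),
            class = "corr_difference")
}
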