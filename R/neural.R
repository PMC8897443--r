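#' Trial response matrix
#'
#' The atom of the single-neuron analyses: one neuron's scalar evoked
#' responses (mean dF/F_std over the 2 s after tone onset), organised as a
#' frequency x repeat matrix.
#'
#' @param responses Numeric matrix `[n_freq, n_repeat]`.
#' @param frequencies Numeric vector of tone frequencies in Hz, strictly
#'   increasing, one per row.
#' @param neuron_id,session_id Optional identifiers.
#' @return An object of class `trial_response_matrix`.
#' @export
trial_response_matrix <- function(responses, frequencies,
                                  neuron_id = NA, session_id = NA) {
  responses <- as.matrix(responses)
  stopifnot(is.numeric(responses),
            length(frequencies) == nrow(responses),
            all(diff(frequencies) > 0))
  if (ncol(responses) < 2L) {
    stop("trial_response_matrix() needs at least 2 repeats per frequency")
  }
  structure(list(responses = responses,
                 frequencies = as.numeric(frequencies),
                 neuron_id = neuron_id, session_id = session_id),
            class = "trial_response_matrix")
}

#' Baseline-normalized fluorescence around one stimulus presentation
#'
#' Computes dF/F_std for a single presentation: the baseline mean and
#' standard deviation are taken over the 1 s preceding tone onset, and the
#' whole segment (1 s pre to `post_s` post) is returned as
#' `(F - F_baseline) / F_std` -- a per-frame z-score of fluorescence
#' relative to the pre-stimulus baseline.
#'
#' @param f Numeric fluorescence trace (neuropil-corrected).
#' @param frame_rate Sampling rate in Hz.
#' @param onset_s Stimulus onset time in seconds.
#' @param post_s Seconds of trace to return after onset (default 2).
#' @return A list with `z` (numeric vector covering `[-1, post_s]` around
#'   onset), `onset_index` (index of the first post-onset frame within `z`),
#'   and `degenerate` (TRUE when the baseline sd is 0, in which case `z` is
#'   all `NA` and the presentation should be excluded).
#' @export
dff_zscore <- function(f, frame_rate, onset_s, post_s = 2) {
  stopifnot(is.numeric(f), frame_rate > 0)
  onset_fr <- onset_s * frame_rate
  pre_n <- as.integer(round(frame_rate))            # 1 s of baseline
  first_base <- as.integer(floor(onset_fr)) - pre_n + 1L
  last_base <- as.integer(floor(onset_fr))
  last_post <- as.integer(floor(onset_fr + post_s * frame_rate))
  if (first_base < 1L || last_post > length(f)) {
    stop("need >= 1 s pre-onset and >= post_s s post-onset of trace")
  }
  baseline <- f[first_base:last_base]
  f_b <- mean(baseline)
  f_sd <- stats::sd(baseline)
  seg <- f[first_base:last_post]
  if (!is.finite(f_sd) || f_sd == 0) {
    return(list(z = rep(NA_real_, length(seg)),
                onset_index = pre_n + 1L, degenerate = TRUE))
  }
  list(z = (seg - f_b) / f_sd, onset_index = pre_n + 1L, degenerate = FALSE)
}

#' Scalar trial response
#'
#' The response to one tone presentation: the mean dF/F_std over the 2 s
#' following tone onset.
#'
#' @param z Output of [dff_zscore()], or a bare numeric vector already
#'   restricted to the post-onset window.
#' @param frame_rate Required when `z` is a [dff_zscore()] result, to count
#'   2 s of frames.
#' @param window_s Length of the response window in seconds (default 2).
#' @return Scalar mean response (`NA` for degenerate presentations).
#' @export
trial_response <- function(z, frame_rate = NULL, window_s = 2) {
  if (is.list(z)) {
    if (isTRUE(z$degenerate)) return(NA_real_)
    stopifnot(!is.null(frame_rate))
    n_post <- as.integer(round(window_s * frame_rate))
    idx <- z$onset_index - 1L + seq_len(min(n_post, length(z$z) - z$onset_index + 1L))
    return(mean(z$z[idx]))
  }
  mean(z)
}

#' Sound-responsiveness test
#'
#' A neuron is sound responsive if at least one frequency's single-trial
#' responses differ from zero: one-sample t-tests per frequency,
#' Holm-corrected across frequencies, any corrected p < `alpha`.
#' A frequency with zero variance counts as significant when its mean is
#' nonzero (an exact nonzero response) and as non-significant when the mean
#' is zero.
#'
#' @param mat A `trial_response_matrix`.
#' @param alpha Significance level after Holm correction (default 0.05).
#' @return Logical scalar, with attribute `p_corrected` (per-frequency
#'   Holm-adjusted p-values).
#' @export
is_responsive <- function(mat, alpha = 0.05) {
  stopifnot(inherits(mat, "trial_response_matrix"))
  p <- apply(mat$responses, 1, function(r) {
    if (stats::sd(r) == 0) {
      if (mean(r) == 0) 1 else 0
    } else {
      stats::t.test(r, mu = 0)$p.value
    }
  })
  p_adj <- stats::p.adjust(p, method = "holm")
  out <- any(p_adj < alpha)
  attr(out, "p_corrected") <- p_adj
  out
}

#' Frequency response function
#'
#' Mean response to each tone frequency across repeats, with the best
#' frequency (BF: the frequency with the highest mean response; ties break
#' to the lowest frequency) and the sparseness of the tuning curve.
#'
#' @param mat A `trial_response_matrix`.
#' @return An object of class `frequency_response_function` with fields
#'   `mean_response`, `frequencies`, `best_frequency`, `sparseness`.
#' @export
frequency_response_function <- function(mat) {
  stopifnot(inherits(mat, "trial_response_matrix"))
  m <- rowMeans(mat$responses)
  bf <- mat$frequencies[which.max(m)]  # which.max takes the first (lowest) tie
  structure(list(mean_response = m,
                 frequencies = mat$frequencies,
                 best_frequency = bf,
                 sparseness = sparseness(m)),
            class = "frequency_response_function")
}

#' Tuning-curve sparseness
#'
#' Sharpness of a frequency response function on a 0-1 scale:
#' `a = (sum(r)/N)^2 / (sum(r^2)/N)` and `S = (1 - a) / (1 - 1/N)`,
#' where `r` are the per-frequency mean responses and `N` the number of
#' frequencies. A flat positive curve gives S = 0; a one-hot curve gives
#' S = 1. Negative mean responses are kept as-is (no rectification), so S
#' can exceed 1; such values are returned unchanged. An all-zero curve is
#' undefined (0/0) and returns `NA`.
#'
#' @param r Numeric vector of per-frequency mean responses, or a
#'   `frequency_response_function`.
#' @return Scalar sparseness, `NA` when undefined.
#' @export
sparseness <- function(r) {
  if (inherits(r, "frequency_response_function")) r <- r$mean_response
  n <- length(r)
  stopifnot(n >= 2L)
  denom <- sum(r^2) / n
  if (denom == 0) return(NA_real_)
  a <- (sum(r) / n)^2 / denom
  (1 - a) / (1 - 1 / n)
}

#' Single-neuron CS+/CS- discriminability (Z_diff)
#'
#' `Z_diff = |mean(r+) - mean(r-)| / sqrt(sd(r+) * sd(r-))`, where `r+` and
#' `r-` are the single-trial responses to CS+ and CS- and the standard
#' deviations are sample SDs (denominator n - 1). The statistic is invariant
#' to a common affine transform of both samples.
#'
#' @param r_plus,r_minus Numeric vectors of single-trial responses (>= 2
#'   repeats each).
#' @return Non-negative scalar; `NA` when either SD is zero (degenerate
#'   neuron, to be excluded).
#' @export
zdiff <- function(r_plus, r_minus) {
  stopifnot(length(r_plus) >= 2L, length(r_minus) >= 2L)
  s_p <- stats::sd(r_plus)
  s_m <- stats::sd(r_minus)
  if (s_p == 0 || s_m == 0) return(NA_real_)
  abs(mean(r_plus) - mean(r_minus)) / sqrt(s_p * s_m)
}

#' Permutation significance of Z_diff
#'
#' The CS+/CS- labels of the pooled trials are reshuffled `n_shuffles`
#' times (full relabelling of the pooled 2N trials into two groups of the
#' original sizes); the observed Z_diff is significant if it exceeds the
#' 95th percentile of the shuffled scores (strictly greater).
#'
#' @param r_plus,r_minus Numeric trial-response vectors.
#' @param n_shuffles Number of label shuffles (default 250).
#' @param seed Optional integer seed for reproducible shuffles.
#' @param prob Null percentile used as the significance cut (default 0.95).
#' @return A list of class `zdiff_result`: `zdiff`, `null_scores`,
#'   `null_95th`, `significant`. Degenerate inputs (zero SD) give
#'   `zdiff = NA`, `significant = FALSE`.
#' @export
zdiff_significance <- function(r_plus, r_minus, n_shuffles = 250,
                               seed = NULL, prob = 0.95) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  z_obs <- zdiff(r_plus, r_minus)
  pooled <- c(r_plus, r_minus)
  n_p <- length(r_plus)
  null_scores <- vapply(seq_len(n_shuffles), function(i) {
    idx <- sample.int(length(pooled), n_p)
    z <- zdiff(pooled[idx], pooled[-idx])
    if (is.na(z)) 0 else z
  }, numeric(1))
  crit <- unname(stats::quantile(null_scores, prob, type = 7))
  structure(list(zdiff = z_obs,
                 null_scores = null_scores,
                 null_95th = crit,
                 significant = isTRUE(z_obs > crit)),
            class = "zdiff_result")
}

#' Interpolate a frequency response function at an untested frequency
#'
#' Linear interpolation of the mean FRF on the log2-frequency axis, used to
#' estimate responses at the CS frequencies (11.4 and 15 kHz) for sessions
#' where those exact tones were not presented. Stimuli are log-spaced and
#' all tuning distances are reported in octaves, so interpolation is linear
#' in octaves rather than in Hz.
#'
#' @param frf A `frequency_response_function` (or list with
#'   `mean_response` and `frequencies`).
#' @param target_hz Frequency at which to estimate the response; must lie
#'   within the tested range.
#' @return Scalar interpolated mean response.
#' @export
interpolate_at_frequency <- function(frf, target_hz) {
  freqs <- frf$frequencies
  stopifnot(target_hz >= min(freqs), target_hz <= max(freqs))
  stats::approx(x = log2(freqs), y = frf$mean_response,
                xout = log2(target_hz), method = "linear")$y
}

#' Trial responses at a frequency, interpolating when untested
#'
#' Returns the column of single-trial responses at `target_hz` when that
#' frequency was presented; otherwise interpolates each repeat's response
#' between the two flanking frequencies on the log2 axis (repeat k at the
#' flanking tones is treated as one trial).
#'
#' @param mat A `trial_response_matrix`.
#' @param target_hz Target frequency in Hz.
#' @param tol Relative tolerance for matching a tested frequency.
#' @return Numeric vector of per-repeat responses.
#' @export
responses_at_frequency <- function(mat, target_hz, tol = 1e-6) {
  freqs <- mat$frequencies
  hit <- which(abs(freqs - target_hz) <= tol * target_hz)
  if (length(hit) >= 1L) return(mat$responses[hit[1L], ])
  stopifnot(target_hz >= min(freqs), target_hz <= max(freqs))
  hi <- which(freqs > target_hz)[1L]
  lo <- hi - 1L
  w <- (log2(target_hz) - log2(freqs[lo])) / (log2(freqs[hi]) - log2(freqs[lo]))
  (1 - w) * mat$responses[lo, ] + w * mat$responses[hi, ]
}

#' Normalize a frequency response function
#'
#' Divides the mean FRF by its maximum response, so the peak becomes 1 and
#' curves from different sessions are comparable in shape. Scale-invariant:
#' `normalize_frf(k * frf) == normalize_frf(frf)` for `k > 0`.
#'
#' @param frf A `frequency_response_function` or bare numeric vector.
#' @return Same type as the input, with `mean_response` divided by its max.
#' @export
normalize_frf <- function(frf) {
  if (inherits(frf, "frequency_response_function")) {
    m <- frf$mean_response
    mx <- max(m)
    if (mx == 0) stop("cannot normalize an FRF with non-positive maximum")
    frf$mean_response <- m / mx
    return(frf)
  }
  mx <- max(frf)
  if (mx == 0) stop("cannot normalize an FRF with non-positive maximum")
  frf / mx
}

#' Per-frequency percent change between two normalized FRFs
#'
#' `100 * (post - pre) / |pre|` per frequency, computed on normalized FRFs.
#' Frequencies where the pre response is within `eps` of 0 are returned as
#' `NA` (relative change undefined). Note the measure is relative to `pre`,
#' so swapping pre and post does not simply change the sign.
#'
#' @param pre_frf,post_frf `frequency_response_function`s (or numeric
#'   vectors) on the same frequency grid.
#' @param eps Threshold below which the pre response counts as zero.
#' @return Numeric vector of percent changes.
#' @export
frf_percent_change <- function(pre_frf, post_frf, eps = 1e-9) {
  pre <- if (inherits(pre_frf, "frequency_response_function")) pre_frf$mean_response else pre_frf
  post <- if (inherits(post_frf, "frequency_response_function")) post_frf$mean_response else post_frf
  stopifnot(length(pre) == length(post))
  out <- 100 * (post - pre) / abs(pre)
  out[abs(pre) < eps] <- NA_real_
  out
}

#' Octave distance of a best frequency from a reference tone
#'
#' `|log2(bf / reference)|`; with the default reference of 15 kHz (the
#' CS+), the CS- at 11.4 kHz lies 0.396 octaves away.
#'
#' @param bf_hz Best frequency in Hz (vectorized).
#' @param reference_hz Reference frequency (default 15000).
#' @return Non-negative octave distance.
#' @export
bf_distance_octaves <- function(bf_hz, reference_hz = 15000) {
  stopifnot(all(bf_hz > 0), reference_hz > 0)
  abs(log2(bf_hz / reference_hz))
}

#' Resample neurons to a flat best-frequency distribution
#'
#' Resamples (with replacement) an equal number of neurons from each of
#' `n_bins` log-spaced BF bins, so BF distributions can be matched across
#' groups before comparing tuning statistics. Empty bins are skipped with a
#' warning. The per-bin draw count defaults to the largest occupied bin's
#' count.
#'
#' @param bf_hz Numeric vector of per-neuron best frequencies.
#' @param n_bins Number of log-spaced bins spanning the BF range
#'   (default 12).
#' @param per_bin Draws per non-empty bin (default `max` bin occupancy).
#' @param seed Optional integer seed.
#' @return Integer vector of resampled neuron indices (into `bf_hz`).
#' @export
resample_by_bf_bin <- function(bf_hz, n_bins = 12, per_bin = NULL, seed = NULL) {
  stopifnot(length(bf_hz) >= 1L, all(bf_hz > 0))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  lo <- log2(min(bf_hz))
  hi <- log2(max(bf_hz))
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- findInterval(log2(bf_hz), edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  if (any(counts == 0L)) {
    warning(sum(counts == 0L), " empty BF bin(s) skipped")
  }
  if (is.null(per_bin)) per_bin <- max(counts)
  idx <- integer(0)
  for (b in which(counts > 0L)) {
    members <- which(bin == b)
    idx <- c(idx, members[sample.int(length(members), per_bin, replace = TRUE)])
  }
  idx
}
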