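#' Motion index from a stack of grayscale frames
#'
#' The motion index for frame transition `n` is the mean over pixels of
#' `frame[n+1] - frame[n]` (mean grayscale difference between consecutive
#' frames), the conventional FreezeFrame-style movement score. The returned
#' series has one fewer sample than the number of frames.
#'
#' @param frames A list of numeric matrices (grayscale frames), all with
#'   identical dimensions, or a 3-d numeric array `[row, col, frame]`.
#' @return Numeric vector of length `n_frames - 1`.
#' @export
motion_index <- function(frames) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  }
  stopifnot(is.list(frames))
  if (length(frames) < 2L) {
    stop("motion_index() needs at least 2 frames")
  }
  dims <- lapply(frames, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all frames must have identical dimensions")
  }
  vapply(seq_len(length(frames) - 1L), function(n) {
    mean(frames[[n + 1L]] - frames[[n]])
  }, numeric(1))
}

#' Construct a motion trace
#'
#' Bundles a motion-index sample series with its frame rate and labelled
#' stimulus windows (CS+, CS-, baseline).
#'
#' @param samples Numeric vector of motion-index values.
#' @param frame_rate Sampling rate in Hz (default 3.75, the FreezeFrame
#'   video rate).
#' @param windows A data frame with columns `label` (one of `"CS+"`, `"CS-"`,
#'   `"baseline"`), `start_s`, `end_s`. May be empty.
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(samples, frame_rate = 3.75,
                         windows = data.frame(label = character(),
                                              start_s = numeric(),
                                              end_s = numeric())) {
  stopifnot(is.numeric(samples), frame_rate > 0)
  duration <- length(samples) / frame_rate
  if (nrow(windows) > 0) {
    stopifnot(all(windows$start_s >= 0),
              all(windows$end_s > windows$start_s),
              all(windows$end_s <= duration + 1e-9))
  }
  structure(list(samples = as.numeric(samples),
                 frame_rate = frame_rate,
                 windows = windows),
            class = "motion_trace")
}

#' Session freezing threshold
#'
#' The movement threshold below which the animal is scored as freezing:
#' the 12.5th percentile of all motion-index samples in the session.
#' The percentile uses linear interpolation between order statistics
#' (R's default type-7 quantile); the choice of convention is documented
#' and fixed so that scores are reproducible.
#'
#' @param trace A `motion_trace` (or bare numeric vector of samples).
#' @return The threshold (scalar).
#' @export
freezing_threshold <- function(trace) {
  samples <- if (inherits(trace, "motion_trace")) trace$samples else trace
  if (length(samples) < 8L) {
    stop("freezing_threshold() needs at least 8 samples")
  }
  unname(stats::quantile(samples, probs = 0.125, type = 7, names = FALSE))
}

window_sample_idx <- function(trace, start_s, end_s) {
  n <- length(trace$samples)
  # sample k covers time ((k-1)/fr, k/fr]; take samples whose centre falls
  # inside [start, end)
  centres <- (seq_len(n) - 0.5) / trace$frame_rate
  which(centres >= start_s & centres < end_s)
}

#' Fraction of a window spent freezing
#'
#' The fraction of window samples whose motion index falls strictly below
#' the threshold. Ties count as moving, so a constant trace scores 0.
#'
#' @param trace A `motion_trace`.
#' @param window Numeric length-2 `c(start_s, end_s)`, or a single row of
#'   `trace$windows`.
#' @param threshold Movement threshold, typically [freezing_threshold()]
#'   of the session.
#' @return Fraction in `[0, 1]`.
#' @export
percent_freezing <- function(trace, window, threshold) {
  stopifnot(inherits(trace, "motion_trace"))
  if (is.data.frame(window)) window <- c(window$start_s[1], window$end_s[1])
  idx <- window_sample_idx(trace, window[1], window[2])
  if (length(idx) == 0L) {
    stop("window contains no samples")
  }
  mean(trace$samples[idx] < threshold)
}

#' Score all labelled windows of a trace
#'
#' Applies [percent_freezing()] to every window in the trace, using the
#' session-wide [freezing_threshold()]. Long continuous stimuli can be split
#' into `split` equal sub-trials each scored separately (used for animals
#' that received 60-s or 120-s continuous tones instead of 30-s trials).
#'
#' @param trace A `motion_trace` with labelled windows.
#' @param split Number of equal sub-windows each stimulus window is divided
#'   into (default 1 = no splitting; baseline windows are never split).
#' @return A tibble with columns `label`, `start_s`, `end_s`, `freezing`.
#' @export
score_freezing <- function(trace, split = 1L) {
  stopifnot(inherits(trace, "motion_trace"), nrow(trace$windows) > 0)
  thr <- freezing_threshold(trace)
  rows <- list()
  for (i in seq_len(nrow(trace$windows))) {
    w <- trace$windows[i, ]
    k <- if (w$label == "baseline") 1L else as.integer(split)
    edges <- seq(w$start_s, w$end_s, length.out = k + 1L)
    for (j in seq_len(k)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        label = w$label, start_s = edges[j], end_s = edges[j + 1L],
        freezing = percent_freezing(trace, c(edges[j], edges[j + 1L]), thr))
    }
  }
  do.call(rbind, rows)
}

#' Per-trial freezing record
#'
#' @param fr_cs_plus,fr_cs_minus,fr_baseline Numeric vectors of per-trial
#'   freezing fractions in `[0, 1]` for CS+, CS- and baseline periods.
#' @return An object of class `freezing_record`.
#' @export
freezing_record <- function(fr_cs_plus, fr_cs_minus, fr_baseline = numeric()) {
  for (v in list(fr_cs_plus, fr_cs_minus, fr_baseline)) {
    stopifnot(is.numeric(v), all(v >= 0 & v <= 1))
  }
  if (length(fr_cs_plus) == 0L || length(fr_cs_minus) == 0L) {
    stop("freezing_record() requires at least one trial per CS")
  }
  structure(list(fr_cs_plus = fr_cs_plus, fr_cs_minus = fr_cs_minus,
                 fr_baseline = fr_baseline),
            class = "freezing_record")
}

#' Learning specificity
#'
#' LS = mean per-trial freezing fraction to CS+ minus the mean to CS-.
#' Positive values indicate fear specific to the reinforced tone, values
#' near zero indicate generalized (or absent) fear.
#'
#' @param record A `freezing_record`, or a numeric vector of CS+ fractions
#'   (then `fr_cs_minus` must be supplied).
#' @param fr_cs_minus Optional numeric vector when `record` is a vector.
#' @param percent If `TRUE`, return LS on the 0-100 scale.
#' @return Signed scalar in `[-1, 1]` (or `[-100, 100]`).
#' @export
learning_specificity <- function(record, fr_cs_minus = NULL, percent = FALSE) {
  if (inherits(record, "freezing_record")) {
    plus <- record$fr_cs_plus
    minus <- record$fr_cs_minus
  } else {
    plus <- record
    minus <- fr_cs_minus
  }
  if (length(plus) == 0L || length(minus) == 0L) {
    stop("learning_specificity() requires non-empty CS+ and CS- trials")
  }
  ls <- mean(plus) - mean(minus)
  if (percent) 100 * ls else ls
}

#' Classify a mouse as learner or non-learner
#'
#' Two-way ANOVA on the per-trial freezing fractions with factors
#' `stimulus` (CS+/CS-) and `baseline` (stimulus period vs pre-stimulus
#' baseline). A mouse is a learner if the main effect of `baseline` or the
#' `baseline x stimulus` interaction is significant at `alpha`. Mice that
#' freeze to neither CS beyond their baseline are excluded from downstream
#' analyses as non-learners. The design pairs each CS trial with its own
#' 30-s pre-stimulus baseline, giving (with the standard 16 trials per CS)
#' 32 stimulus and 32 baseline observations.
#'
#' @param record A `freezing_record` whose `fr_baseline` holds the baseline
#'   fractions for CS+ trials followed by those for CS- trials (same order
#'   and length as the corresponding CS vectors).
#' @param alpha Significance level (default 0.05).
#' @return A list with `learner` (logical), `p_baseline`,
#'   `p_interaction`, `p_stimulus`.
#' @export
classify_learner <- function(record, alpha = 0.05) {
  stopifnot(inherits(record, "freezing_record"))
  n_p <- length(record$fr_cs_plus)
  n_m <- length(record$fr_cs_minus)
  if (length(record$fr_baseline) != n_p + n_m) {
    stop("fr_baseline must hold one baseline per CS trial (CS+ then CS-)")
  }
  if (n_p < 2L || n_m < 2L) {
    stop("classify_learner() needs at least 2 trials per CS")
  }
  dat <- data.frame(
    freezing = c(record$fr_cs_plus, record$fr_cs_minus, record$fr_baseline),
    stimulus = factor(rep(c("CS+", "CS-", "CS+", "CS-"),
                          times = c(n_p, n_m, n_p, n_m))),
    baseline = factor(rep(c("stimulus", "none"), times = c(n_p + n_m, n_p + n_m)))
  )
  fit <- stats::aov(freezing ~ stimulus * baseline, data = dat)
  tab <- summary(fit)[[1]]
  p <- tab[["Pr(>F)"]]
  rn <- trimws(rownames(tab))
  p_stim <- p[match("stimulus", rn)]
  p_base <- p[match("baseline", rn)]
  p_int <- p[match("stimulus:baseline", rn)]
  list(learner = isTRUE(p_base < alpha) || isTRUE(p_int < alpha),
       p_baseline = p_base, p_interaction = p_int, p_stimulus = p_stim)
}
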