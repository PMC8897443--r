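#' Default tone frequencies
#'
#' Twelve log-spaced frequencies spanning 5-32 kHz with the two grid points
#' nearest the conditioned tones snapped to exactly 11.4 kHz (CS-) and
#' 15 kHz (CS+).
#'
#' @param n_freq Number of tones (default 12).
#' @param range_hz Frequency range (default `c(5000, 32000)`).
#' @param cs_plus_hz,cs_minus_hz Conditioned-tone frequencies.
#' @return Strictly increasing numeric vector of frequencies in Hz.
#' @export
default_frequencies <- function(n_freq = 12, range_hz = c(5000, 32000),
                                cs_plus_hz = 15000, cs_minus_hz = 11400) {
  f <- 2^seq(log2(range_hz[1]), log2(range_hz[2]), length.out = n_freq)
  for (cs in c(cs_minus_hz, cs_plus_hz)) {
    f[which.min(abs(log2(f) - log2(cs)))] <- cs
  }
  f <- sort(f)
  stopifnot(all(diff(f) > 0))
  f
}

#' Configuration of a synthetic imaging cohort
#'
#' The generator emulates the statistical structure of a longitudinal
#' two-photon DFC cohort: per mouse, tens-to-hundreds of neurons with
#' Gaussian log2-frequency tuning, repeated tone presentations with
#' additive trial noise, session-to-session tuning drift, and a programmed
#' per-mouse discriminability gradient that determines both the population
#' CS+/CS- separation and (through a logistic link) the mouse's
#' ground-truth learning specificity.
#'
#' @param n_conditioned,n_pseudo Mice per group (defaults 14 and 9).
#' @param neurons_per_mouse Inclusive range of neuron counts
#'   (default `c(60, 120)`).
#' @param frequencies Tone frequencies in Hz (default
#'   [default_frequencies()]).
#' @param repeats_per_frequency Repeats of each tone per session
#'   (default 25).
#' @param n_sessions Imaging sessions (default 8; sessions 1-4 pre-DFC,
#'   5-8 post-DFC).
#' @param tuning_width_octaves Range of tuning widths for
#'   non-discriminative neurons, in octaves (default `c(0.5, 1.5)`).
#' @param noise_sd Additive trial noise SD in dF/F_std units (default 1).
#' @param shared_gain_sd SD of the log-normal population-wide gain shared
#'   by all neurons on a given trial (default 0.3).
#' @param limiting_noise_sd SD of the shared trial noise along the
#'   population's CS+/CS- signal direction (default 6, in dF/F_std units
#'   distributed over the whole population). These information-limiting
#'   correlations cap population decoding below ceiling independently of
#'   neuron count, as observed in real cortex; without them a linear
#'   decoder over ~100 independently noisy neurons is essentially perfect.
#' @param discriminability_gradient Per-conditioned-mouse gradient values
#'   in `[0, 1]`; default spans `[0, 1]` evenly. Pseudo-conditioned mice
#'   sit at 0.
#' @param ls_noise_sd SD of the noise added to the ground-truth learning
#'   specificity (default 0.05).
#' @param drift_rate Per-session SD of the Gaussian perturbation of each
#'   neuron's best frequency (octaves) and log-gain (default 0.05).
#' @param prop_silent Fraction of simulated neurons with no evoked
#'   response (default 0.2), mirroring the responsiveness filter's job.
#' @param amp_range Evoked-response amplitude range in dF/F_std units
#'   (default `c(2, 5)`).
#' @param cs_plus_hz,cs_minus_hz Conditioned tones (defaults 15000, 11400).
#' @param ls_scale,ls_slope,ls_sep_mid Amplitude, slope and centre of the
#'   logistic link from population CS separation (in noise-SD units) to
#'   ground-truth learning specificity; the defaults place conditioned-mouse
#'   LS roughly in 0.1-0.6 with a spread comparable to real cohorts.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_conditioned = 14, n_pseudo = 9,
                          neurons_per_mouse = c(60, 120),
                          frequencies = default_frequencies(),
                          repeats_per_frequency = 25, n_sessions = 8,
                          tuning_width_octaves = c(0.5, 1.5),
                          noise_sd = 1, shared_gain_sd = 0.3,
                          limiting_noise_sd = 6,
                          discriminability_gradient = NULL,
                          ls_noise_sd = 0.05, drift_rate = 0.05,
                          prop_silent = 0.2, amp_range = c(2, 5),
                          cs_plus_hz = 15000, cs_minus_hz = 11400,
                          ls_scale = 0.65, ls_slope = 4, ls_sep_mid = 1,
                          seed = 1L) {
  if (repeats_per_frequency < 2) stop("repeats_per_frequency must be >= 2")
  stopifnot(all(diff(frequencies) > 0),
            n_conditioned >= 1, n_sessions >= 1,
            length(neurons_per_mouse) == 2,
            neurons_per_mouse[1] <= neurons_per_mouse[2],
            tuning_width_octaves[1] > 0,
            tuning_width_octaves[1] <= tuning_width_octaves[2],
            noise_sd >= 0, shared_gain_sd >= 0, limiting_noise_sd >= 0,
            drift_rate >= 0,
            ls_noise_sd >= 0,
            prop_silent >= 0, prop_silent < 1)
  if (is.null(discriminability_gradient)) {
    discriminability_gradient <-
      if (n_conditioned == 1) 0.5 else seq(0, 1, length.out = n_conditioned)
  }
  stopifnot(length(discriminability_gradient) == n_conditioned,
            all(discriminability_gradient >= 0),
            all(discriminability_gradient <= 1))
  structure(as.list(environment()), class = "cohort_config")
}

# Per-neuron ground-truth tuning for one mouse. A gradient-dependent
# fraction of neurons is CS-tuned: best frequency at exactly CS+ or CS-
# with a narrow width, which is what separates the population responses to
# the two conditioned tones.
draw_neuron_params <- function(config, gradient) {
  n <- if (config$neurons_per_mouse[1] == config$neurons_per_mouse[2]) {
    config$neurons_per_mouse[1]
  } else {
    sample(seq(config$neurons_per_mouse[1], config$neurons_per_mouse[2]), 1)
  }
  # deterministic composition: the gradient fixes the CS-tuned count
  # exactly, so the population separation is not blurred by binomial noise
  p_disc <- 0.1 + 0.6 * gradient
  n_silent <- round(config$prop_silent * n)
  n_cs <- round(p_disc * (n - n_silent))
  kind <- sample(rep(c("silent", "cs", "broad"),
                     c(n_silent, n_cs, n - n_silent - n_cs)))
  lo <- log2(min(config$frequencies))
  hi <- log2(max(config$frequencies))
  bf_oct <- stats::runif(n, lo, hi)
  width <- stats::runif(n, config$tuning_width_octaves[1],
                        config$tuning_width_octaves[2])
  amp <- stats::runif(n, config$amp_range[1], config$amp_range[2])
  is_cs <- kind == "cs"
  bf_oct[is_cs] <- log2(ifelse(stats::runif(sum(is_cs)) < 0.5,
                               config$cs_plus_hz, config$cs_minus_hz))
  width[is_cs] <- stats::runif(sum(is_cs), 0.2, 0.35)
  amp[kind == "silent"] <- 0
  tibble::tibble(neuron_id = sprintf("n%03d", seq_len(n)),
                 kind = kind, bf_oct = bf_oct, width = width, amp = amp)
}

neuron_mean_response <- function(bf_oct, width, amp, freq_hz) {
  amp * exp(-(log2(freq_hz) - bf_oct)^2 / (2 * width^2))
}

# Expected (noise-free) population CS+/CS- separation, in noise-SD units.
population_separation <- function(config, neurons) {
  mu_p <- neuron_mean_response(neurons$bf_oct, neurons$width, neurons$amp,
                               config$cs_plus_hz)
  mu_m <- neuron_mean_response(neurons$bf_oct, neurons$width, neurons$amp,
                               config$cs_minus_hz)
  mean(abs(mu_p - mu_m)) / max(config$noise_sd, 1e-12)
}

#' Generate a synthetic cohort
#'
#' Produces, per mouse: the ground-truth tuning table, per-session
#' response arrays `[neuron, frequency, repeat]` (Gaussian log2-frequency
#' tuning plus additive trial noise, with cumulative per-session drift of
#' best frequencies and gains), a ground-truth learning specificity
#' (logistic in the population CS+/CS- separation for conditioned mice,
#' noise around 0 for pseudo-conditioned mice), and motion-index traces
#' for the four retrieval sessions whose freezing structure realizes that
#' specificity. The output is a deterministic function of the
#' configuration (including its seed).
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `config`,
#'   `manifest` (tibble: mouse_id, group, gradient, ls_true, n_neurons),
#'   and `mice` (named list with `neurons`, `sessions` (list of response
#'   arrays), `motion` (list of retrieval `motion_trace`s), `ls_true`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  groups <- c(rep("conditioned", config$n_conditioned),
              rep("pseudo", config$n_pseudo))
  gradients <- c(config$discriminability_gradient, rep(0, config$n_pseudo))
  mouse_ids <- sprintf("m%02d", seq_along(groups))

  mice <- list()
  manifest <- list()
  f_oct <- log2(config$frequencies)
  for (m in seq_along(mouse_ids)) {
    neurons <- draw_neuron_params(config, gradients[m])
    n <- nrow(neurons)
    sep <- population_separation(config, neurons)
    ls_true <- if (groups[m] == "conditioned") {
      config$ls_scale *
        stats::plogis(config$ls_slope * (sep - config$ls_sep_mid)) +
        stats::rnorm(1, 0, config$ls_noise_sd)
    } else {
      stats::rnorm(1, 0, config$ls_noise_sd)
    }
    ls_true <- min(max(ls_true, -1), 1)

    bf <- neurons$bf_oct
    log_gain <- rep(0, n)
    sessions <- vector("list", config$n_sessions)
    for (s in seq_len(config$n_sessions)) {
      if (s > 1 && config$drift_rate > 0) {
        bf <- bf + stats::rnorm(n, 0, config$drift_rate)
        log_gain <- log_gain + stats::rnorm(n, 0, config$drift_rate)
      }
      mu <- outer(seq_len(n), seq_along(f_oct), function(i, j) {
        neurons$amp[i] * exp(log_gain[i]) *
          exp(-(f_oct[j] - bf[i])^2 / (2 * neurons$width[i]^2))
      })
      n_trial <- length(f_oct) * config$repeats_per_frequency
      gain <- if (config$shared_gain_sd > 0) {
        exp(stats::rnorm(n_trial, 0, config$shared_gain_sd))
      } else {
        rep(1, n_trial)
      }
      # information-limiting noise: shared per-trial fluctuation along the
      # unit vector of the population CS+/CS- mean-response difference
      d_cs <- neurons$amp * exp(log_gain) *
        (exp(-(log2(config$cs_plus_hz) - bf)^2 / (2 * neurons$width^2)) -
           exp(-(log2(config$cs_minus_hz) - bf)^2 / (2 * neurons$width^2)))
      v <- if (sum(d_cs^2) > 0) d_cs / sqrt(sum(d_cs^2)) else d_cs
      lim <- if (config$limiting_noise_sd > 0) {
        outer(v, stats::rnorm(n_trial, 0, config$limiting_noise_sd))
      } else {
        0
      }
      # trial gain is shared across neurons: mu[i, f] scales by gain[f, k]
      arr <- array(rep(mu, config$repeats_per_frequency) *
                     rep(gain, each = n) + lim +
                     stats::rnorm(n * n_trial, 0, config$noise_sd),
                   dim = c(n, length(f_oct), config$repeats_per_frequency),
                   dimnames = list(neurons$neuron_id, NULL, NULL))
      sessions[[s]] <- arr
    }

    motion <- lapply(seq_len(4), function(r) {
      f_minus <- min(max(0.2 + stats::rnorm(1, 0, 0.02), 0.02), 0.9)
      f_plus <- min(max(f_minus + ls_true, 0.02), 0.9)
      generate_motion_trace(retrieval_schedule(f_plus, f_minus))
    })

    mice[[mouse_ids[m]]] <- list(neurons = neurons, sessions = sessions,
                                 motion = motion, ls_true = ls_true,
                                 group = groups[m], gradient = gradients[m])
    manifest[[m]] <- tibble::tibble(mouse_id = mouse_ids[m],
                                    group = groups[m],
                                    gradient = gradients[m],
                                    ls_true = ls_true, n_neurons = n)
  }
  structure(list(config = config, manifest = do.call(rbind, manifest),
                 mice = mice),
            class = "synthetic_cohort")
}

#' Retrieval-session stimulus schedule
#'
#' Four CS+ and four CS- trials of 30 s each, interleaved with 60-s
#' inter-trial intervals, each preceded by a 30-s baseline window. Freezing
#' fractions apply to the CS windows; baseline and inter-trial periods get
#' a low resting fraction. With moderate CS freezing the session-wide
#' freezing occupancy stays below the 12.5% threshold mass, which is the
#' regime where percentile thresholding scores freezing accurately.
#'
#' @param f_plus,f_minus Freezing fractions during CS+ and CS- trials.
#' @param f_base Resting freezing fraction outside stimuli (default 0.05).
#' @param trial_s,iti_s Trial and inter-trial durations in seconds.
#' @return A schedule data frame for [generate_motion_trace()].
#' @export
retrieval_schedule <- function(f_plus, f_minus, f_base = 0.05,
                               trial_s = 30, iti_s = 90) {
  labels <- rep(c("CS+", "CS-"), times = 4)
  rows <- list()
  t <- 0
  for (lab in labels) {
    rows[[length(rows) + 1L]] <- data.frame(
      label = "baseline", start_s = t, end_s = t + 30,
      freeze_fraction = f_base)
    t <- t + 30
    rows[[length(rows) + 1L]] <- data.frame(
      label = lab, start_s = t, end_s = t + trial_s,
      freeze_fraction = if (lab == "CS+") f_plus else f_minus)
    t <- t + trial_s + iti_s
  }
  do.call(rbind, rows)
}

#' Generate a two-state motion-index trace
#'
#' Builds a motion trace from a schedule of windows with target freezing
#' fractions. Within each window the requested fraction of samples (one
#' contiguous bout at a random offset) takes low-motion values; all other
#' samples, including unscheduled time, take moving values. The two state
#' distributions are separated by a gap: the low state lies below 0.25 and
#' the moving state at or above 1, with an atom at the moving-state floor
#' (the quantization floor of a digitized motion index). The atom makes
#' the session's 12.5th-percentile threshold land in the inter-state gap
#' whenever freezing occupies less of the session than the percentile
#' mass, which is the regime where percentile thresholding scores
#' freezing accurately.
#'
#' @param schedule Data frame with columns `start_s`, `end_s`,
#'   `freeze_fraction` and optionally `label` (defaults applied).
#' @param frame_rate Sampling rate in Hz (default 3.75).
#' @param noise_sd Spread of the moving-state motion index (default 0.5).
#' @param seed Optional integer seed.
#' @return A `motion_trace` whose `windows` carry the schedule labels.
#' @export
generate_motion_trace <- function(schedule, frame_rate = 3.75,
                                  noise_sd = 0.5, seed = NULL) {
  if (is.null(schedule) || nrow(schedule) == 0L) {
    stop("generate_motion_trace() needs a non-empty schedule")
  }
  stopifnot(all(schedule$freeze_fraction >= 0),
            all(schedule$freeze_fraction <= 1),
            all(schedule$end_s > schedule$start_s))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  duration <- max(schedule$end_s)
  n <- as.integer(ceiling(duration * frame_rate))
  moving <- pmax(1, stats::rnorm(n, 1 + noise_sd / 2, noise_sd))
  samples <- moving
  centres <- (seq_len(n) - 0.5) / frame_rate
  for (i in seq_len(nrow(schedule))) {
    idx <- which(centres >= schedule$start_s[i] & centres < schedule$end_s[i])
    k <- round(schedule$freeze_fraction[i] * length(idx))
    if (k > 0) {
      offset <- if (k < length(idx)) sample.int(length(idx) - k + 1L, 1) else 1L
      frozen <- idx[offset:(offset + k - 1L)]
      samples[frozen] <- stats::runif(k, 0.02, 0.25)
    }
  }
  lab <- if ("label" %in% names(schedule)) schedule$label else rep("CS+", nrow(schedule))
  motion_trace(samples, frame_rate,
               windows = data.frame(label = lab,
                                    start_s = schedule$start_s,
                                    end_s = schedule$end_s))
}

#' Extract one neuron's trial-response matrix from a cohort
#'
#' @param cohort A `synthetic_cohort`.
#' @param mouse_id,session,neuron Mouse id, session index, and neuron
#'   index or id.
#' @return A [trial_response_matrix()].
#' @export
cohort_trm <- function(cohort, mouse_id, session, neuron) {
  arr <- cohort$mice[[mouse_id]]$sessions[[session]]
  trial_response_matrix(arr[neuron, , ], cohort$config$frequencies,
                        neuron_id = neuron, session_id = session)
}

#' Population trial set for one mouse/session of a cohort
#'
#' Assembles the `[trials x neurons]` matrix of single-trial responses at
#' the CS+ and CS- frequencies, labelled by stimulus, for decoding.
#'
#' @param cohort A `synthetic_cohort`.
#' @param mouse_id,session Mouse id and session index.
#' @return A [population_trials()] with neuron ids as column names.
#' @export
cohort_population <- function(cohort, mouse_id, session) {
  arr <- cohort$mice[[mouse_id]]$sessions[[session]]
  freqs <- cohort$config$frequencies
  i_plus <- which.min(abs(freqs - cohort$config$cs_plus_hz))
  i_minus <- which.min(abs(freqs - cohort$config$cs_minus_hz))
  x_plus <- t(arr[, i_plus, ])   # repeats x neurons
  x_minus <- t(arr[, i_minus, ])
  x <- rbind(x_plus, x_minus)
  colnames(x) <- dimnames(arr)[[1]]
  population_trials(x, rep(c("CS+", "CS-"), each = nrow(x_plus)),
                    mouse_id = mouse_id, session_id = session)
}

#' Write a cohort to plain-text files
#'
#' Persists the manifest and the per-mouse, per-session responses as CSV
#' (long format: mouse_id, session, neuron_id, frequency_hz, repeat,
#' response) under `dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  freqs <- cohort$config$frequencies
  for (mid in names(cohort$mice)) {
    rows <- list()
    for (s in seq_along(cohort$mice[[mid]]$sessions)) {
      arr <- cohort$mice[[mid]]$sessions[[s]]
      d <- dim(arr)
      rows[[s]] <- data.frame(
        mouse_id = mid, session = s,
        neuron_id = rep(dimnames(arr)[[1]], times = d[2] * d[3]),
        frequency_hz = rep(rep(freqs, each = d[1]), times = d[3]),
        rep = rep(seq_len(d[3]), each = d[1] * d[2]),
        response = as.vector(arr))
    }
    utils::write.csv(do.call(rbind, rows),
                     file.path(dir, paste0("responses_", mid, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read back per-session response arrays written by [write_cohort_csv()]
#'
#' @param dir Directory written by [write_cohort_csv()].
#' @param mouse_id Mouse to load.
#' @return A list of `[neuron, frequency, repeat]` arrays, one per session.
#' @export
read_cohort_responses_csv <- function(dir, mouse_id) {
  df <- utils::read.csv(file.path(dir, paste0("responses_", mouse_id, ".csv")))
  lapply(sort(unique(df$session)), function(s) {
    sub <- df[df$session == s, ]
    ids <- unique(sub$neuron_id)
    freqs <- sort(unique(sub$frequency_hz))
    arr <- array(NA_real_, c(length(ids), length(freqs), max(sub$rep)),
                 dimnames = list(ids, NULL, NULL))
    arr[cbind(match(sub$neuron_id, ids),
              match(sub$frequency_hz, freqs),
              sub$rep)] <- sub$response
    arr
  })
}
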