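#' Per-neuron statistics for one mouse/session
#'
#' Responsiveness, frequency response function (best frequency,
#' sparseness), and CS+/CS- discriminability (Z_diff, optionally with the
#' 250-shuffle permutation significance) for every neuron of one session.
#' CS responses are taken at the presented CS frequencies, interpolating
#' on the log2 axis when a CS tone was not presented.
#'
#' @param cohort A `synthetic_cohort`.
#' @param mouse_id,session Mouse id and session index.
#' @param n_shuffles Permutation shuffles for the Z_diff null (default
#'   250; set 0 to skip the permutation test).
#' @param seed Optional integer seed for the shuffles.
#' @return A tibble with one row per neuron: `mouse_id`, `session`,
#'   `neuron_id`, `responsive`, `bf_hz`, `bf_dist_oct`, `sparseness`,
#'   `zdiff`, `zdiff_significant`.
#' @export
session_neuron_stats <- function(cohort, mouse_id, session,
                                 n_shuffles = 250, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  arr <- cohort$mice[[mouse_id]]$sessions[[session]]
  ids <- dimnames(arr)[[1]]
  cfg <- cohort$config
  n <- dim(arr)[1]; n_f <- dim(arr)[2]; n_r <- dim(arr)[3]

  # vectorized one-sample t-tests per frequency + Holm per neuron
  # (numerically identical to is_responsive(); cross-checked in the tests)
  mu <- rowMeans(arr, dims = 2)
  ss <- rowSums(arr^2, dims = 2)
  sdv <- sqrt(pmax(ss - n_r * mu^2, 0) / (n_r - 1))
  tstat <- mu / (sdv / sqrt(n_r))
  p <- 2 * stats::pt(-abs(tstat), df = n_r - 1)
  p[sdv == 0 & mu != 0] <- 0
  p[sdv == 0 & mu == 0] <- 1
  p_holm <- t(apply(p, 1, stats::p.adjust, method = "holm"))
  responsive <- apply(p_holm < 0.05, 1, any)

  bf <- cfg$frequencies[max.col(mu, ties.method = "first")]
  a <- (rowSums(mu) / n_f)^2 / (rowSums(mu^2) / n_f)
  spars <- (1 - a) / (1 - 1 / n_f)

  resp_at <- function(target_hz) {
    hit <- which(abs(cfg$frequencies - target_hz) <= 1e-6 * target_hz)
    if (length(hit) >= 1L) return(arr[, hit[1L], , drop = TRUE])
    t(vapply(seq_len(n), function(i) {
      responses_at_frequency(
        trial_response_matrix(arr[i, , ], cfg$frequencies), target_hz)
    }, numeric(n_r)))
  }
  r_plus <- resp_at(cfg$cs_plus_hz)
  r_minus <- resp_at(cfg$cs_minus_hz)
  m_p <- rowMeans(r_plus); m_m <- rowMeans(r_minus)
  s_p <- sqrt(pmax(rowSums(r_plus^2) - n_r * m_p^2, 0) / (n_r - 1))
  s_m <- sqrt(pmax(rowSums(r_minus^2) - n_r * m_m^2, 0) / (n_r - 1))
  z <- abs(m_p - m_m) / sqrt(s_p * s_m)
  z[s_p == 0 | s_m == 0] <- NA_real_

  sig <- rep(NA, n)
  if (n_shuffles > 0) {
    sig <- vapply(seq_len(n), function(i) {
      if (is.na(z[i])) return(NA)
      zdiff_significance(r_plus[i, ], r_minus[i, ],
                         n_shuffles = n_shuffles)$significant
    }, logical(1))
  }
  tibble::tibble(mouse_id = mouse_id, session = session, neuron_id = ids,
                 responsive = unname(responsive), bf_hz = unname(bf),
                 bf_dist_oct = unname(bf_distance_octaves(bf, cfg$cs_plus_hz)),
                 sparseness = unname(spars), zdiff = unname(z),
                 zdiff_significant = unname(sig))
}

#' Per-neuron statistics for a whole cohort
#'
#' @param cohort A `synthetic_cohort`.
#' @param sessions Session indices (default all).
#' @param n_shuffles Permutation shuffles per neuron (default 0 here:
#'   session-level summaries need only the Z_diff scores themselves).
#' @param seed Optional integer seed.
#' @return Row-bound tibble of [session_neuron_stats()] results.
#' @export
cohort_neuron_stats <- function(cohort, sessions = NULL, n_shuffles = 0,
                                seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (is.null(sessions)) sessions <- seq_len(cohort$config$n_sessions)
  out <- list()
  for (mid in names(cohort$mice)) {
    for (s in sessions) {
      out[[length(out) + 1L]] <-
        session_neuron_stats(cohort, mid, s, n_shuffles = n_shuffles)
    }
  }
  do.call(rbind, out)
}

#' Per-mouse session summaries of discriminability
#'
#' Mean Z_diff over responsive neurons per mouse and session, plus the
#' fraction of significant neurons when significance was computed.
#'
#' @param neuron_stats Output of [cohort_neuron_stats()].
#' @return A tibble: `mouse_id`, `session`, `mean_zdiff`, `n_responsive`,
#'   `frac_significant`.
#' @export
mouse_session_summary <- function(neuron_stats) {
  key <- interaction(neuron_stats$mouse_id, neuron_stats$session, drop = TRUE)
  rows <- lapply(split(neuron_stats, key), function(d) {
    r <- d[d$responsive & is.finite(d$zdiff), ]
    tibble::tibble(mouse_id = d$mouse_id[1], session = d$session[1],
                   mean_zdiff = mean(r$zdiff),
                   n_responsive = nrow(r),
                   frac_significant = if (all(is.na(r$zdiff_significant))) {
                     NA_real_
                   } else {
                     mean(r$zdiff_significant, na.rm = TRUE)
                   })
  })
  out <- do.call(rbind, rows)
  out[order(out$mouse_id, out$session), ]
}

#' Per-mouse SVM decoding performance for selected sessions
#'
#' Cross-validated linear-SVM accuracy per mouse and session, with
#' neuron counts matched across mice by the min-count resampling protocol.
#'
#' @param cohort A `synthetic_cohort`.
#' @param sessions Session indices (default all).
#' @param n_resamples Neuron resamples per mouse/session (default 100).
#' @param folds Cross-validation folds (default 10).
#' @param seed Optional integer seed.
#' @return A tibble: `mouse_id`, `session`, `svm_accuracy`, `svm_sd`,
#'   `n_neurons_used`.
#' @export
cohort_svm_performance <- function(cohort, sessions = NULL, n_resamples = 100,
                                   folds = 10, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (is.null(sessions)) sessions <- seq_len(cohort$config$n_sessions)
  out <- list()
  for (s in sessions) {
    pops <- lapply(names(cohort$mice), function(mid) {
      cohort_population(cohort, mid, s)
    })
    names(pops) <- names(cohort$mice)
    res <- resampled_metric(pops, svm_cv_performance, n_resamples = n_resamples,
                            folds = folds)
    out[[length(out) + 1L]] <-
      tibble::tibble(mouse_id = res$mouse_id, session = s,
                     svm_accuracy = res$mean, svm_sd = res$sd,
                     n_neurons_used = res$n_neurons_used)
  }
  do.call(rbind, out)
}

#' Score the retrieval behavior of a cohort
#'
#' Thresholds each retrieval session's motion trace, scores freezing per
#' trial, and computes learning specificity per mouse and retrieval
#' session.
#'
#' @param cohort A `synthetic_cohort`.
#' @return A tibble: `mouse_id`, `retrieval_session`, `ls`,
#'   `mean_fr_plus`, `mean_fr_minus`.
#' @export
cohort_behavior <- function(cohort) {
  rows <- list()
  for (mid in names(cohort$mice)) {
    traces <- cohort$mice[[mid]]$motion
    for (r in seq_along(traces)) {
      sc <- score_freezing(traces[[r]])
      rec <- freezing_record(sc$freezing[sc$label == "CS+"],
                             sc$freezing[sc$label == "CS-"],
                             sc$freezing[sc$label == "baseline"])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        mouse_id = mid, retrieval_session = r,
        ls = learning_specificity(rec),
        mean_fr_plus = mean(rec$fr_cs_plus),
        mean_fr_minus = mean(rec$fr_cs_minus))
    }
  }
  do.call(rbind, rows)
}

#' Run the full synthetic-cohort analysis
#'
#' Generates a cohort, scores behavior, computes per-neuron and per-mouse
#' discriminability, decodes CS identity per mouse, and correlates the
#' pre-DFC neural measures of the conditioned mice with their learning
#' specificity (bootstrap CIs throughout). Sessions `pre_sessions`
#' (default 1-4) are averaged as the pre-DFC window and `post_sessions`
#' (default 5-8) as post-DFC.
#'
#' @param config A [cohort_config()].
#' @param pre_sessions,post_sessions Session groupings.
#' @param n_resamples SVM neuron resamples (default 20; raise to 100 for
#'   the full protocol).
#' @param n_boot Bootstrap replicates for correlation CIs (default 1000).
#' @param seed Integer seed for the analysis stages (the cohort itself is
#'   seeded by `config$seed`).
#' @return A list of class `pipeline_report`: `manifest`, `behavior`,
#'   `neuron_stats`, `mouse_summary`, `svm`, `mouse_table` (one row per
#'   mouse with pre/post means and LS), and `correlations` (tibble of the
#'   correlation analyses with bootstrap CIs).
#' @export
run_full_pipeline <- function(config, pre_sessions = 1:4,
                              post_sessions = 5:8, n_resamples = 20,
                              n_boot = 1000, seed = 1L) {
  stopifnot(max(pre_sessions) <= config$n_sessions,
            max(post_sessions) <= config$n_sessions)
  cohort <- generate_cohort(config)
  behavior <- cohort_behavior(cohort)
  neuron_stats <- cohort_neuron_stats(cohort, seed = seed)
  mouse_summary <- mouse_session_summary(neuron_stats)
  svm <- cohort_svm_performance(cohort, n_resamples = n_resamples,
                                seed = seed + 1L)

  pre_z <- tapply(mouse_summary$mean_zdiff[mouse_summary$session %in% pre_sessions],
                  mouse_summary$mouse_id[mouse_summary$session %in% pre_sessions], mean)
  post_z <- tapply(mouse_summary$mean_zdiff[mouse_summary$session %in% post_sessions],
                   mouse_summary$mouse_id[mouse_summary$session %in% post_sessions], mean)
  pre_svm <- tapply(svm$svm_accuracy[svm$session %in% pre_sessions],
                    svm$mouse_id[svm$session %in% pre_sessions], mean)
  post_svm <- tapply(svm$svm_accuracy[svm$session %in% post_sessions],
                     svm$mouse_id[svm$session %in% post_sessions], mean)
  ls1 <- behavior$ls[behavior$retrieval_session == 1]
  names(ls1) <- behavior$mouse_id[behavior$retrieval_session == 1]
  ls_mean <- tapply(behavior$ls, behavior$mouse_id, mean)

  ids <- cohort$manifest$mouse_id
  mouse_table <- tibble::tibble(
    mouse_id = ids,
    group = cohort$manifest$group,
    gradient = cohort$manifest$gradient,
    ls_true = cohort$manifest$ls_true,
    ls_retrieval1 = as.numeric(ls1[ids]),
    ls_mean = as.numeric(ls_mean[ids]),
    zdiff_pre = as.numeric(pre_z[ids]),
    zdiff_post = as.numeric(post_z[ids]),
    svm_pre = as.numeric(pre_svm[ids]),
    svm_post = as.numeric(post_svm[ids]))

  cond <- mouse_table[mouse_table$group == "conditioned", ]
  corr_row <- function(label, x, y, boot_seed) {
    bc <- bootstrap_corr_ci(x, y, n_boot = n_boot, seed = boot_seed)
    tibble::tibble(analysis = label, r = bc$r_point,
                   ci_low = bc$ci_low, ci_high = bc$ci_high,
                   n = length(x))
  }
  correlations <- rbind(
    corr_row("zdiff_pre_vs_ls1", cond$zdiff_pre, cond$ls_retrieval1, seed + 2L),
    corr_row("svm_pre_vs_ls1", cond$svm_pre, cond$ls_retrieval1, seed + 3L),
    corr_row("zdiff_pre_vs_svm_pre", cond$zdiff_pre, cond$svm_pre, seed + 4L),
    corr_row("zdiff_post_vs_ls_mean", cond$zdiff_post, cond$ls_mean, seed + 5L),
    corr_row("svm_post_vs_ls_mean", cond$svm_post, cond$ls_mean, seed + 6L))

  structure(list(manifest = cohort$manifest, behavior = behavior,
                 neuron_stats = neuron_stats, mouse_summary = mouse_summary,
                 svm = svm, mouse_table = mouse_table,
                 correlations = correlations),
            class = "pipeline_report")
}
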