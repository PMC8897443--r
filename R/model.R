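#' Parameters of the thalamo-cortico-amygdala circuit model
#'
#' A rate-based model with `n_channels` frequency channels in the auditory
#' thalamus (MGB) and auditory cortex (AC), both projecting to a single
#' basolateral amygdala (BLA) readout. Channel tuning is Gaussian on a
#' circular frequency axis; note the tuning exponent is
#' `-d^2 / (2 * sigma)` with sigma entering *unsquared*, which differs from
#' the conventional `2 sigma^2` form and is kept deliberately. Cortical
#' tuning carries a subtractive broad inhibitory term and a 1/1.8 gain;
#' cortical tuning width drifts over time as a bounded random walk.
#' Projections to BLA are potentiated by a Delta rule gated by the shock.
#'
#' @param n_channels Number of frequency channels (default 10).
#' @param sigma_mgb Thalamic tuning width parameter (default 0.8).
#' @param sigma_ctx_init Initial cortical tuning width: 3 = narrow
#'   (discriminating), 10 = broad (generalizing).
#' @param inhibition_ctx Cortical subtractive inhibition (default 0.9).
#' @param ctx_gain Cortical gain (default 1/1.8).
#' @param alpha Delta-rule learning rate (default 0.1).
#' @param w_init Initial BLA projection weight (default 0.1).
#' @param w_bounds Weight clipping bounds (default `c(0, 1)`).
#' @param drift_amplitude Half-width of the uniform per-step perturbation
#'   of the cortical tuning width (default 0.25).
#' @param sigma_ctx_bounds Bounds of the drifting cortical width
#'   (default `c(4, 20)`; applied from the first drift step onward, so a
#'   narrow initial width of 3 is honoured during conditioning).
#' @param n_conditioning_steps CS+/shock pairings (default 10).
#' @param n_drift_steps Post-conditioning drift steps (default 10000).
#' @param cs_plus_channel,cs_minus_channel 1-based channel indices of the
#'   conditioned tones (defaults 3 and 6).
#' @return A list of class `circuit_params`.
#' @export
circuit_params <- function(n_channels = 10, sigma_mgb = 0.8,
                           sigma_ctx_init = 3, inhibition_ctx = 0.9,
                           ctx_gain = 1 / 1.8, alpha = 0.1, w_init = 0.1,
                           w_bounds = c(0, 1), drift_amplitude = 0.25,
                           sigma_ctx_bounds = c(4, 20),
                           n_conditioning_steps = 10, n_drift_steps = 10000,
                           cs_plus_channel = 3, cs_minus_channel = 6) {
  stopifnot(n_channels >= 2, sigma_mgb > 0, sigma_ctx_init > 0,
            w_bounds[1] < w_bounds[2],
            sigma_ctx_bounds[1] < sigma_ctx_bounds[2],
            n_conditioning_steps >= 1,
            cs_plus_channel >= 1, cs_plus_channel <= n_channels,
            cs_minus_channel >= 1, cs_minus_channel <= n_channels)
  structure(as.list(environment()), class = "circuit_params")
}

#' Initial circuit state
#'
#' @param params A `circuit_params`.
#' @return A list of class `circuit_state` with weight vectors `w_mgb` and
#'   `w_ctx` (initialized at `w_init`) and the current cortical width
#'   `sigma_ctx`.
#' @export
circuit_state <- function(params) {
  stopifnot(inherits(params, "circuit_params"))
  structure(list(w_mgb = rep(params$w_init, params$n_channels),
                 w_ctx = rep(params$w_init, params$n_channels),
                 sigma_ctx = params$sigma_ctx_init),
            class = "circuit_state")
}

#' Circular channel distance
#'
#' Distance between channels `i` and `j` on a ring of `n` channels:
#' `min(|i - j|, n - |i - j|)`, so channel 1 and channel `n` are
#' neighbours.
#'
#' @param i,j 1-based channel indices (vectorized).
#' @param n Number of channels.
#' @return Integer distance(s).
#' @export
circular_distance <- function(i, j, n) {
  d <- abs(i - j)
  pmin(d, n - d)
}

#' Gaussian tuning matrix on the circular frequency axis
#'
#' `T[i, j] = gain * max(exp(-d(i, j)^2 / (2 * sigma)) - inhibition, 0)`
#' with circular distance `d`. The MGB matrix uses gain 1 and no
#' inhibition; the cortical matrix uses gain 1/1.8 and subtractive
#' inhibition 0.9. Sigma enters the exponent unsquared.
#'
#' @param sigma Tuning width parameter (> 0).
#' @param inhibition Subtractive inhibition (default 0).
#' @param gain Multiplicative gain (default 1).
#' @param n Number of channels (default 10).
#' @return An `n x n` numeric matrix.
#' @export
tuning_matrix <- function(sigma, inhibition = 0, gain = 1, n = 10) {
  if (sigma <= 0) stop("sigma must be positive")
  idx <- seq_len(n)
  d <- outer(idx, idx, circular_distance, n = n)
  gain * pmax(exp(-d^2 / (2 * sigma)) - inhibition, 0)
}

mgb_tuning <- function(params) {
  tuning_matrix(params$sigma_mgb, 0, 1, params$n_channels)
}

ctx_tuning <- function(params, sigma_ctx, inhibition = NULL) {
  if (is.null(inhibition)) inhibition <- params$inhibition_ctx
  tuning_matrix(sigma_ctx, inhibition, params$ctx_gain, params$n_channels)
}

#' One-hot tone stimulus
#'
#' @param channel 1-based active channel.
#' @param n Number of channels.
#' @return Numeric vector with 1 at `channel`, 0 elsewhere.
#' @export
tone_stimulus <- function(channel, n = 10) {
  s <- numeric(n)
  s[channel] <- 1
  s
}

#' Forward pass through the circuit
#'
#' The thalamic and cortical equations are mutually dependent (MGB drives
#' AC, AC feeds back to MGB channel-by-channel). The default resolution is
#' a single feedforward-then-feedback pass:
#' `x0 = T_mgb s`, `x_ctx = T_ctx x0`, `x_mgb = x0 + x_ctx`.
#' An optional fixed-point iteration (`recurrent = TRUE`) resolves the
#' loop to tolerance `tol` for sensitivity checks.
#'
#' @param params A `circuit_params`.
#' @param state A `circuit_state` (supplies the current cortical width).
#' @param s Stimulus vector of channel amplitudes.
#' @param ac_off Silence cortex (`x_ctx = 0`, no feedback).
#' @param inhibition_ctx Override of the cortical inhibition (used for the
#'   reduced-inhibition manipulation).
#' @param recurrent Resolve the MGB/AC loop by fixed-point iteration.
#' @param tol,max_iter Fixed-point tolerance and iteration cap.
#' @return A list with `x_mgb` and `x_ctx`.
#' @export
circuit_forward <- function(params, state, s, ac_off = FALSE,
                            inhibition_ctx = NULL, recurrent = FALSE,
                            tol = 1e-8, max_iter = 50) {
  t_mgb <- mgb_tuning(params)
  x0 <- drop(t_mgb %*% s)
  if (ac_off) {
    return(list(x_mgb = x0, x_ctx = numeric(params$n_channels)))
  }
  t_ctx <- ctx_tuning(params, state$sigma_ctx, inhibition_ctx)
  if (!recurrent) {
    x_ctx <- drop(t_ctx %*% x0)
    return(list(x_mgb = x0 + x_ctx, x_ctx = x_ctx))
  }
  x_mgb <- x0
  for (it in seq_len(max_iter)) {
    x_ctx <- drop(t_ctx %*% x_mgb)
    x_new <- x0 + x_ctx
    if (max(abs(x_new - x_mgb)) < tol) {
      return(list(x_mgb = x_new, x_ctx = x_ctx))
    }
    x_mgb <- x_new
  }
  warning("fixed-point iteration did not converge within max_iter")
  list(x_mgb = x_mgb, x_ctx = x_ctx)
}

#' Delta-rule update of the BLA projection weights
#'
#' `w <- clip(w + alpha * x * e, w_bounds)` for both the thalamic and
#' cortical pathways; the shock signal `e` gates learning, so nothing
#' changes on unreinforced presentations.
#'
#' @param params A `circuit_params`.
#' @param state A `circuit_state`.
#' @param x_mgb,x_ctx Pathway activities from [circuit_forward()].
#' @param shock Teaching signal `e` (0 or 1).
#' @return Updated `circuit_state`.
#' @export
delta_update <- function(params, state, x_mgb, x_ctx, shock) {
  stopifnot(shock %in% c(0, 1))
  clip <- function(w) pmin(pmax(w, params$w_bounds[1]), params$w_bounds[2])
  state$w_mgb <- clip(state$w_mgb + params$alpha * x_mgb * shock)
  state$w_ctx <- clip(state$w_ctx + params$alpha * x_ctx * shock)
  state
}

#' Normalized BLA freezing response to a tone
#'
#' BLA activity `y = w_mgb . x_mgb + w_ctx . x_ctx` under auditory input
#' alone, normalized by the maximal activity -- the activity obtained with
#' all weights at 1 under the same readout condition but with the *intact*
#' inhibition -- and saturated at 1, so the output lies in `[0, 1]` and
#' reads as a freezing propensity. `readout = "ac_off"` silences cortex in
#' both the numerator and the normalizer (pharmacological AC inactivation
#' at recall). An `inhibition_ctx` override applies to the numerator only
#' (the optogenetic disinhibition manipulation); the normalizer always
#' keeps the normal inhibitory term, which is why a disinhibited circuit
#' can saturate the freezing response.
#'
#' @param params A `circuit_params`.
#' @param state A `circuit_state` holding the learned weights.
#' @param s Tone stimulus vector.
#' @param readout `"intact"` or `"ac_off"`.
#' @param inhibition_ctx Optional cortical-inhibition override for the
#'   numerator.
#' @return Normalized activity in `[0, 1]`.
#' @export
freezing_response <- function(params, state, s, readout = c("intact", "ac_off"),
                              inhibition_ctx = NULL) {
  readout <- match.arg(readout)
  ac_off <- readout == "ac_off"
  x <- circuit_forward(params, state, s, ac_off = ac_off,
                       inhibition_ctx = inhibition_ctx)
  y <- sum(state$w_mgb * x$x_mgb) + sum(state$w_ctx * x$x_ctx)
  x_norm <- circuit_forward(params, state, s, ac_off = ac_off)
  ymax <- sum(x_norm$x_mgb) + sum(x_norm$x_ctx)   # all weights = 1, intact I
  if (ymax == 0) stop("zero normalizer: no activity reaches BLA")
  min(y / ymax, 1)
}

#' Model learning specificity
#'
#' Freezing response to the CS+ minus the freezing response to the CS-,
#' under the given readout condition.
#'
#' @inheritParams freezing_response
#' @return Signed scalar in `[-1, 1]`.
#' @export
model_learning_specificity <- function(params, state,
                                       readout = c("intact", "ac_off"),
                                       inhibition_ctx = NULL) {
  readout <- match.arg(readout)
  n <- params$n_channels
  freezing_response(params, state, tone_stimulus(params$cs_plus_channel, n),
                    readout, inhibition_ctx) -
    freezing_response(params, state, tone_stimulus(params$cs_minus_channel, n),
                      readout, inhibition_ctx)
}

#' One drift step of the cortical tuning width
#'
#' `sigma_ctx <- clip(sigma_ctx + U(-a, a), bounds)` with
#' `a = drift_amplitude` and bounds `sigma_ctx_bounds`; weights are
#' untouched. Uses the session RNG (seed externally for reproducibility).
#'
#' @param params A `circuit_params`.
#' @param state A `circuit_state`.
#' @return Updated `circuit_state`.
#' @export
drift_step <- function(params, state) {
  a <- params$drift_amplitude
  if (a == 0) return(state)   # no drift: width (and its bounds) untouched
  s <- state$sigma_ctx + stats::runif(1, -a, a)
  state$sigma_ctx <- min(max(s, params$sigma_ctx_bounds[1]),
                         params$sigma_ctx_bounds[2])
  state
}

#' Run one conditioning-plus-drift experiment
#'
#' The conditioning protocol presents the CS+ paired with the shock for
#' `n_conditioning_steps` steps (Delta-rule updates), measures learning
#' specificity immediately, then lets the cortical tuning width drift for
#' `n_drift_steps` steps and measures specificity again. Manipulations:
#'
#' * `control` -- intact circuit throughout.
#' * `reduced_inhibition` -- cortical inhibition halved (0.9 to 0.45) in
#'   the disinhibited circuit (conditioning and the freezing readout's
#'   numerator); the freezing normalizer keeps the intact inhibition, so
#'   the disinhibited response can saturate (the analog of optogenetic
#'   PV-interneuron silencing).
#' * `ac_off_conditioning` -- cortex silenced (no cortical activity or
#'   feedback) during conditioning only.
#' * `ac_off_recall` -- conditioning intact, cortex silenced during the
#'   freezing readout only (muscimol at recall).
#'
#' @param params A `circuit_params`.
#' @param manipulation One of the four conditions above.
#' @param seed Optional integer seed (drives the drift noise).
#' @return A list of class `experiment_result`: `ls_at_conditioning`,
#'   `ls_after_drift`, `state` (post-drift), `manipulation`,
#'   `sigma_ctx_init`.
#' @export
run_experiment <- function(params,
                           manipulation = c("control", "reduced_inhibition",
                                            "ac_off_conditioning",
                                            "ac_off_recall"),
                           seed = NULL) {
  manipulation <- match.arg(manipulation)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  state <- circuit_state(params)
  s_plus <- tone_stimulus(params$cs_plus_channel, params$n_channels)
  cond_inh <- if (manipulation == "reduced_inhibition") params$inhibition_ctx / 2 else NULL
  cond_ac_off <- manipulation == "ac_off_conditioning"
  for (t in seq_len(params$n_conditioning_steps)) {
    x <- circuit_forward(params, state, s_plus, ac_off = cond_ac_off,
                         inhibition_ctx = cond_inh)
    state <- delta_update(params, state, x$x_mgb, x$x_ctx, shock = 1)
  }
  readout <- if (manipulation == "ac_off_recall") "ac_off" else "intact"
  ls_t0 <- model_learning_specificity(params, state, readout, cond_inh)
  for (t in seq_len(params$n_drift_steps)) {
    state <- drift_step(params, state)
  }
  ls_t1 <- model_learning_specificity(params, state, readout, cond_inh)
  structure(list(ls_at_conditioning = ls_t0, ls_after_drift = ls_t1,
                 state = state, manipulation = manipulation,
                 sigma_ctx_init = params$sigma_ctx_init),
            class = "experiment_result")
}

#' Tuning-width / learning-specificity correlation before and after drift
#'
#' Simulates a population of model subjects with heterogeneous initial
#' cortical tuning widths, conditions each, and correlates tuning
#' sharpness (negative width, so sharper = larger) with learning
#' specificity immediately after conditioning and again after the drift
#' period. Drift erodes the correlation: each subject's width random-walks
#' away from its initial value, decoupling post-drift specificity
#' measurements from the width at conditioning.
#'
#' @param params Template `circuit_params` (its `sigma_ctx_init` is
#'   overridden per subject).
#' @param n_subjects Number of model subjects (default 20).
#' @param sigma_range Range of initial widths, spanned evenly
#'   (default `c(3, 10)`).
#' @param seed Integer seed.
#' @return A list with `r_t0`, `r_after_drift` (Spearman correlations of
#'   sharpness with LS at each time point) and the per-subject tibble
#'   `subjects`.
#' @export
tuning_ls_correlation_over_time <- function(params, n_subjects = 20,
                                            sigma_range = c(3, 10),
                                            seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  sigmas <- seq(sigma_range[1], sigma_range[2], length.out = n_subjects)
  seeds <- sample.int(.Machine$integer.max %/% 2, n_subjects)
  rows <- lapply(seq_len(n_subjects), function(i) {
    p <- params
    p$sigma_ctx_init <- sigmas[i]
    res <- run_experiment(p, "control", seed = seeds[i])
    tibble::tibble(sigma_ctx_init = sigmas[i],
                   ls_t0 = res$ls_at_conditioning,
                   ls_after_drift = res$ls_after_drift)
  })
  subjects <- do.call(rbind, rows)
  list(r_t0 = spearman(-subjects$sigma_ctx_init, subjects$ls_t0),
       r_after_drift = spearman(-subjects$sigma_ctx_init,
                                subjects$ls_after_drift),
       subjects = subjects)
}
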