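#' Within-trial dynamics configuration
#'
#' Time constants and trial-event times shared by all models. Time is
#' dimensionless simulation time; one trial spans `[0, t_end]` with the
#' stimulus appearing at `t_stim`, the action executed and the outcome
#' delivered at `t_reward`, and the reward held on for `reward_duration`.
#'
#' @param tau Time constant of the slow units (value, action, eligibility,
#'   reward signal).
#' @param tau_delta Time constant of the prediction-error units; must be
#'   at least `dt` for the explicit Euler scheme to be stable.
#' @param dt Euler integration step.
#' @param t_stim Stimulus onset time.
#' @param t_reward Outcome time (action execution and reward delivery).
#' @param t_end Trial end time.
#' @param reward_duration Length of the reward presentation window. All
#'   parameter updates are confined to `[t_reward, t_reward + reward_duration)`.
#'
#' @return A list of class `hs_dynamics_config`.
#' @examples
#' cfg <- dynamics_config()
#' cfg$dt
#' @export
dynamics_config <- function(tau = 0.05, tau_delta = 0.02, dt = 0.001,
                            t_stim = 1, t_reward = 2, t_end = 3,
                            reward_duration = 0.2) {
  stopifnot(is.numeric(dt), length(dt) == 1)
  if (!is.finite(dt) || dt <= 0) {
    stop("`dt` must be a positive finite number, got ", dt, call. = FALSE)
  }
  if (dt > tau_delta) {
    stop("`dt` (", dt, ") must not exceed `tau_delta` (", tau_delta,
         ") for the Euler scheme to be stable", call. = FALSE)
  }
  if (!(t_stim < t_reward && t_reward < t_end)) {
    stop("trial events must be ordered t_stim < t_reward < t_end", call. = FALSE)
  }
  if (tau <= 0 || tau_delta <= 0 || reward_duration <= 0) {
    stop("`tau`, `tau_delta` and `reward_duration` must be positive", call. = FALSE)
  }
  structure(
    list(tau = tau, tau_delta = tau_delta, dt = dt, t_stim = t_stim,
         t_reward = t_reward, t_end = t_end, reward_duration = reward_duration),
    class = "hs_dynamics_config"
  )
}

#' Parameters of the single-action intensity actor
#'
#' The goal-directed system models reward as Gaussian with mean `q * a * s`
#' and variance `sigma_g`; the habit system models action intensity as
#' Gaussian with mean `h * s` and variance `sigma_h`. Precisions (inverse
#' variances) set each system's weight during planning. Variances never fall
#' below `sigma_floor`.
#'
#' @param q Goal-directed gain (reward per unit action x stimulus).
#' @param h Habit gain (action intensity per unit stimulus).
#' @param sigma_g,sigma_h Variances of the two systems.
#' @param alpha_g,alpha_h Learning rates for `q` and `h`.
#' @param alpha_sg,alpha_sh Learning rates for the two variances.
#' @param sigma_floor Minimum admissible variance.
#'
#' @return A list of class `hs_intensity_params`.
#' @export
intensity_params <- function(q = 0.1, h = 0, sigma_g = 1, sigma_h = 100,
                             alpha_g = 0.05, alpha_h = 0.02,
                             alpha_sg = 0.05, alpha_sh = 0.1,
                             sigma_floor = 0.2) {
  vals <- c(q = q, h = h, sigma_g = sigma_g, sigma_h = sigma_h,
            alpha_g = alpha_g, alpha_h = alpha_h, alpha_sg = alpha_sg,
            alpha_sh = alpha_sh, sigma_floor = sigma_floor)
  if (any(!is.finite(vals))) {
    stop("all intensity-actor parameters must be finite", call. = FALSE)
  }
  if (sigma_g < sigma_floor || sigma_h < sigma_floor) {
    stop("`sigma_g` and `sigma_h` must be at least `sigma_floor` (",
         sigma_floor, ")", call. = FALSE)
  }
  structure(as.list(vals), class = "hs_intensity_params")
}

#' Parameters of the temporal-difference valuation system
#'
#' The valuation system divides post-stimulus time into `n_intervals`
#' intervals of length `interval` and learns one reward weight per interval.
#' Eligibility traces are recycled from one interval to the next with
#' retention `lambda`, allowing credit assignment to earlier intervals.
#'
#' @param w Initial weight vector (one non-negative entry per interval).
#' @param alpha_v Learning rate.
#' @param lambda Fraction of an eligibility trace retained per interval.
#' @param interval Interval length in simulation time.
#' @param n_intervals Number of represented intervals per stimulus.
#' @param n_stimuli Number of stimulus blocks (1 for a single lever; 2 for
#'   lever + conditioned stimulus). The weight vector then has
#'   `n_stimuli * n_intervals` entries.
#'
#' @return A list of class `hs_td_params`.
#' @export
td_params <- function(w = NULL, alpha_v = 0.5, lambda = 0.9,
                      interval = 0.2, n_intervals = 5, n_stimuli = 1) {
  if (lambda < 0 || lambda > 1) {
    stop("`lambda` must lie in [0, 1]", call. = FALSE)
  }
  if (interval <= 0 || n_intervals < 1 || n_stimuli < 1) {
    stop("`interval` must be positive and counts at least 1", call. = FALSE)
  }
  n_w <- n_intervals * n_stimuli
  if (is.null(w)) w <- rep(0.1, n_w)
  if (length(w) != n_w) {
    stop("`w` must have length n_intervals * n_stimuli = ", n_w, call. = FALSE)
  }
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("`w` entries must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(w = as.numeric(w), alpha_v = alpha_v, lambda = lambda,
         interval = interval, n_intervals = as.integer(n_intervals),
         n_stimuli = as.integer(n_stimuli)),
    class = "hs_td_params"
  )
}

#' Parameters of the simplified per-state valuation system
#'
#' Used by the two-action choice model: one scalar weight per discrete
#' state, with asymmetric learning rates for positive and negative
#' valuation prediction errors.
#'
#' @param w Numeric vector, one weight per state.
#' @param alpha_v_pos Learning rate applied when the prediction error is
#'   positive.
#' @param alpha_v_neg Learning rate applied when it is zero or negative.
#'
#' @return A list of class `hs_simple_valuation_params`.
#' @export
simple_valuation_params <- function(w = c(0.1, 0.1), alpha_v_pos = 0.5,
                                    alpha_v_neg = 0.1) {
  if (any(!is.finite(w))) stop("`w` must be finite", call. = FALSE)
  structure(
    list(w = as.numeric(w), alpha_v_pos = alpha_v_pos,
         alpha_v_neg = alpha_v_neg),
    class = "hs_simple_valuation_params"
  )
}

#' Parameters of the two-action choice actor
#'
#' The goal-directed system holds a matrix `Q` of expected rewards
#' (action x state) and the habit system a matrix `H` of habit strengths.
#' During planning the two action intensities compete through mutual
#' inhibition of strength `comp` and are clipped to `[0, 1]`; at the end of
#' planning Gaussian exploration noise of SD `sigma_a_choice` is added and
#' the strongest action is chosen.
#'
#' @param Q 2x2 matrix of expected rewards for (action i, state j).
#' @param H 2x2 matrix of habit strengths, entries in `[0, 1]`.
#' @param sigma_g,sigma_h Variances of the two systems.
#' @param alpha_g,alpha_h Learning rates for `Q` and `H`.
#' @param alpha_sigma Shared learning rate for both variances.
#' @param comp Competition (mutual inhibition) coefficient.
#' @param sigma_a_choice SD of the pre-choice exploration noise.
#' @param sigma_floor Minimum admissible variance.
#' @param habit_rule `"vector"` updates every row of `H` from the full
#'   habit prediction-error vector; `"scalar"` uses the single
#'   chosen-action prediction error with opposite-sign plasticity for the
#'   non-chosen action. The variance update always uses the scalar error.
#'
#' @return A list of class `hs_choice_params`.
#' @export
choice_params <- function(Q = matrix(0.1, 2, 2), H = matrix(0, 2, 2),
                          sigma_g = 1, sigma_h = 1,
                          alpha_g = 0.1, alpha_h = 0.05, alpha_sigma = 0.01,
                          comp = 1, sigma_a_choice = 2, sigma_floor = 0.2,
                          habit_rule = c("vector", "scalar")) {
  habit_rule <- match.arg(habit_rule)
  Q <- as.matrix(Q); H <- as.matrix(H)
  if (!all(dim(Q) == c(2, 2)) || !all(dim(H) == c(2, 2))) {
    stop("`Q` and `H` must be 2x2 matrices", call. = FALSE)
  }
  if (any(H < 0) || any(H > 1)) {
    stop("`H` entries must lie in [0, 1]", call. = FALSE)
  }
  if (sigma_g < sigma_floor || sigma_h < sigma_floor) {
    stop("variances must be at least `sigma_floor`", call. = FALSE)
  }
  structure(
    list(Q = Q, H = H, sigma_g = sigma_g, sigma_h = sigma_h,
         alpha_g = alpha_g, alpha_h = alpha_h, alpha_sigma = alpha_sigma,
         comp = comp, sigma_a_choice = sigma_a_choice,
         sigma_floor = sigma_floor, habit_rule = habit_rule),
    class = "hs_choice_params"
  )
}

#' Fresh within-trial actor state
#'
#' At trial start the planned intensity and both actor prediction errors
#' are zero.
#'
#' @return A list with entries `a`, `delta_g`, `delta_h` and `goal_input`
#'   (the gain-modulated striatal drive `delta_g * q * s`).
#' @export
actor_state <- function() {
  list(a = 0, delta_g = 0, delta_h = 0, goal_input = 0)
}

#' Fresh valuation state with zeroed history buffers
#'
#' Buffers are long enough to read the value one interval back and the
#' eligibility trace one interval plus three slow time constants back, at
#' resolution `cfg$dt`.
#'
#' @param params A [td_params()] object.
#' @param cfg A [dynamics_config()] object.
#' @return A list of class `hs_td_state`.
#' @export
td_state <- function(params, cfg) {
  n_w <- length(params$w)
  lag_v <- as.integer(round(params$interval / cfg$dt))
  lag_e <- as.integer(round((params$interval + 3 * cfg$tau) / cfg$dt))
  structure(
    list(v = 0, delta_v = 0, r_sig = 0, e = rep(0, n_w),
         v_buf = rep(0, lag_v), e_buf = matrix(0, lag_e, n_w),
         lag_v = lag_v, lag_e = lag_e, step = 0L),
    class = "hs_td_state"
  )
}
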