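#' Interval-indicator state vector of the valuation system
#'
#' Post-stimulus time is divided into `n_intervals` intervals of length
#' `interval`; the entry for the current interval is 1 and all others 0.
#' Before the stimulus, or once the represented span is exhausted, the
#' vector is all zero. With several stimulus blocks (`n_stimuli > 1`) the
#' same one-hot pattern is placed in each block listed in `active_blocks`.
#'
#' @param t_since_stimulus Time since stimulus onset (may be negative).
#' @param params A [td_params()] object.
#' @param active_blocks Integer vector of stimulus blocks currently present
#'   (1-based); defaults to block 1.
#' @return A binary vector of length `length(params$w)`.
#' @examples
#' td_state_vector(0.1, td_params())   # c(1, 0, 0, 0, 0)
#' td_state_vector(-0.5, td_params())  # all zero
#' @export
td_state_vector <- function(t_since_stimulus, params, active_blocks = 1L) {
  s_v <- rep(0, length(params$w))
  if (t_since_stimulus < 0) return(s_v)
  idx <- floor(t_since_stimulus / params$interval)
  if (idx >= params$n_intervals) return(s_v)
  for (b in active_blocks) {
    s_v[(b - 1L) * params$n_intervals + idx + 1L] <- 1
  }
  s_v
}

#' One Euler step of the temporal-difference valuation dynamics
#'
#' Advances the value estimate, valuation prediction error, eligibility
#' traces and smoothed reward signal by one step:
#' \deqn{\tau \dot v = w s_v - v}
#' \deqn{\tau_\delta \dot\delta_v = r + v - v(t - I) - \delta_v}
#' \deqn{\tau \dot e = \lambda e(t - I - 3\tau) + s_v - e}
#' \deqn{\tau \dot r = r_0 - r}
#' The prediction error converges to the difference between total reward
#' (`r + v`) and the value expected one interval earlier, as in
#' temporal-difference learning; the eligibility lag skips the transient at
#' interval boundaries. History buffers are zero at trial start (trials are
#' independent episodes) and rolled here.
#'
#' This is the reference implementation; [run_intensity_trial()] uses an
#' identical compiled loop.
#'
#' @param state A [td_state()] object.
#' @param params A [td_params()] object.
#' @param s_v Current indicator vector from [td_state_vector()].
#' @param r0 Current delivered reward (0 outside the reward window).
#' @param cfg A [dynamics_config()] object.
#' @return The advanced state.
#' @export
td_step <- function(state, params, s_v, r0, cfg) {
  k <- state$step
  slot_v <- (k %% state$lag_v) + 1L
  slot_e <- (k %% state$lag_e) + 1L
  v_lag <- state$v_buf[slot_v]
  e_lag <- state$e_buf[slot_e, ]

  d_v  <- sum(params$w * s_v) - state$v
  d_dv <- state$r_sig + state$v - v_lag - state$delta_v
  d_e  <- params$lambda * e_lag + s_v - state$e
  d_r  <- r0 - state$r_sig
  state$e_lag <- e_lag

  # store pre-update values so the slot read `lag` steps later sees time t_k
  state$v_buf[slot_v]   <- state$v
  state$e_buf[slot_e, ] <- state$e

  state$v       <- euler_advance(state$v, d_v, cfg$tau, cfg$dt)
  state$delta_v <- euler_advance(state$delta_v, d_dv, cfg$tau_delta, cfg$dt)
  state$e       <- euler_advance(state$e, d_e, cfg$tau, cfg$dt)
  state$r_sig   <- euler_advance(state$r_sig, d_r, cfg$tau, cfg$dt)
  state$step    <- k + 1L
  state
}

#' One learning step of the valuation weights
#'
#' Weights move in proportion to the valuation prediction error along the
#' lagged eligibility traces (the trace from one interval plus the
#' transient guard earlier), so that the error arising at an interval
#' transition corrects the prediction made in the preceding interval --
#' the standard temporal-difference credit assignment. Pairing the error
#' with the instantaneous trace instead would let the value jump at
#' stimulus onset credit its own interval's weight, a positive feedback
#' with no fixed point. Negative weights are clamped at zero (the desired
#' reward value is never negative).
#'
#' @param params A [td_params()] object.
#' @param state A [td_state()] object holding the current `delta_v` and
#'   the lagged trace `e_lag` (populated by [td_step()]).
#' @param dt Integration step (updates are rate * dt, making learning
#'   robust to the step size).
#' @return `params` with updated `w`.
#' @export
td_learn_step <- function(params, state, dt) {
  e_lag <- if (is.null(state$e_lag)) state$e else state$e_lag
  w <- params$w + dt * params$alpha_v * state$delta_v * e_lag
  params$w <- pmax(w, 0)
  params
}

#' Equilibrium value of the simplified valuation system
#'
#' For the choice model the valuation system keeps one weight per state and
#' its value estimate relaxes with time constant `tau` toward `w . s`; the
#' equilibrium `w . s` is exposed for equilibrium-mode use.
#'
#' @param params A [simple_valuation_params()] object.
#' @param s_bar Binary state vector.
#' @return The equilibrium value estimate.
#' @export
simple_valuation_value <- function(params, s_bar) {
  if (length(s_bar) != length(params$w)) {
    stop("`s_bar` must have length ", length(params$w), call. = FALSE)
  }
  sum(params$w * s_bar)
}

#' Per-trial update of the simplified valuation weights
#'
#' The prediction error is the obtained reward minus the value estimate at
#' the end of the planning phase; the learning rate is asymmetric in its
#' sign. Weights are clamped at zero.
#'
#' @param params A [simple_valuation_params()] object.
#' @param s_bar Binary state vector for the trial.
#' @param r Obtained reward.
#' @param v_end Value estimate at the end of planning.
#' @return A list with updated `params` and the trial's `delta_v`.
#' @export
simple_valuation_update <- function(params, s_bar, r, v_end) {
  delta_v <- r - v_end
  alpha <- if (delta_v > 0) params$alpha_v_pos else params$alpha_v_neg
  params$w <- pmax(params$w + alpha * delta_v * s_bar, 0)
  list(params = params, delta_v = delta_v)
}
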