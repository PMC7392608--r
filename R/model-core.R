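#' Planning-and-learning objective of the intensity actor
#'
#' The log numerator of Bayes' theorem for action intensity: the sum of the
#' (precision-weighted) squared prediction errors of the goal-directed and
#' habit systems plus the log-variance penalties, with the 2*pi constants
#' dropped. Both within-trial planning and between-trial learning ascend
#' this objective.
#'
#' \deqn{F = -\frac{(R - a q s)^2}{2\Sigma_g} - \frac{(a - h s)^2}{2\Sigma_h}
#'       - \tfrac12 \ln \Sigma_g - \tfrac12 \ln \Sigma_h}
#'
#' @param a Action intensity.
#' @param R Total reward (instantaneous reward plus available value).
#' @param s Stimulus intensity.
#' @param params An [intensity_params()] object.
#' @return The scalar objective value.
#' @examples
#' p <- intensity_params(q = 1, h = 1, sigma_g = 1, sigma_h = 1)
#' objective_f(a = 1.5, R = 2, s = 1, p)
#' @export
objective_f <- function(a, R, s, params) {
  if (!all(is.finite(c(a, R, s)))) {
    stop("`a`, `R` and `s` must be finite", call. = FALSE)
  }
  dg <- R - a * params$q * s
  dh <- a - params$h * s
  -dg^2 / (2 * params$sigma_g) - dh^2 / (2 * params$sigma_h) -
    0.5 * log(params$sigma_g) - 0.5 * log(params$sigma_h)
}

#' Closed-form maximum-a-posteriori action intensity
#'
#' The unique maximiser of [objective_f()] over `a`: a precision-weighted
#' combination of the action implied by the goal-directed likelihood
#' (`R / (q s)`) and the habitual action (`h s`). The within-trial planning
#' dynamics converge to this value when the drive is held constant.
#'
#' @inheritParams objective_f
#' @return The MAP action intensity.
#' @examples
#' p <- intensity_params(q = 1, h = 0, sigma_g = 1, sigma_h = 1)
#' map_action(R = 2, s = 1, p)  # 1
#' @export
map_action <- function(R, s, params) {
  qs <- params$q * s
  denom <- qs^2 / params$sigma_g + 1 / params$sigma_h
  if (denom <= 0 || !is.finite(denom)) {
    stop("no unique maximiser: degenerate precision (q*s = 0 with ",
         "infinite habit variance)", call. = FALSE)
  }
  (qs * R / params$sigma_g + params$h * s / params$sigma_h) / denom
}

#' One explicit Euler step
#'
#' Advances `x` by `(dt / tau) * deriv`. Fixed-step, non-adaptive: the
#' integration scheme used throughout the simulator.
#'
#' @param x Current value (scalar or vector).
#' @param deriv Time derivative scaled by `tau` (i.e. the right-hand side
#'   of `tau * dx/dt = deriv`).
#' @param tau Time constant.
#' @param dt Step size.
#' @return The advanced value.
#' @export
euler_advance <- function(x, deriv, tau, dt) {
  stopifnot(dt > 0, tau > 0)
  x + (dt / tau) * deriv
}
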