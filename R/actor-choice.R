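#' One Euler step of the two-action planning dynamics
#'
#' Competitive gradient dynamics on the two action intensities:
#' \deqn{\tau_\delta \dot\delta_g = r + v - \bar a^T Q \bar s - \Sigma_g \delta_g}
#' \deqn{\tau \dot a_i = \delta_g (Q\bar s)_i + ((H\bar s)_i - a_i)/\Sigma_h
#'       - c\, a_{j \ne i}}
#' followed by clipping each intensity to `[0, 1]`. The mutual-inhibition
#' term implements the prior that only one action deviates from zero.
#'
#' This is the reference implementation; [run_choice_trial()] uses an
#' identical compiled loop.
#'
#' @param a_vec Current intensities (length 2, entries in `[0, 1]`).
#' @param delta_g Current goal-directed prediction error.
#' @param params A [choice_params()] object.
#' @param s_bar Binary state vector (length 2).
#' @param v Valuation output.
#' @param r_sig Smoothed reward signal (0 during planning).
#' @param cfg A [dynamics_config()] object.
#' @return A list with advanced `a_vec` and `delta_g`.
#' @export
choice_plan_step <- function(a_vec, delta_g, params, s_bar, v, r_sig = 0,
                             cfg = dynamics_config()) {
  Qs <- as.numeric(params$Q %*% s_bar)
  Hs <- as.numeric(params$H %*% s_bar)
  d_dg <- r_sig + v - sum(a_vec * Qs) - params$sigma_g * delta_g
  d_a <- delta_g * Qs + (Hs - a_vec) / params$sigma_h -
    params$comp * rev(a_vec)
  delta_g <- euler_advance(delta_g, d_dg, cfg$tau_delta, cfg$dt)
  a_vec <- euler_advance(a_vec, d_a, cfg$tau, cfg$dt)
  a_vec <- pmin(pmax(a_vec, 0), 1)
  if (any(!is.finite(c(a_vec, delta_g)))) {
    stop("integration diverged in choice planning", call. = FALSE)
  }
  list(a_vec = a_vec, delta_g = delta_g)
}

#' Choose an action from the planned intensities
#'
#' Independent Gaussian exploration noise is added to each intensity and
#' the strongest entry wins; the returned action vector is binarised (1
#' for the winner, 0 otherwise). Ties break toward the lower index.
#'
#' @param a_vec Intensities at the end of planning (length 2).
#' @param sigma_a_choice Exploration noise SD.
#' @param eps Standard-normal draws (length 2); default fresh draws from
#'   the session RNG.
#' @return A list with `choice` (1 or 2) and the binarised `a_vec`.
#' @export
choose <- function(a_vec, sigma_a_choice, eps = rnorm(2)) {
  stopifnot(length(a_vec) == 2)
  noisy <- a_vec + sigma_a_choice * eps
  i <- which.max(noisy)  # which.max breaks ties toward the lower index
  out <- c(0, 0)
  out[i] <- 1
  list(choice = i, a_vec = out)
}

#' Equilibrium prediction errors at the outcome
#'
#' Outcome-phase dynamics are not integrated; the prediction errors are
#' evaluated at their fixed points with the binarised action vector. After
#' the outcome no further reward is expected, so the valuation term drops
#' out of the goal-directed error. The habit error is the scalar
#' chosen-action form used by the single dopaminergic population.
#'
#' @param params A [choice_params()] object.
#' @param s_bar Binary state vector.
#' @param a_binary One-hot action vector from [choose()].
#' @param r Delivered reward.
#' @return A list with `delta_g` and `delta_h`.
#' @export
equilibrium_errors <- function(params, s_bar, a_binary, r) {
  stopifnot(sum(a_binary) == 1)
  i <- which.max(a_binary)
  Qs <- as.numeric(params$Q %*% s_bar)
  Hs <- as.numeric(params$H %*% s_bar)
  delta_g <- (r - sum(a_binary * Qs)) / params$sigma_g
  delta_h <- a_binary[i] - Hs[i]
  list(delta_g = delta_g, delta_h = delta_h)
}

#' Per-trial learning of the choice-actor parameters
#'
#' The reward matrix receives the three-factor update
#' `Q[i, j] <- Q[i, j] + alpha_g * delta_g * a_i * s_j` (non-zero only for
#' the chosen action and current state). The habit matrix is updated for
#' all actions: under the default vector rule each row moves toward the
#' binarised action (`delta H[k, j] = alpha_h (a_k - (H s)_k) s_j`); under
#' the scalar approximation the chosen row increases with the scalar habit
#' error while the other rows are depressed in proportion to their own
#' strength. Variances follow the same rescaled gradients as the intensity
#' model, with the scalar habit error, and are floored; `H` is clipped to
#' `[0, 1]`.
#'
#' @param params A [choice_params()] object.
#' @param s_bar Binary state vector.
#' @param a_binary One-hot action vector.
#' @param delta_g,delta_h Equilibrium errors from [equilibrium_errors()].
#' @return Updated parameters.
#' @export
choice_learn <- function(params, s_bar, a_binary, delta_g, delta_h) {
  i <- which.max(a_binary)
  params$Q <- params$Q + params$alpha_g * delta_g * outer(a_binary, s_bar)
  if (params$habit_rule == "vector") {
    dh_vec <- a_binary - as.numeric(params$H %*% s_bar)
    params$H <- params$H + params$alpha_h * outer(dh_vec, s_bar)
  } else {
    upd <- matrix(0, 2, 2)
    upd[i, ] <- params$alpha_h * delta_h * s_bar
    k <- setdiff(1:2, i)
    upd[k, ] <- -params$alpha_h * delta_h * params$H[k, ] * s_bar
    params$H <- params$H + upd
  }
  params$H <- pmin(pmax(params$H, 0), 1)
  sg <- params$sigma_g +
    params$alpha_sigma * (params$sigma_g^2 * delta_g^2 - params$sigma_g)
  sh <- params$sigma_h + params$alpha_sigma * (delta_h^2 - params$sigma_h)
  params$sigma_g <- max(sg, params$sigma_floor)
  params$sigma_h <- max(sh, params$sigma_floor)
  params
}

#' Initial planning drive of the two actions
#'
#' The drive each action receives at the start of planning (intensities
#' still zero): the goal-directed input `R (Q s)_i / Sigma_g * (Q s)_i`
#' arises from the prediction error at zero intensity (`delta_g = R /
#' Sigma_g`) and the habit input is `(H s)_i / Sigma_h`. The action with
#' the larger initial drive is the likely winner of the competition.
#'
#' @param params A [choice_params()] object.
#' @param s_bar Binary state vector.
#' @param R Total reward sought (valuation output during planning).
#' @return A numeric drive per action.
#' @export
initial_drive <- function(params, s_bar, R) {
  Qs <- as.numeric(params$Q %*% s_bar)
  Hs <- as.numeric(params$H %*% s_bar)
  (R / params$sigma_g) * Qs + Hs / params$sigma_h
}

#' Simulate one trial of the two-action choice model
#'
#' Planning runs from stimulus onset to the choice time via the
#' competitive dynamics; exploration noise then selects an action, the
#' environment returns a reward, and the valuation and actor parameters
#' are updated once per trial using equilibrium prediction errors.
#'
#' @param params A [choice_params()] object.
#' @param valuation A [simple_valuation_params()] object.
#' @param s_bar Binary state vector for the trial.
#' @param reward_fn Function `(choice, s_bar, eps_r)` returning the
#'   delivered reward.
#' @param cfg A [dynamics_config()] object; planning spans
#'   `[t_stim, t_reward)`.
#' @param eps_r Standard-normal draw for reward noise.
#' @param eps_choice Standard-normal draws (length 2) for choice noise.
#' @param depleted Clamp the goal-directed error during planning.
#' @param learn Apply the per-trial parameter updates.
#' @param record Keep the planning trajectory.
#' @return A list with updated `params` and `valuation`, the `choice`,
#'   `reward`, end-of-planning intensities `a_plan`, `v_end`, equilibrium
#'   errors, planning-phase maxima of the prediction errors, and
#'   optionally a trajectory tibble.
#' @export
run_choice_trial <- function(params, valuation, s_bar, reward_fn,
                             cfg = dynamics_config(), eps_r = rnorm(1),
                             eps_choice = rnorm(2), depleted = FALSE,
                             learn = TRUE, record = FALSE) {
  n_steps <- as.integer(round((cfg$t_reward - cfg$t_stim) / cfg$dt))
  v_eq <- simple_valuation_value(valuation, s_bar)
  plan <- choice_plan_cpp(
    Qs = as.numeric(params$Q %*% s_bar), Hs = as.numeric(params$H %*% s_bar),
    sg = params$sigma_g, sh = params$sigma_h, comp = params$comp,
    v_eq = v_eq, tau = cfg$tau, tau_delta = cfg$tau_delta, dt = cfg$dt,
    n_steps = n_steps, depleted = depleted, record = record
  )
  sel <- choose(plan$a, params$sigma_a_choice, eps_choice)
  r <- reward_fn(sel$choice, s_bar, eps_r)
  errs <- equilibrium_errors(params, s_bar, sel$a_vec, r)
  delta_v <- r - plan$v_end
  if (learn) {
    upd <- simple_valuation_update(valuation, s_bar, r, plan$v_end)
    valuation <- upd$params
    delta_v <- upd$delta_v
    params <- choice_learn(params, s_bar, sel$a_vec, errs$delta_g,
                           errs$delta_h)
  }
  traj <- NULL
  if (record) {
    traj <- tibble::as_tibble(as.data.frame(plan$trajectory))
    names(traj) <- c("t", "a1", "a2", "delta_g", "goal_input_1",
                     "habit_input_1", "v")
    traj$t <- traj$t + cfg$t_stim
  }
  list(params = params, valuation = valuation, choice = sel$choice,
       reward = r, a_plan = plan$a, v_end = plan$v_end,
       delta_g = errs$delta_g, delta_h = errs$delta_h, delta_v = delta_v,
       max_dg_plan = plan$max_dg, max_dh_plan = plan$max_dh,
       trajectory = traj)
}
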