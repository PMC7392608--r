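#' Reward environment specification
#'
#' @param type `"tanh"`: saturating reward minus effort cost,
#'   `r = 5 tanh(3a/5) - a` plus Gaussian noise; `"cost"`: extinction
#'   testing, `r = -a` (effort only, no noise); `"fixed"`: a fixed reward
#'   magnitude plus Gaussian noise (classical conditioning).
#' @param sigma_r SD of the reward noise (ignored for `"cost"`).
#' @param value Reward magnitude for `"fixed"`.
#' @return A list of class `hs_reward_env`.
#' @export
reward_env <- function(type = c("tanh", "cost", "fixed"), sigma_r = 0.5,
                       value = 1) {
  type <- match.arg(type)
  structure(list(type = type, sigma_r = sigma_r, value = value),
            class = "hs_reward_env")
}

#' Saturating reward schedule
#'
#' Mean reward as a function of executed action intensity,
#' `r = 5 tanh(3 a / 5) - a`: reward saturates with intensity while effort
#' cost grows linearly, so the mean peaks at an intermediate intensity
#' (about 1.91, where the mean reward is about 2.17).
#'
#' @param a_exec Executed action intensity (vectorised).
#' @param sigma_r Reward noise SD.
#' @param eps Standard-normal noise draw(s); defaults to fresh draws from
#'   the session RNG. Pass 0 for the noise-free mean.
#' @return Delivered reward.
#' @examples
#' env_tanh(2, eps = 0)  # 5 * tanh(1.2) - 2
#' @export
env_tanh <- function(a_exec, sigma_r = 0.5, eps = rnorm(length(a_exec))) {
  5 * tanh(3 * a_exec / 5) - a_exec + sigma_r * eps
}

env_reward <- function(env, a_exec, eps) {
  switch(env$type,
    tanh  = env_tanh(a_exec, env$sigma_r, eps),
    cost  = -a_exec,
    fixed = env$value + env$sigma_r * eps
  )
}

#' One Euler step of the intensity actor's planning dynamics
#'
#' Advances the two actor prediction errors and the planned intensity:
#' \deqn{\tau_\delta \dot\delta_g = r + v - a q s - \Sigma_g \delta_g}
#' \deqn{\tau_\delta \dot\delta_h = a - h s - \delta_h}
#' \deqn{\tau \dot a = \delta_g q s + (h s - a)/\Sigma_h}
#' The goal-directed error relaxes to `(R - a q s) / Sigma_g` (its gain
#' encodes the system's precision) and the habit error to `a - h s`. Under
#' dopamine depletion both errors are clamped to zero, so the intensity is
#' driven by the habit term alone.
#'
#' @param actor An [actor_state()] list.
#' @param params An [intensity_params()] object.
#' @param s Stimulus intensity seen by the actor.
#' @param r_sig Smoothed reward signal.
#' @param v Valuation output (available reward).
#' @param cfg A [dynamics_config()] object.
#' @param depleted Clamp all dopaminergic signals to zero.
#' @param freeze_a Hold the intensity fixed (used after execution).
#' @return The advanced actor state.
#' @export
plan_step <- function(actor, params, s, r_sig, v, cfg, depleted = FALSE,
                      freeze_a = FALSE) {
  if (!all(is.finite(c(actor$a, actor$delta_g, actor$delta_h)))) {
    stop("integration diverged: non-finite actor state", call. = FALSE)
  }
  d_dg <- r_sig + v - actor$a * params$q * s - params$sigma_g * actor$delta_g
  d_dh <- actor$a - params$h * s - actor$delta_h
  d_a  <- actor$delta_g * params$q * s + (params$h * s - actor$a) / params$sigma_h

  actor$delta_g <- euler_advance(actor$delta_g, d_dg, cfg$tau_delta, cfg$dt)
  actor$delta_h <- euler_advance(actor$delta_h, d_dh, cfg$tau_delta, cfg$dt)
  if (!freeze_a) actor$a <- euler_advance(actor$a, d_a, cfg$tau, cfg$dt)
  if (depleted) {
    actor$delta_g <- 0
    actor$delta_h <- 0
  }
  actor$goal_input <- actor$delta_g * params$q * s
  actor
}

#' Execute a planned action with motor noise
#'
#' @param planned Planned intensity at execution time.
#' @param sigma_a Motor noise SD.
#' @param eps Standard-normal draw; defaults to a fresh draw from the
#'   session RNG.
#' @return Executed intensity.
#' @export
execute_action <- function(planned, sigma_a, eps = rnorm(1)) {
  stopifnot(sigma_a >= 0)
  planned + sigma_a * eps
}

#' One learning step of the intensity-actor parameters
#'
#' Three-factor updates gated by the dopaminergic prediction errors,
#' applied only during the reward window with the executed intensity as
#' the postsynaptic factor:
#' \deqn{\Delta q = dt\,\alpha_g \delta_g a s, \quad
#'       \Delta h = dt\,\alpha_h \delta_h s}
#' \deqn{\Delta\Sigma_g = dt\,\alpha_{\Sigma g}(\Sigma_g^2\delta_g^2-\Sigma_g),
#'       \quad \Delta\Sigma_h = dt\,\alpha_{\Sigma h}(\delta_h^2-\Sigma_h)}
#' The variance gradients are rescaled by the squared variances (which does
#' not move their fixed points); both variances are floored at
#' `sigma_floor`.
#'
#' @param params An [intensity_params()] object.
#' @param s Stimulus intensity.
#' @param a_exec Executed action intensity.
#' @param actor Actor state holding the current prediction errors.
#' @param dt Integration step.
#' @return Updated parameters.
#' @export
learn_step <- function(params, s, a_exec, actor, dt) {
  dg <- actor$delta_g
  dh <- actor$delta_h
  q  <- params$q + dt * params$alpha_g * dg * a_exec * s
  h  <- params$h + dt * params$alpha_h * dh * s
  sg <- params$sigma_g + dt * params$alpha_sg * (params$sigma_g^2 * dg^2 - params$sigma_g)
  sh <- params$sigma_h + dt * params$alpha_sh * (dh^2 - params$sigma_h)
  params$q <- q
  params$h <- h
  params$sigma_g <- max(sg, params$sigma_floor)
  params$sigma_h <- max(sh, params$sigma_floor)
  params
}

#' Simulate one trial of the intensity model
#'
#' Runs the full within-trial loop: valuation and actor dynamics from trial
#' start, stimulus onset at `cfg$t_stim`, execution with motor noise and
#' outcome delivery at `cfg$t_reward`. The valuation system learns
#' continuously; actor learning is confined to the reward window. The planned intensity is the value of `a` at
#' execution time, before motor noise; afterwards the intensity is held at
#' the executed value so that learning evaluates the prediction errors at
#' the action actually emitted.
#'
#' @param params An [intensity_params()] object.
#' @param td A [td_params()] object.
#' @param cfg A [dynamics_config()] object.
#' @param env A [reward_env()] object.
#' @param sigma_a Motor noise SD.
#' @param eps_r,eps_a Standard-normal draws for reward and motor noise;
#'   default to fresh draws (in that order) from the session RNG.
#' @param depleted Simulate dopamine depletion: all prediction errors
#'   (`delta_v`, `delta_g`, `delta_h`) clamped to zero.
#' @param learn_valuation Update the valuation weights (the critic learns
#'   continuously throughout the trial).
#' @param learn_actor Update the actor parameters during the reward
#'   window.
#' @param actor_on Engage the actor (FALSE for pure classical
#'   conditioning: no stimulus to the actor, no execution, reward as
#'   scheduled by `env`).
#' @param active_blocks Stimulus blocks present on this trial (see
#'   [td_state_vector()]).
#' @param record Keep the full per-step trajectory.
#' @param engine `"cpp"` (compiled loop) or `"r"` (reference
#'   implementation built from the exported step functions; identical
#'   results, much slower).
#' @return A list with updated `params` and `td`, the `planned` and
#'   `executed` intensities, the delivered `reward`, signed per-trial
#'   maxima of the three prediction errors, `delta_h_exec` (habit error at
#'   the end of the reward window) and, if `record`, a tibble `trajectory`
#'   with columns t, a, delta_v, delta_g, delta_h, v, r_sig, goal_input.
#' @export
run_intensity_trial <- function(params, td, cfg = dynamics_config(),
                                env = reward_env("tanh"), sigma_a = 1,
                                eps_r = rnorm(1), eps_a = rnorm(1),
                                depleted = FALSE, learn_valuation = TRUE,
                                learn_actor = TRUE,
                                actor_on = TRUE, active_blocks = 1L,
                                record = FALSE,
                                engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (engine == "cpp") {
    out <- intensity_trial_cpp(
      w = td$w, n_intervals = td$n_intervals,
      active_blocks = as.integer(active_blocks) - 1L,
      q = params$q, h = params$h, sg = params$sigma_g, sh = params$sigma_h,
      tau = cfg$tau, tau_delta = cfg$tau_delta, dt = cfg$dt,
      t_stim = cfg$t_stim, t_reward = cfg$t_reward, t_end = cfg$t_end,
      reward_duration = cfg$reward_duration, interval = td$interval,
      lambda = td$lambda, alpha_v = td$alpha_v,
      alpha_g = params$alpha_g, alpha_h = params$alpha_h,
      alpha_sg = params$alpha_sg, alpha_sh = params$alpha_sh,
      sigma_floor = params$sigma_floor,
      env_type = match(env$type, c("tanh", "cost", "fixed")) - 1L,
      sigma_r = env$sigma_r, reward_value = env$value,
      sigma_a = sigma_a, eps_r = eps_r, eps_a = eps_a,
      depleted = depleted, learn_valuation = learn_valuation,
      learn_actor = learn_actor, actor_on = actor_on, record = record
    )
  } else {
    out <- intensity_trial_r(params, td, cfg, env, sigma_a, eps_r, eps_a,
                             depleted, learn_valuation, learn_actor,
                             actor_on, as.integer(active_blocks), record)
  }
  params$q <- out$q
  params$h <- out$h
  params$sigma_g <- out$sg
  params$sigma_h <- out$sh
  td$w <- out$w
  traj <- NULL
  if (record) {
    traj <- tibble::as_tibble(as.data.frame(out$trajectory))
    names(traj) <- c("t", "a", "delta_v", "delta_g", "delta_h", "v",
                     "r_sig", "goal_input")
  }
  list(params = params, td = td, planned = out$planned,
       executed = out$executed, reward = out$reward,
       max_delta_v = out$max_dv, max_delta_g = out$max_dg,
       max_delta_h = out$max_dh, delta_h_exec = out$dh_exec,
       trajectory = traj)
}

# Reference trial loop assembled from the exported step operations.
# Mirrors the compiled loop step for step; used to validate it in tests.
intensity_trial_r <- function(params, td, cfg, env, sigma_a, eps_r, eps_a,
                              depleted, learn_valuation, learn_actor,
                              actor_on, active_blocks, record) {
  n_steps <- as.integer(round(cfg$t_end / cfg$dt))
  k_stim  <- as.integer(round(cfg$t_stim / cfg$dt))
  k_rew   <- as.integer(round(cfg$t_reward / cfg$dt))
  k_rend  <- as.integer(round((cfg$t_reward + cfg$reward_duration) / cfg$dt))

  vstate <- td_state(td, cfg)
  actor  <- actor_state()
  planned <- 0; executed <- 0; r_trial <- 0
  max_dv <- -Inf; max_dg <- -Inf; max_dh <- -Inf; dh_exec <- 0
  traj <- if (record) matrix(0, n_steps, 8) else NULL

  for (k in seq_len(n_steps) - 1L) {
    t <- k * cfg$dt
    s <- if (k >= k_stim && actor_on) 1 else 0
    s_v <- td_state_vector(t - cfg$t_stim, td, active_blocks)
    if (k == k_rew) {
      planned <- actor$a
      executed <- if (actor_on) execute_action(actor$a, sigma_a, eps_a) else 0
      r_trial <- env_reward(env, executed, eps_r)
      actor$a <- executed
    }
    r0 <- if (k >= k_rew && k < k_rend) r_trial else 0

    # actor derivatives read the pre-update valuation state (synchronous step)
    actor_new <- plan_step(actor, params, s, vstate$r_sig, vstate$v, cfg,
                           depleted = depleted, freeze_a = k >= k_rew || !actor_on)
    vstate <- td_step(vstate, td, s_v, r0, cfg)
    if (depleted) vstate$delta_v <- 0
    actor <- actor_new

    if (learn_valuation) {
      td <- td_learn_step(td, vstate, cfg$dt)
    }
    if (learn_actor && k >= k_rew && k < k_rend) {
      params <- learn_step(params, s, executed, actor, cfg$dt)
    }
    max_dv <- max(max_dv, vstate$delta_v)
    max_dg <- max(max_dg, actor$delta_g)
    max_dh <- max(max_dh, actor$delta_h)
    if (k == k_rend - 1L) dh_exec <- actor$delta_h
    if (record) {
      traj[k + 1L, ] <- c(t, actor$a, vstate$delta_v, actor$delta_g,
                          actor$delta_h, vstate$v, vstate$r_sig,
                          actor$goal_input)
    }
  }
  list(q = params$q, h = params$h, sg = params$sigma_g, sh = params$sigma_h,
       w = td$w, planned = planned, executed = executed, reward = r_trial,
       max_dv = max_dv, max_dg = max_dg, max_dh = max_dh, dh_exec = dh_exec,
       trajectory = traj)
}
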