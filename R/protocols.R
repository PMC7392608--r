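#' Specify a scripted experiment
#'
#' Builds a validated experiment specification with all model parameters
#' filled in at their standard values. Unnamed defaults follow the
#' protocol; any field of the dynamics configuration, the actor, the
#' valuation system or the choice model can be overridden through `...`
#' (e.g. `alpha_g = 0.1`). Unknown names are rejected.
#'
#' @param protocol One of `"acquisition"`, `"depletion"`, `"devaluation"`,
#'   `"pit"`, `"reversal"`.
#' @param seed Integer seed; every source of randomness in a run derives
#'   from it.
#' @param n_trials Number of training trials (acquisition, depletion).
#' @param n_train Training lengths for devaluation (default `c(120, 360)`).
#' @param n_test Number of test trials (devaluation, PIT).
#' @param replicates Number of replicate simulations (devaluation, PIT).
#' @param probe_trials Trials whose full trajectories are recorded.
#' @param bin_width Trials per summary bin.
#' @param n_pre,n_post Trials before and after the contingency reversal.
#' @param cs_trials Test trials on which the conditioned stimulus is
#'   co-presented (PIT).
#' @param sigma_a Motor noise SD at execution.
#' @param ... Parameter overrides (fields of [dynamics_config()],
#'   [intensity_params()], [td_params()], [choice_params()] or
#'   [simple_valuation_params()]).
#' @return A list of class `hs_experiment_spec`.
#' @examples
#' experiment_spec("acquisition", seed = 1)$params$alpha_g
#' @export
experiment_spec <- function(protocol = c("acquisition", "depletion",
                                         "devaluation", "pit", "reversal"),
                            seed = 1, n_trials = NULL, n_train = NULL,
                            n_test = NULL, replicates = NULL,
                            probe_trials = NULL, bin_width = NULL,
                            n_pre = NULL, n_post = NULL, cs_trials = NULL,
                            sigma_a = NULL, ...) {
  protocol <- match.arg(protocol)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be an integer", call. = FALSE)
  dots <- list(...)

  pick <- function(x, default) if (is.null(x)) default else x
  spec <- list(protocol = protocol, seed = seed)
  spec$sigma_a <- pick(sigma_a, if (protocol == "reversal") 2 else 1)

  if (protocol %in% c("acquisition", "depletion")) {
    spec$n_trials <- pick(n_trials, 360L)
    spec$probe_trials <- pick(probe_trials,
                              if (protocol == "acquisition") c(1L, 120L, 360L)
                              else c(120L, 360L))
    if (any(spec$probe_trials > spec$n_trials)) {
      stop("`probe_trials` must not exceed `n_trials`", call. = FALSE)
    }
  } else if (protocol == "devaluation") {
    spec$n_train <- pick(n_train, c(120L, 360L))
    if (!all(spec$n_train %in% c(120L, 360L))) {
      warning("devaluation training lengths other than 120/360 trials ",
              "depart from the standard protocol", call. = FALSE)
    }
    spec$n_test <- pick(n_test, 180L)
    spec$replicates <- pick(replicates, 10L)
    spec$bin_width <- pick(bin_width, 30L)
  } else if (protocol == "pit") {
    spec$n_stage1 <- pick(n_trials, 100L)
    spec$n_stage2 <- 100L
    spec$n_test <- pick(n_test, 60L)
    spec$replicates <- pick(replicates, 10L)
    spec$bin_width <- pick(bin_width, 10L)
    spec$cs_trials <- pick(cs_trials, c(21:30, 41:50))
  } else if (protocol == "reversal") {
    spec$n_pre <- pick(n_pre, 150L)
    spec$n_post <- pick(n_post, 150L)
    spec$probe_trials <- pick(probe_trials, NULL)
  }

  # assemble component parameter sets, then apply ... overrides by field name
  cfg_args <- dots[names(dots) %in% names(formals(dynamics_config))]
  spec$cfg <- do.call(dynamics_config, cfg_args)

  if (protocol == "pit") {
    # slower actor learning reproduces the gradual extinction seen in
    # transfer tests
    base_int <- list(alpha_g = 0.015, alpha_h = 0.005)
  } else {
    base_int <- list()
  }
  int_args <- modifyList(base_int,
                         dots[names(dots) %in% names(formals(intensity_params))])
  spec$params <- do.call(intensity_params, int_args)

  td_base <- if (protocol == "pit") list(n_stimuli = 2L) else list()
  td_args <- modifyList(td_base,
                        dots[names(dots) %in% names(formals(td_params))])
  spec$td <- do.call(td_params, td_args)

  ch_args <- dots[names(dots) %in% names(formals(choice_params))]
  # shared names (sigma_g, sigma_h, alpha_g, alpha_h) default to the
  # choice model's own values unless explicitly overridden
  spec$choice <- do.call(choice_params, ch_args)
  sv_args <- dots[names(dots) %in% names(formals(simple_valuation_params))]
  spec$valuation <- do.call(simple_valuation_params, sv_args)

  known <- unique(c(names(formals(dynamics_config)),
                    names(formals(intensity_params)),
                    names(formals(td_params)),
                    names(formals(choice_params)),
                    names(formals(simple_valuation_params))))
  bad <- setdiff(names(dots), known)
  if (length(bad)) {
    stop("unknown parameter override(s): ", paste(bad, collapse = ", "),
         "; valid names are fields of the configuration objects",
         call. = FALSE)
  }
  structure(spec, class = "hs_experiment_spec")
}

new_run <- function(class, ...) {
  structure(list(...), class = c(class, "hs_run"))
}

# one training/testing trial inside a protocol loop; draws noise in the
# documented order (reward, then motor)
protocol_trial <- function(params, td, spec, env, depleted = FALSE,
                           learn = TRUE, actor_on = TRUE, active_blocks = 1L,
                           record = FALSE) {
  eps_r <- rnorm(1)
  eps_a <- rnorm(1)
  run_intensity_trial(params, td, spec$cfg, env, sigma_a = spec$sigma_a,
                      eps_r = eps_r, eps_a = eps_a, depleted = depleted,
                      learn_valuation = learn, learn_actor = learn && actor_on,
                      actor_on = actor_on, active_blocks = active_blocks,
                      record = record)
}

trial_row <- function(trial, out, td) {
  tibble::tibble(
    trial = trial, planned = out$planned, executed = out$executed,
    reward = out$reward, w1 = td$w[1], q = out$params$q, h = out$params$h,
    sigma_g = out$params$sigma_g, sigma_h = out$params$sigma_h,
    max_delta_v = out$max_delta_v, max_delta_g = out$max_delta_g,
    max_delta_h = out$max_delta_h, delta_h_exec = out$delta_h_exec
  )
}

#' Run the acquisition protocol
#'
#' Repeated single-action trials against the saturating reward schedule:
#' the valuation system learns the available reward, the goal-directed
#' system the reward-per-action gain, and the habit system the typical
#' intensity, whose variance shrinks with practice. Trajectories of the
#' probe trials are recorded in full.
#'
#' @param spec An [experiment_spec()] with protocol `"acquisition"`.
#' @return An object of class `hs_acquisition` with tibbles `trials`
#'   (per-trial records and parameter snapshots) and `trajectories`
#'   (per-step dynamics of the probe trials), plus the final parameter
#'   objects.
#' @export
run_acquisition <- function(spec = experiment_spec("acquisition")) {
  stopifnot(spec$protocol == "acquisition")
  set.seed(spec$seed)
  params <- spec$params
  td <- spec$td
  env <- reward_env("tanh")
  rows <- vector("list", spec$n_trials)
  trajs <- list()
  for (i in seq_len(spec$n_trials)) {
    rec <- i %in% spec$probe_trials
    out <- protocol_trial(params, td, spec, env, record = rec)
    params <- out$params
    td <- out$td
    rows[[i]] <- trial_row(i, out, td)
    if (rec) trajs[[length(trajs) + 1L]] <-
        dplyr::mutate(out$trajectory, trial = i, .before = 1)
  }
  new_run("hs_acquisition",
          trials = dplyr::bind_rows(rows),
          trajectories = if (length(trajs)) dplyr::bind_rows(trajs) else NULL,
          final = list(params = params, td = td), spec = spec)
}

#' Run the dopamine-depletion probe protocol
#'
#' Trains as in acquisition, but at each probe trial all dopaminergic
#' prediction errors are clamped to zero and no learning occurs; the
#' planned intensity under depletion is compared with the intact planned
#' intensity computed from the same parameters. Early in training the
#' goal-directed system leads planning, so depletion abolishes the
#' response; once the habit has formed, responding survives depletion.
#'
#' @param spec An [experiment_spec()] with protocol `"depletion"`.
#' @return An object of class `hs_depletion` with tibbles `probes`
#'   (planned intensity depleted vs intact at each probe trial) and
#'   `trials`.
#' @export
run_depletion_probe <- function(spec = experiment_spec("depletion")) {
  stopifnot(spec$protocol == "depletion")
  set.seed(spec$seed)
  params <- spec$params
  td <- spec$td
  env <- reward_env("tanh")
  rows <- vector("list", spec$n_trials)
  probes <- list()
  for (i in seq_len(spec$n_trials)) {
    if (i %in% spec$probe_trials) {
      # probe trials are deterministic (planning only): no RNG, no learning
      dep <- run_intensity_trial(params, td, spec$cfg, env,
                                 sigma_a = spec$sigma_a, eps_r = 0, eps_a = 0,
                                 depleted = TRUE, learn_valuation = FALSE,
                                 learn_actor = FALSE)
      intact <- run_intensity_trial(params, td, spec$cfg, env,
                                    sigma_a = spec$sigma_a, eps_r = 0,
                                    eps_a = 0, depleted = FALSE,
                                    learn_valuation = FALSE,
                                    learn_actor = FALSE)
      probes[[length(probes) + 1L]] <- tibble::tibble(
        trial = i, planned_depleted = dep$planned,
        planned_intact = intact$planned
      )
      rows[[i]] <- trial_row(i, dep, td)
    } else {
      out <- protocol_trial(params, td, spec, env)
      params <- out$params
      td <- out$td
      rows[[i]] <- trial_row(i, out, td)
    }
  }
  new_run("hs_depletion",
          probes = dplyr::bind_rows(probes), trials = dplyr::bind_rows(rows),
          final = list(params = params, td = td), spec = spec)
}

bin_means <- function(x, bin_width) {
  n_bins <- length(x) %/% bin_width
  tibble::tibble(
    bin = seq_len(n_bins),
    mean_intensity = vapply(seq_len(n_bins), function(b) {
      mean(x[((b - 1) * bin_width + 1):(b * bin_width)])
    }, numeric(1))
  )
}

#' Run the outcome-devaluation protocol
#'
#' Trains the intensity model for each training length, then tests for
#' `n_test` trials in extinction (reward replaced by the pure effort cost
#' `r = -a`). In the devalued condition the reward expectation is removed
#' at test start (all valuation weights and the goal-directed gain set to
#' zero); the control condition keeps its parameters. Learning stays on
#' during testing, so responding extinguishes in all conditions. The
#' devalued and control tests of a replicate share the training run and
#' the test noise (paired design).
#'
#' @param spec An [experiment_spec()] with protocol `"devaluation"`.
#' @return An object of class `hs_devaluation` with tibbles `tests`
#'   (per-trial planned intensities), `bins` (per-replicate bin means) and
#'   `summary` (mean and SD across replicates per bin).
#' @export
run_devaluation <- function(spec = experiment_spec("devaluation")) {
  stopifnot(spec$protocol == "devaluation")
  set.seed(spec$seed)
  env_train <- reward_env("tanh")
  env_test <- reward_env("cost")
  tests <- list()
  for (rep in seq_len(spec$replicates)) {
    for (n_train in spec$n_train) {
      params <- spec$params
      td <- spec$td
      for (i in seq_len(n_train)) {
        out <- protocol_trial(params, td, spec, env_train)
        params <- out$params
        td <- out$td
      }
      # shared test noise: the two groups of a replicate are paired
      noise <- matrix(rnorm(2 * spec$n_test), ncol = 2)
      for (group in c("devalued", "control")) {
        p <- params
        v <- td
        if (group == "devalued") {
          v$w[] <- 0
          p$q <- 0
        }
        planned <- executed <- rewards <- numeric(spec$n_test)
        for (i in seq_len(spec$n_test)) {
          out <- run_intensity_trial(p, v, spec$cfg, env_test,
                                     sigma_a = spec$sigma_a,
                                     eps_r = noise[i, 1], eps_a = noise[i, 2])
          p <- out$params
          v <- out$td
          planned[i] <- out$planned
          executed[i] <- out$executed
          rewards[i] <- out$reward
        }
        tests[[length(tests) + 1L]] <- tibble::tibble(
          replicate = rep, n_train = n_train, group = group,
          trial = seq_len(spec$n_test), planned = planned,
          executed = executed, reward = rewards
        )
      }
    }
  }
  tests <- dplyr::bind_rows(tests)
  bins <- tests |>
    dplyr::group_by(.data$replicate, .data$n_train, .data$group) |>
    dplyr::reframe(bin_means(.data$planned, spec$bin_width))
  summary <- bins |>
    dplyr::group_by(.data$n_train, .data$group, .data$bin) |>
    dplyr::summarise(mean = mean(.data$mean_intensity),
                     sd = sd(.data$mean_intensity), .groups = "drop")
  new_run("hs_devaluation", tests = tests, bins = bins, summary = summary,
          spec = spec)
}

#' Run the Pavlovian-instrumental transfer protocol
#'
#' Three stages: (1) operant training of the intensity model with the
#' lever stimulus; (2) classical conditioning in which a separate
#' conditioned stimulus predicts reward and only the valuation system
#' learns; (3) extinction testing in which the conditioned stimulus is
#' co-presented on designated trials. On those trials the valuation
#' system's expectation is the sum of the values of both stimuli, so the
#' actor plans a stronger response.
#'
#' @param spec An [experiment_spec()] with protocol `"pit"`.
#' @param stage2 Set `FALSE` to skip classical conditioning (control run:
#'   no transfer expected).
#' @return An object of class `hs_pit` with tibbles `tests`, `bins` and
#'   `summary` (mean and SE across replicates per 10-trial bin).
#' @export
run_pit <- function(spec = experiment_spec("pit"), stage2 = TRUE) {
  stopifnot(spec$protocol == "pit")
  set.seed(spec$seed)
  tests <- list()
  for (rep in seq_len(spec$replicates)) {
    params <- spec$params
    td <- spec$td
    for (i in seq_len(spec$n_stage1)) {
      out <- protocol_trial(params, td, spec, reward_env("tanh"),
                            active_blocks = 1L)
      params <- out$params
      td <- out$td
    }
    if (stage2) {
      for (i in seq_len(spec$n_stage2)) {
        out <- protocol_trial(params, td, spec, reward_env("fixed", value = 1),
                              actor_on = FALSE, active_blocks = 2L)
        td <- out$td
      }
    }
    for (i in seq_len(spec$n_test)) {
      cs <- i %in% spec$cs_trials
      out <- protocol_trial(params, td, spec, reward_env("cost"),
                            active_blocks = if (cs) c(1L, 2L) else 1L)
      params <- out$params
      td <- out$td
      tests[[length(tests) + 1L]] <- tibble::tibble(
        replicate = rep, trial = i, cs = cs, planned = out$planned,
        executed = out$executed, reward = out$reward
      )
    }
  }
  tests <- dplyr::bind_rows(tests)
  bins <- tests |>
    dplyr::group_by(.data$replicate) |>
    dplyr::reframe(bin_means(.data$planned, spec$bin_width)) |>
    dplyr::mutate(cs = .data$bin %in% (unique(ceiling(spec$cs_trials / spec$bin_width))))
  summary <- bins |>
    dplyr::group_by(.data$bin, .data$cs) |>
    dplyr::summarise(mean = mean(.data$mean_intensity),
                     se = sd(.data$mean_intensity) / sqrt(dplyr::n()),
                     .groups = "drop")
  new_run("hs_pit", tests = tests, bins = bins, summary = summary,
          spec = spec)
}

#' Run the probabilistic reversal protocol
#'
#' Two stimuli, two actions. For the first `n_pre` trials action 1 is
#' correct for stimulus 1 and action 2 for stimulus 2; afterwards the
#' contingency reverses. Correct responses earn mean reward 1, errors 0,
#' both with Gaussian noise. The choice model plans through competitive
#' dynamics, explores through pre-choice noise, and learns from
#' equilibrium prediction errors; the simplified valuation system tracks
#' each stimulus's value.
#'
#' @param spec An [experiment_spec()] with protocol `"reversal"`.
#' @return An object of class `hs_reversal` with tibble `trials` (choices,
#'   rewards, prediction errors and parameter snapshots) and optional
#'   probe `trajectories`.
#' @export
run_reversal <- function(spec = experiment_spec("reversal")) {
  stopifnot(spec$protocol == "reversal")
  set.seed(spec$seed)
  params <- spec$choice
  valuation <- spec$valuation
  n <- spec$n_pre + spec$n_post
  rows <- vector("list", n)
  trajs <- list()
  for (i in seq_len(n)) {
    # draw order: reward noise, choice noise, stimulus
    eps_r <- rnorm(1)
    eps_choice <- rnorm(2)
    stim <- 1L + (runif(1) > 0.5)
    s_bar <- c(0, 0)
    s_bar[stim] <- 1
    correct_action <- if (i <= spec$n_pre) stim else 3L - stim
    reward_fn <- function(choice, s_bar, eps) {
      as.numeric(choice == correct_action) + 0.5 * eps
    }
    rec <- i %in% spec$probe_trials
    out <- run_choice_trial(params, valuation, s_bar, reward_fn, spec$cfg,
                            eps_r = eps_r, eps_choice = eps_choice,
                            record = rec)
    params <- out$params
    valuation <- out$valuation
    rows[[i]] <- tibble::tibble(
      trial = i, stimulus = stim, choice = out$choice,
      correct = out$choice == correct_action, reward = out$reward,
      a1_plan = out$a_plan[1], a2_plan = out$a_plan[2], v_end = out$v_end,
      delta_v = out$delta_v, delta_g = out$delta_g, delta_h = out$delta_h,
      max_dg_plan = out$max_dg_plan, max_dh_plan = out$max_dh_plan,
      Q11 = params$Q[1, 1], Q12 = params$Q[1, 2],
      Q21 = params$Q[2, 1], Q22 = params$Q[2, 2],
      H11 = params$H[1, 1], H12 = params$H[1, 2],
      H21 = params$H[2, 1], H22 = params$H[2, 2],
      sigma_g = params$sigma_g, sigma_h = params$sigma_h,
      w1 = valuation$w[1], w2 = valuation$w[2]
    )
    if (rec) trajs[[length(trajs) + 1L]] <-
        dplyr::mutate(out$trajectory, trial = i, .before = 1)
  }
  new_run("hs_reversal",
          trials = dplyr::bind_rows(rows),
          trajectories = if (length(trajs)) dplyr::bind_rows(trajs) else NULL,
          final = list(params = params, valuation = valuation), spec = spec)
}
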