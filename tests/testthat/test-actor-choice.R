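test_that("choice planning is inert without parameters and symmetric under
           symmetric ones", {
  cfg <- dynamics_config()
  p <- choice_params(Q = matrix(0, 2, 2), H = matrix(0, 2, 2))
  st <- list(a_vec = c(0, 0), delta_g = 0)
  for (k in 1:200) {
    st <- choice_plan_step(st$a_vec, st$delta_g, p, c(1, 0), v = 0, cfg = cfg)
  }
  expect_equal(st$a_vec, c(0, 0))

  p <- choice_params(Q = matrix(0.5, 2, 2), H = matrix(0.3, 2, 2), comp = 1)
  st <- list(a_vec = c(0, 0), delta_g = 0)
  for (k in 1:500) {
    st <- choice_plan_step(st$a_vec, st$delta_g, p, c(1, 0), v = 1, cfg = cfg)
    expect_equal(st$a_vec[1], st$a_vec[2])
    expect_true(all(st$a_vec >= 0 & st$a_vec <= 1))
  }
})

test_that("initial planning drive weights the systems by precision", {
  p <- choice_params(Q = matrix(0, 2, 2),
                     H = matrix(c(0.8, 0.2, 0.4, 0.6), 2, 2),
                     sigma_h = 2)
  expect_equal(initial_drive(p, c(1, 0), R = 3), c(0.4, 0.1))  # habit only
  p <- choice_params(Q = matrix(c(1, 0.5, 0, 0), 2, 2), sigma_g = 2,
                     sigma_h = 1e9)
  expect_equal(initial_drive(p, c(1, 0), R = 2), c(1, 0.5), tolerance = 1e-6)
  # larger goal-directed variance strictly reduces the goal contribution
  drives <- vapply(c(0.5, 1, 2, 4), function(sg) {
    initial_drive(choice_params(Q = matrix(1, 2, 2), sigma_g = sg),
                  c(1, 0), R = 1)[1]
  }, numeric(1))
  expect_true(all(diff(drives) < 0))
})

test_that("noisy argmax choice matches the Gaussian closed form", {
  expect_equal(choose(c(1, 0), sigma_a_choice = 0)$choice, 1)
  expect_equal(choose(c(1, 0), 0)$a_vec, c(1, 0))

  set.seed(31)
  picks <- replicate(1e4, choose(c(0, 0), 2)$choice)
  expect_lt(abs(mean(picks == 1) - 0.5), 0.02)

  set.seed(32)
  picks <- replicate(1e4, choose(c(0.8, 0.2), 2)$choice)
  expect_lt(abs(mean(picks == 1) - pnorm(0.6 / (2 * sqrt(2)))), 0.02)
})

test_that("equilibrium prediction errors match direct evaluation", {
  p <- choice_params(Q = matrix(0.7, 2, 2), H = matrix(0, 2, 2))
  e <- equilibrium_errors(p, c(0, 1), c(1, 0), r = 0.7)
  expect_equal(e$delta_g, 0)   # perfectly predicted reward
  expect_equal(e$delta_h, 1)   # maximally surprising action
  p <- choice_params(Q = matrix(0.4, 2, 2), sigma_g = 0.5)
  e <- equilibrium_errors(p, c(1, 0), c(0, 1), r = 1)
  expect_equal(e$delta_g, 1.2)  # (1 - 0.4) / 0.5
})

test_that("per-trial learning drives Q and H to their contingency values", {
  p <- choice_params(Q = matrix(0, 2, 2), H = matrix(0, 2, 2))
  # no errors: only variance decay
  p0 <- choice_learn(p, c(1, 0), c(1, 0), delta_g = 0, delta_h = 0)
  expect_equal(p0$Q, p$Q)
  expect_equal(p0$H[1, 1], 0.05)  # vector rule: moves toward chosen action
  expect_lt(p0$sigma_g, p$sigma_g)

  # chosen action's habit grows; unchosen in the same state is untouched
  # when its own habit error is zero
  p1 <- choice_learn(p, c(0, 1), c(0, 1), delta_g = 0.5, delta_h = 1)
  expect_equal(p1$H[2, 2], 0.05)
  expect_equal(p1$H[1, 2], 0)
  expect_equal(p1$Q[2, 2], 0.1 * 0.5)
  expect_equal(p1$Q[1, 2], 0)

  # repeated rewarded choice of action 1 in state 1
  p <- choice_params(Q = matrix(0, 2, 2), H = matrix(0, 2, 2))
  for (k in 1:100) {
    e <- equilibrium_errors(p, c(1, 0), c(1, 0), r = 1)
    p <- choice_learn(p, c(1, 0), c(1, 0), e$delta_g, e$delta_h)
  }
  expect_equal(p$Q[1, 1], 1, tolerance = 0.1)
  expect_equal(p$H[1, 1], 1, tolerance = 0.05)
  expect_equal(p$H[2, 1], 0)
})

test_that("scalar habit rule depresses the unchosen action", {
  p <- choice_params(Q = matrix(0, 2, 2),
                     H = matrix(c(0.5, 0.5, 0, 0), 2, 2),
                     habit_rule = "scalar")
  up <- choice_learn(p, c(1, 0), c(1, 0), delta_g = 0, delta_h = 0.5)
  expect_equal(up$H[1, 1], 0.5 + 0.05 * 0.5)
  expect_equal(up$H[2, 1], 0.5 - 0.05 * 0.5 * 0.5)
  expect_equal(up$H[, 2], c(0, 0))
})

test_that("habit strengths stay in [0, 1] and variances floored under
           random updates", {
  set.seed(33)
  p <- choice_params()
  for (k in 1:300) {
    s_bar <- c(0, 0); s_bar[sample(2, 1)] <- 1
    a_bin <- c(0, 0); a_bin[sample(2, 1)] <- 1
    e <- equilibrium_errors(p, s_bar, a_bin, r = rnorm(1, 0.5, 2))
    p <- choice_learn(p, s_bar, a_bin, e$delta_g, e$delta_h)
    expect_true(all(p$H >= 0 & p$H <= 1))
    expect_gte(p$sigma_g, 0.2)
    expect_gte(p$sigma_h, 0.2)
  }
})

test_that("one choice trial couples planning, outcome and learning", {
  set.seed(34)
  p <- choice_params(Q = matrix(c(1, 0, 0, 1), 2, 2),
                     H = matrix(0, 2, 2))
  v <- simple_valuation_params(w = c(1, 1))
  out <- run_choice_trial(p, v, c(1, 0),
                          reward_fn = function(ch, s, eps) as.numeric(ch == 1),
                          eps_r = 0, eps_choice = c(0, 0), record = TRUE)
  expect_equal(out$choice, 1)       # noiseless choice follows the drive
  expect_gt(out$a_plan[1], out$a_plan[2])
  expect_equal(out$v_end, 1, tolerance = 1e-3)
  expect_equal(sum(out$trajectory$a1 < -1e-9), 0)  # clipped throughout
  # goal-only sanity: habit frozen at 0 with huge variance, choices follow Q
  p2 <- choice_params(Q = matrix(c(1, 0, 0, 1), 2, 2), H = matrix(0, 2, 2),
                      sigma_h = 1e6, alpha_h = 0)
  out2 <- run_choice_trial(p2, v, c(0, 1),
                           reward_fn = function(ch, s, eps) 1,
                           eps_r = 0, eps_choice = c(0, 0))
  expect_equal(out2$choice, 2)
})
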