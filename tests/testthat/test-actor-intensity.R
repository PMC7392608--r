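test_that("planning has no drive without reward expectation or habit", {
  p <- intensity_params(h = 0)
  actor <- converge_plan(p, v = 0, n = 500)
  expect_equal(actor$a, 0)
  expect_equal(actor$delta_g, 0)
})

test_that("planning converges to the stated fixed point", {
  # sigma_g = sigma_h = 1, q = s = 1, h = 0, v = 2: a* = 1, delta_g* = 1
  p <- intensity_params(q = 1, h = 0, sigma_g = 1, sigma_h = 1)
  actor <- converge_plan(p, v = 2)
  expect_equal(actor$a, 1, tolerance = 1e-3)
  expect_equal(actor$delta_g, 1, tolerance = 1e-3)
})

test_that("converged planning equals the analytic MAP action", {
  set.seed(21)
  for (i in 1:25) {
    p <- intensity_params(q = runif(1, 0.2, 2), h = runif(1, 0, 2),
                          sigma_g = runif(1, 0.3, 3),
                          sigma_h = runif(1, 0.3, 5))
    v <- runif(1, 0.5, 3)
    actor <- converge_plan(p, v)
    expect_equal(actor$a, map_action(v, 1, p), tolerance = 1e-3)
  }
})

test_that("execution adds seeded, unbiased motor noise", {
  expect_equal(execute_action(1.7, sigma_a = 0), 1.7)
  set.seed(7); a1 <- execute_action(1, 1)
  set.seed(7); a2 <- execute_action(1, 1)
  expect_identical(a1, a2)
  set.seed(8)
  draws <- replicate(1e4, execute_action(2, 0.5))
  expect_lt(abs(mean(draws - 2)), 3 * 0.5 / 100)
})

test_that("three-factor learning matches direct evaluation and floors
           variances", {
  p <- intensity_params()
  st <- list(delta_g = 0, delta_h = 0)
  up <- learn_step(p, s = 1, a_exec = 1, st, dt = 0.001)
  expect_equal(up$q, p$q)
  expect_equal(up$h, p$h)
  expect_lt(up$sigma_g, p$sigma_g)  # decays toward the floor
  expect_lt(up$sigma_h, p$sigma_h)

  st <- list(delta_g = 1, delta_h = 0)
  up <- learn_step(p, s = 1, a_exec = 2, st, dt = 0.001)
  expect_equal(up$q, 0.1001)

  # sigma_h decreases monotonically toward the floor, never below
  p <- intensity_params()
  st <- list(delta_g = 0, delta_h = 0)
  prev <- p$sigma_h
  for (k in 1:5000) {
    p <- learn_step(p, 1, 1, st, dt = 0.05)
    expect_lte(p$sigma_h, prev)
    expect_gte(p$sigma_h, 0.2)
    prev <- p$sigma_h
  }
  expect_equal(p$sigma_h, 0.2)
})

test_that("compiled and reference trial loops agree exactly", {
  p <- intensity_params()
  td <- td_params()
  cfg <- dynamics_config()
  for (depl in c(FALSE, TRUE)) {
    o_cpp <- run_intensity_trial(p, td, cfg, eps_r = 0.3, eps_a = -0.5,
                                 depleted = depl, record = TRUE,
                                 engine = "cpp")
    o_r <- run_intensity_trial(p, td, cfg, eps_r = 0.3, eps_a = -0.5,
                               depleted = depl, record = TRUE, engine = "r")
    expect_equal(as.matrix(o_r$trajectory), as.matrix(o_cpp$trajectory),
                 tolerance = 1e-12)
    expect_equal(o_r$td$w, o_cpp$td$w, tolerance = 1e-12)
    expect_equal(o_r$params$q, o_cpp$params$q, tolerance = 1e-12)
    expect_equal(o_r$max_delta_g, o_cpp$max_delta_g, tolerance = 1e-12)
  }
})

test_that("trials are deterministic given the noise draws", {
  p <- intensity_params()
  td <- td_params()
  o1 <- run_intensity_trial(p, td, eps_r = 0.1, eps_a = 0.2)
  o2 <- run_intensity_trial(p, td, eps_r = 0.1, eps_a = 0.2)
  expect_identical(o1$planned, o2$planned)
  expect_identical(o1$td$w, o2$td$w)
})

test_that("depleted untrained actor cannot plan; trained habit survives", {
  p <- intensity_params()  # h = 0, sigma_h = 100
  td <- td_params()
  out <- run_intensity_trial(p, td, depleted = TRUE, eps_r = 0, eps_a = 0,
                             learn_valuation = FALSE, learn_actor = FALSE)
  expect_equal(out$planned, 0)  # no habit, no dopamine: exactly zero drive

  acq <- run_acquisition(experiment_spec("acquisition", seed = 1))
  dep <- run_intensity_trial(acq$final$params, acq$final$td, depleted = TRUE,
                             eps_r = 0, eps_a = 0, learn_valuation = FALSE,
                             learn_actor = FALSE)
  expect_gt(dep$planned, 1)  # habit-driven response survives depletion
})

test_that("acquisition reproduces the dopaminergic trajectory patterns", {
  acq <- run_acquisition(experiment_spec("acquisition", seed = 1))
  tj <- acq$trajectories

  peak_time <- function(trial, col) {
    d <- tj[tj$trial == trial, ]
    d$t[which.max(d[[col]])]
  }
  # valuation error peaks after the reward on trial 1, and within 0.3 of
  # the stimulus once the reward is predicted
  expect_gt(peak_time(1, "delta_v"), 2)
  expect_lt(peak_time(120, "delta_v"), 1.3)
  expect_lt(peak_time(360, "delta_v"), 1.3)

  # planning resolves the goal-directed error: delta_g rises after the
  # stimulus and falls by >= 50% of its peak before the reward (trial 120)
  d <- tj[tj$trial == 120 & tj$t >= 1 & tj$t < 2, ]
  expect_lt(d$delta_g[nrow(d)], 0.5 * max(d$delta_g))
  # while the planned intensity rises
  expect_gt(d$a[nrow(d)], d$a[1])

  # habitual-regime attenuation: post-stimulus delta_g peak shrinks
  pk <- function(trial) {
    d <- tj[tj$trial == trial & tj$t >= 1 & tj$t < 2, ]
    max(d$delta_g)
  }
  expect_lt(pk(360), pk(120))

  # habit error at execution has the sign of (a_exec - h*s)
  tr <- acq$trials
  ok <- sign(tr$delta_h_exec) == sign(tr$executed - tr$h) |
    abs(tr$delta_h_exec) < 1e-4
  expect_true(all(ok))
})
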