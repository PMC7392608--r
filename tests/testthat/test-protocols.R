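test_that("saturating reward schedule matches its closed form and optimum", {
  expect_equal(env_tanh(0, eps = 0), 0)
  expect_equal(env_tanh(2, eps = 0), 5 * tanh(1.2) - 2)
  opt <- optimize(function(a) env_tanh(a, eps = 0), c(0, 5), maximum = TRUE)
  expect_equal(opt$maximum, 1.9103, tolerance = 1e-3)
  expect_equal(opt$objective, 2.1716, tolerance = 1e-3)
})

test_that("experiment specs fill protocol defaults and validate overrides", {
  sp <- experiment_spec("acquisition", seed = 1)
  expect_equal(sp$td$alpha_v, 0.5)
  expect_equal(sp$params$alpha_g, 0.05)
  expect_equal(sp$params$alpha_h, 0.02)
  expect_equal(sp$params$alpha_sg, 0.05)
  expect_equal(sp$params$alpha_sh, 0.1)
  expect_equal(sp$cfg$dt, 0.001)
  expect_equal(sp$n_trials, 360L)

  pit <- experiment_spec("pit", seed = 1)
  expect_equal(pit$params$alpha_g, 0.015)
  expect_equal(pit$params$alpha_h, 0.005)
  expect_length(pit$td$w, 10)

  expect_error(experiment_spec("acquisition", dt = 0), "dt")
  expect_error(experiment_spec("acquisition", nonsense = 1), "nonsense")
  expect_warning(experiment_spec("devaluation", n_train = 240),
                 "training lengths")
})

test_that("protocol runs are reproducible bit-for-bit from (spec, seed)", {
  sp <- experiment_spec("acquisition", seed = 4, n_trials = 12,
                        probe_trials = 3)
  a1 <- run_acquisition(sp)
  a2 <- run_acquisition(sp)
  expect_identical(a1$trials, a2$trials)
  expect_identical(a1$trajectories, a2$trajectories)
  b <- run_acquisition(experiment_spec("acquisition", seed = 5,
                                       n_trials = 12, probe_trials = 3))
  expect_false(identical(a1$trials$reward, b$trials$reward))

  r1 <- run_reversal(experiment_spec("reversal", seed = 2, n_pre = 20,
                                     n_post = 20))
  r2 <- run_reversal(experiment_spec("reversal", seed = 2, n_pre = 20,
                                     n_post = 20))
  expect_identical(r1$trials, r2$trials)
})

test_that("depletion probes dissociate goal-directed from habitual control", {
  dep <- run_depletion_probe(experiment_spec("depletion", seed = 1))
  pr <- dep$probes
  expect_equal(pr$trial, c(120L, 360L))
  # the depleted response grows with training while the intact one does not
  expect_lt(pr$planned_depleted[1] / pr$planned_intact[1],
            pr$planned_depleted[2] / pr$planned_intact[2])
  expect_gt(pr$planned_depleted[2], 1)

  # without a habit (h frozen at 0) the depleted response is exactly zero
  dep0 <- run_depletion_probe(experiment_spec("depletion", seed = 1,
                                              n_trials = 40,
                                              probe_trials = 40L,
                                              alpha_h = 0))
  expect_equal(dep0$probes$planned_depleted, 0)
})

test_that("devaluation summaries recompute from per-replicate records", {
  sp <- experiment_spec("devaluation", seed = 2, replicates = 3,
                        n_train = 120L, n_test = 60L)
  dv <- run_devaluation(sp)
  # summary SD must equal a direct recomputation from the stored bins
  for (b in unique(dv$summary$bin)) {
    for (g in c("devalued", "control")) {
      got <- dv$summary[dv$summary$bin == b & dv$summary$group == g, ]
      raw <- dv$bins$mean_intensity[dv$bins$bin == b & dv$bins$group == g]
      expect_equal(got$mean, mean(raw))
      expect_equal(got$sd, sd(raw))
    }
  }
  # bins recompute from the per-trial tests table
  one <- dv$tests[dv$tests$replicate == 1 & dv$tests$group == "control", ]
  expect_equal(dv$bins$mean_intensity[dv$bins$replicate == 1 &
                                        dv$bins$group == "control"][1],
               mean(one$planned[1:30]))
  # devalued responding starts below control
  g <- glance(dv)
  expect_lt(g$ratio_120, 1)
})

test_that("transfer requires the Pavlovian stage", {
  sp <- experiment_spec("pit", seed = 3, replicates = 2)
  full <- run_pit(sp)
  ctrl <- run_pit(sp, stage2 = FALSE)
  cs_effect <- function(x) {
    s <- x$summary
    mean(s$mean[s$bin %in% c(3, 5)]) - mean(s$mean[s$bin %in% c(2, 4, 6)])
  }
  expect_gt(cs_effect(full), 0.15)
  expect_lt(cs_effect(ctrl), cs_effect(full) / 3)
  # responding declines over the extinction test
  s <- full$summary
  expect_lt(s$mean[s$bin == 6], s$mean[s$bin == 1])
})

test_that("reversal learning is above chance and perseverates briefly", {
  rv <- run_reversal(experiment_spec("reversal", seed = 3))
  tr <- rv$trials
  # exploration noise (SD 2 on intensities in [0,1]) caps accuracy at
  # Phi(1/(2*sqrt(2))) ~ 0.64; trained accuracy must clear chance
  expect_gt(mean(tr$correct[51:150]), 0.55)
  # choices are one-hot and H stays bounded
  expect_true(all(tr$choice %in% 1:2))
  expect_true(all(tr[, c("H11", "H12", "H21", "H22")] >= 0 &
                    tr[, c("H11", "H12", "H21", "H22")] <= 1))
  # perseveration right after the contingency flip
  expect_gte(mean(!tr$correct[151:165]), 0.5)
  # habit prediction errors rise again following the reversal
  expect_gt(max(tr$max_dh_plan[151:200]), mean(tr$max_dh_plan[100:150]))
})
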