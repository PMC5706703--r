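test_that("blocked schedules are balanced and alternate the prior", {
  sched <- build_schedule(default_design, start_prior = "Narrow", seed = 7)
  expect_equal(nrow(sched), 480L)
  tab <- table(sched$prior, sched$likelihood)
  expect_true(all(tab == 80L))  # 2 blocks per prior x 40 per likelihood
  bp <- unique(sched[, c("block", "prior")])$prior
  expect_equal(bp, c("Narrow", "Wide", "Narrow", "Wide"))
  sched2 <- build_schedule(default_design, start_prior = "Wide", seed = 7)
  bp2 <- unique(sched2[, c("block", "prior")])$prior
  expect_equal(bp2, c("Wide", "Narrow", "Wide", "Narrow"))
  # within a block every likelihood appears equally often
  for (b in 1:4)
    expect_true(all(table(sched$likelihood[sched$block == b]) == 40L))
  # determinism
  expect_identical(sched,
                   build_schedule(default_design, "Narrow", seed = 7))
  expect_error(build_schedule(task_design(trials_per_block = 100L)),
               "divisible")
})

test_that("trial stimuli follow the stated generative distributions", {
  set.seed(31)
  n <- 1e5
  stim <- sample_trial(rep(0.1, n), rep(0.25, n), default_design)
  expect_equal(mean(stim$target), 0.5, tolerance = 3 * 0.1 / sqrt(n) / 0.5)
  expect_equal(sd(stim$target), 0.1, tolerance = 0.01)
  dev <- as.vector(stim$splash - stim$target)
  expect_equal(sd(dev), 0.25, tolerance = 0.01)
  expect_equal(mean(dev), 0, tolerance = 3 * 0.25 / sqrt(4 * n))
  expect_true(all(stim$net_init >= 0 & stim$net_init <= 1))
  # Kolmogorov-Smirnov calibration at a fixed seed
  set.seed(99)
  stim2 <- sample_trial(rep(0.03, 2000), rep(0.1, 2000), default_design)
  expect_gt(ks.test(stim2$target, "pnorm", 0.5, 0.03)$p.value, 0.01)
  expect_gt(ks.test(stim2$splash[, 1] - stim2$target, "pnorm", 0,
                    0.1)$p.value, 0.01)
  # degenerate likelihood: all dots sit on the target
  stim3 <- sample_trial(rep(0.1, 50), rep(1e-12, 50), default_design)
  expect_equal(as.vector(stim3$splash),
               rep(stim3$target, default_design$n_samples),
               tolerance = 1e-9)
})

test_that("the linear readout reproduces its limiting observers", {
  set.seed(5)
  stim <- sample_trial(rep(0.1, 100), rep(0.1, 100), default_design)
  cen <- splash_centroid(stim$splash)
  cond <- rep("Wide-Medium", 100)
  r1 <- simulate_response(noiseless_observer(1), stim$splash,
                          stim$net_init, cond)
  expect_equal(r1, cen)
  r0 <- simulate_response(noiseless_observer(0), stim$splash,
                          stim$net_init, cond)
  expect_equal(r0, rep(0.5, 100))
  # optimal-weight observer lands on the posterior mean, cross-module
  w <- optimal_slope(0.1, 0.1, 4)
  rw <- simulate_response(noiseless_observer(w), stim$splash,
                          stim$net_init, cond)
  expect_equal(rw, posterior_params(0.5, 0.1, cen, 0.1, 4)$mean)
})

test_that("lapse modes produce net_init responses or timeouts", {
  set.seed(12)
  stim <- sample_trial(rep(0.1, 4000), rep(0.1, 4000), default_design)
  cond <- rep("Wide-Medium", 4000)
  obs_t <- observer("L1", weights = 0.8, motor_noise_sd = 0,
                    lapse_rate = 0.2, lapse_mode = "timeout")
  rt <- simulate_response(obs_t, stim$splash, stim$net_init, cond)
  expect_equal(mean(is.na(rt)), 0.2, tolerance = 0.15)
  obs_n <- observer("L2", weights = 0.8, motor_noise_sd = 0,
                    lapse_rate = 0.2, lapse_mode = "net_init")
  rn <- simulate_response(obs_n, stim$splash, stim$net_init, cond)
  expect_false(anyNA(rn))
  expect_equal(mean(rn == stim$net_init), 0.2, tolerance = 0.15)
})

test_that("simulated subjects have the full blocked session layout", {
  obs <- noiseless_observer(0.7, id = "A")
  d <- simulate_subject(obs, default_design, seed = 3)
  expect_equal(nrow(d), 480L)
  expect_true(all(table(d$prior, d$likelihood) == 80L))
  expect_named(d, c("subject_id", "group", "age", "match_id", "block",
                    "trial_index", "prior", "likelihood", "prior_sd",
                    "likelihood_sd", "target", paste0("splash_", 1:4),
                    "net_init", "response", "caught"))
  expect_identical(d, simulate_subject(obs, default_design, seed = 3))
  # caught is missing exactly when the response is missing
  expect_identical(is.na(d$caught), is.na(d$response))
  expect_equal(d$caught,
               ifelse(is.na(d$response), NA,
                      abs(d$response - d$target) <= 0.01))
})

test_that("cohorts are reproducible, age-matched and extendable", {
  tr <- simulate_cohort(n_per_group = 3, seed = 42)
  expect_equal(nrow(tr), 6L * 480L)
  expect_equal(sort(unique(tr$group)), c("CP", "TD"))
  man <- attr(tr, "manifest")
  expect_equal(nrow(man), 6L * 6L)  # subjects x conditions
  expect_true(all(c("weight_true", "motor_noise_sd", "lapse_rate") %in%
                    names(man)))
  # age matching: both members of a pair share one age
  ages <- unique(tr[, c("subject_id", "match_id", "age")])
  expect_true(all(tapply(ages$age, ages$match_id,
                         function(a) length(unique(a))) == 1L))
  # determinism: byte-identical CSV for the same master seed
  tr2 <- simulate_cohort(n_per_group = 3, seed = 42)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trials(tr, f1); write_trials(tr2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # extendability: enlarging the cohort leaves earlier subjects intact
  tr4 <- simulate_cohort(n_per_group = 4, seed = 42)
  keep <- tr4$subject_id %in% unique(tr$subject_id)
  expect_equal(tr4[keep, ], tr, ignore_attr = TRUE)
})

test_that("noise-free cohorts are recovered exactly by the slope fit", {
  spec0 <- flat_spec(scale = 0.85, jitter = 0, noise = 0, lapse = 0)
  tr <- simulate_cohort(n_per_group = 2, cp_spec = spec0,
                        td_spec = spec0, seed = 9)
  fit <- estimation_fit(tr, n_boot = 0)
  man <- attr(tr, "manifest")
  m <- merge(fit$slopes, man, by = c("subject_id", "condition"))
  expect_equal(m$slope, m$weight_true, tolerance = 1e-10)
})

test_that("invalid observer and spec fields are rejected", {
  expect_error(observer("x", weights = 1.2), "weights")
  expect_error(observer("x", weights = c(0.3, 0.4)), "named")
  expect_error(observer("x", lapse_rate = 1), "lapse_rate")
  expect_error(observer("x", motor_noise_sd = -1), "motor_noise_sd")
  expect_error(group_spec(weight_scale = "a"), "weight_scale")
  expect_error(simulate_cohort(n_per_group = 0), "n_per_group")
  expect_error(simulate_cohort(1, cp_spec = list(a = 1)), "group_spec")
})
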