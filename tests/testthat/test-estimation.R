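test_that("through-origin slope matches hand-computed least squares", {
  # mu = 0.5; num = 0.1*0.08 + (-0.1)(-0.07) + 0.2*0.14 = 0.043
  # den = 0.01 + 0.01 + 0.04 = 0.06
  s <- fit_slope(c(0.6, 0.4, 0.7), c(0.58, 0.43, 0.64), 0.5)
  expect_equal(s, 0.043 / 0.06)
  expect_equal(s, 0.717, tolerance = 1e-3)
  # independent least-squares oracle: lm through the origin
  set.seed(8)
  cen <- runif(30, 0.2, 0.8)
  resp <- 0.5 + 0.63 * (cen - 0.5) + rnorm(30, 0, 0.02)
  expect_equal(fit_slope(cen, resp, 0.5),
               unname(coef(lm(I(resp - 0.5) ~ I(cen - 0.5) - 1))))
})

test_that("slope fit honours exact observers and missing trials", {
  cell <- sim_cell(50, 0.6, 0.1, 0.1)
  expect_equal(fit_slope(cell$centroid, cell$response, 0.5), 0.6)
  # prior-only responses give slope zero
  expect_equal(fit_slope(cell$centroid, rep(0.5, 50), 0.5), 0)
  # timeouts are excluded from the fit
  resp <- cell$response
  resp[1:10] <- NA
  expect_equal(fit_slope(cell$centroid, resp, 0.5), 0.6)
  expect_error(fit_slope(cell$centroid, rep(NA_real_, 50), 0.5),
               "non-missing")
  expect_error(fit_slope(rep(0.5, 10), runif(10), 0.5), "degenerate")
})

test_that("slope is equivariant under rescaling about the prior mean", {
  set.seed(21)
  cell <- sim_cell(80, 0.7, 0.1, 0.1, noise = 0.03)
  s0 <- fit_slope(cell$centroid, cell$response, 0.5)
  for (k in c(0.2, 2, 7)) {
    s <- fit_slope(0.5 + k * (cell$centroid - 0.5),
                   0.5 + k * (cell$response - 0.5), 0.5)
    expect_equal(s, s0)
  }
})

test_that("slope estimates are consistent for noisy linear observers", {
  set.seed(77)
  for (w in c(0.2, 0.8)) {
    cell <- sim_cell(1e4, w, 0.1, 0.1, noise = 0.05)
    expect_equal(fit_slope(cell$centroid, cell$response, 0.5), w,
                 tolerance = 0.01 / w)
  }
})

test_that("bootstrap interval collapses for noiseless data and is stable", {
  cell <- sim_cell(60, 0.55, 0.1, 0.1)
  ci <- boot_slope_ci(cell$centroid, cell$response, 0.5, n_boot = 500,
                      seed = 1)
  expect_equal(unname(ci), c(0.55, 0.55))
  # determinism given seed, and stability when n_boot doubles
  set.seed(14)
  cell <- sim_cell(80, 0.6, 0.1, 0.1, noise = 0.04)
  ci1 <- boot_slope_ci(cell$centroid, cell$response, 0.5, 1000, seed = 2)
  expect_identical(ci1, boot_slope_ci(cell$centroid, cell$response, 0.5,
                                      1000, seed = 2))
  ci2 <- boot_slope_ci(cell$centroid, cell$response, 0.5, 2000, seed = 3)
  width <- ci1[["ci_high"]] - ci1[["ci_low"]]
  expect_lt(max(abs(ci2 - ci1)), 0.25 * width)
  expect_true(ci1[["ci_low"]] <= 0.6 && ci1[["ci_high"]] >= 0.55)
})

test_that("p(correct) counts timeouts as misses", {
  expect_equal(p_correct(c(TRUE, TRUE, TRUE)), 1)
  expect_equal(p_correct(c(NA, NA)), 0)
  expect_equal(p_correct(c(TRUE, FALSE, NA, TRUE)), 0.5)
  expect_error(p_correct(logical(0)), "no trials")
})

test_that("optimal-observer catch rate matches a direct posterior integral", {
  # narrow prior-narrow likelihood: simulate many trials of an optimal
  # noiseless observer and compare with an independent Monte-Carlo
  # integral of P(|posterior mean - target| <= net halfwidth)
  set.seed(55)
  n <- 1e5
  w <- optimal_slope(0.03, 0.025, 4)
  cell <- sim_cell(n, w, 0.03, 0.025)
  p_sim <- mean(abs(cell$response - cell$target) <= 0.01)
  # oracle: posterior mean error ~ N(0, w^2 sigma_l^2/n + (1-w)^2 sigma_s^2)
  # integrated directly from independent draws
  t2 <- rnorm(n, 0.5, 0.03)
  c2 <- t2 + rnorm(n, 0, 0.025 / 2)
  pm <- w * c2 + (1 - w) * 0.5
  p_mc <- mean(abs(pm - t2) <= 0.01)
  expect_equal(p_sim, p_mc, tolerance = 0.005 / p_mc)
})

test_that("estimation_fit returns a coherent per-cell model object", {
  tr <- simulate_cohort(n_per_group = 2, cp_spec = flat_spec(0.7),
                        td_spec = flat_spec(0.9), seed = 6)
  fit <- estimation_fit(tr, n_boot = 300, seed = 11)
  expect_s3_class(fit, "estimation_fit")
  expect_equal(nrow(fit$slopes), 4L * 6L)
  expect_true(all(fit$slopes$n_trials_used <= 80L))
  # CI brackets the point estimate
  expect_true(all(fit$slopes$ci_low <= fit$slopes$slope + 1e-12))
  expect_true(all(fit$slopes$ci_high >= fit$slopes$slope - 1e-12))
  # coef matrix: subjects x conditions
  cm <- coef(fit)
  expect_equal(dim(cm), c(4L, 6L))
  expect_equal(cm["TD01", "Wide-Medium"],
               fit$slopes$slope[fit$slopes$subject_id == "TD01" &
                                  fit$slopes$condition == "Wide-Medium"])
  # response decomposes into fit + residual on non-missing trials
  res <- residuals(fit)
  pred <- predict(fit)
  ok <- !is.na(tr$response)
  expect_equal(tr$response[ok], (pred + res)[ok])
  # summary and print run quietly
  expect_output(print(fit), "Estimation-slope fit")
  expect_output(print(summary(fit)), "p\\(correct\\)")
  # deterministic given the seed
  fit2 <- estimation_fit(tr, n_boot = 300, seed = 11)
  expect_identical(fit$slopes, fit2$slopes)
})

test_that("fitted slopes reproduce the optimal ordering across conditions", {
  spec <- flat_spec(scale = 1, jitter = 0, noise = 0.03)
  tr <- simulate_cohort(n_per_group = 4, cp_spec = spec, td_spec = spec,
                        seed = 30)
  fit <- estimation_fit(tr, n_boot = 0)
  mean_by_cond <- tapply(fit$slopes$slope, fit$slopes$condition, mean)
  cond <- conditions(default_design)
  ord_fit <- names(sort(mean_by_cond))
  ord_opt <- cond$condition[order(cond$optimal)]
  expect_equal(ord_fit, ord_opt)
})

test_that("bootstrap CIs from a fitted model cover the known weight", {
  # moderate check here (the full 500-subject calibration runs in the
  # acceptance suite): 100 subjects, one condition, noise 0.03
  set.seed(303)
  hits <- vapply(1:100, function(i) {
    cell <- sim_cell(80, 0.6, 0.1, 0.1, noise = 0.03)
    ci <- boot_slope_ci(cell$centroid, cell$response, 0.5, 1000,
                        seed = 7000 + i)
    ci[["ci_low"]] <= 0.6 && 0.6 <= ci[["ci_high"]]
  }, logical(1))
  expect_gte(mean(hits), 0.88)
})

test_that("simulate() regenerates cohorts from the fitted weights", {
  tr <- simulate_cohort(n_per_group = 2, cp_spec = flat_spec(0.8),
                        td_spec = flat_spec(0.8), seed = 17)
  fit <- estimation_fit(tr, n_boot = 0)
  sims <- simulate(fit, nsim = 2, seed = 23)
  expect_length(sims, 2L)
  expect_equal(nrow(sims[[1]]), nrow(tr))
  refit <- estimation_fit(sims[[1]], n_boot = 0)
  m <- merge(refit$slopes, fit$slopes, by = c("subject_id", "condition"))
  expect_lt(median(abs(m$slope.x - m$slope.y)), 0.1)
})
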