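test_that("decay-rate fit recovers a pure exponential exactly", {
  t <- c(0, 600, 1800, 3600)
  s <- exp(-0.001 * t)
  for (mode in c("through_origin", "free_intercept")) {
    est <- fit_decay_rate(t, s, mode = mode, temperature = 319.15)
    expect_equal(est$rate_k, 0.001, tolerance = 1e-12)
    expect_identical(est$shoulder_td, 0)
    expect_equal(est$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("free-intercept fit recovers rate and shoulder from delayed decay", {
  # points restricted to the decaying branch: x-intercept gives the delay
  t <- c(1000, 1500, 2500, 4000)
  s <- exp(-0.001 * (t - 1000))
  est <- fit_decay_rate(t, s, mode = "free_intercept")
  expect_equal(est$rate_k, 0.001, tolerance = 1e-9)
  expect_equal(est$shoulder_td, 1000, tolerance = 1e-6)

  # full grid including flat shoulder points: iterative trimming finds them
  tg <- 60 * c(3, 5, 10, 15, 20, 30, 45, 60)
  sg <- exp(-0.001 * pmax(0, tg - 1000))
  estg <- fit_decay_rate(tg, sg, mode = "free_intercept")
  expect_equal(estg$rate_k, 0.001, tolerance = 1e-9)
  expect_equal(estg$shoulder_td, 1000, tolerance = 1e-6)
})

test_that("decay-rate fit censors floor-clipped survival and rejects degenerate input", {
  # very deep kill: late points sit below the quantification floor
  t <- 60 * c(3, 5, 10, 15, 20, 30, 45, 60)
  k <- 6.96e-3
  s_true <- exp(-k * t)
  est <- fit_decay_rate(t, s_true, mode = "free_intercept")
  expect_equal(est$rate_k, k, tolerance = 1e-9)
  expect_lt(est$n_points, length(t))   # clipped tail excluded, not fitted

  expect_error(fit_decay_rate(t, rep(0.8, length(t))),
               class = "thermodose_degenerate_fit")
  expect_error(fit_decay_rate(c(1, 2), c(0.9, 0.8)),
               class = "thermodose_invalid_argument")
  expect_error(fit_decay_rate(t, -s_true), class = "thermodose_invalid_argument")
})

test_that("Arrhenius regression inverts rates generated from known coefficients", {
  temps <- c(315.65, 317.15, 319.15, 323.15)
  ests <- lapply(temps, function(temp)
    decay_rate_estimate(temp, k_direct(137.63, 383112, temp)))
  fit <- fit_arrhenius(ests)
  expect_equal(fit$params$activation_energy, 383112, tolerance = 1e-6)
  expect_equal(fit$params$ln_frequency_factor, 137.63, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # two points determine the line exactly
  fit2 <- fit_arrhenius(ests[c(1, 4)])
  expect_equal(fit2$params$activation_energy, 383112, tolerance = 1e-6)
  expect_identical(fit2$r_squared, 1)

  expect_error(fit_arrhenius(ests[1]), class = "thermodose_invalid_argument")
})

test_that("Arrhenius slope is unbiased under iid noise on ln k", {
  temps <- c(315.65, 317.15, 319.15, 323.15)
  k0 <- k_direct(137.63, 383112, temps)
  slopes <- with(list(), {
    set.seed(42)
    replicate(200, {
      ests <- Map(function(temp, k) decay_rate_estimate(temp, k * exp(rnorm(1, 0, 0.1))),
                  temps, k0)
      fit_arrhenius(ests)$params$activation_energy
    })
  })
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 383112), 3 * se)
})

test_that("delay line is recovered from per-temperature shoulders", {
  # exact line, no clamping: exact recovery
  ests <- lapply(c(314.65, 315.65, 316.65), function(temp)
    decay_rate_estimate(temp, 1e-4, shoulder_td = 254920 - 800 * temp))
  d <- fit_time_delay(ests)
  expect_equal(d$intercept_b, 254920, tolerance = 1e-9)
  expect_equal(d$slope_m, 800, tolerance = 1e-9)

  # third temperature clamped at zero: excluded from the regression,
  # line still recovered from the two observed shoulders
  ests_cl <- list(
    decay_rate_estimate(316.15, 1e-4, shoulder_td = 2000),
    decay_rate_estimate(317.15, 2e-4, shoulder_td = 1200),
    decay_rate_estimate(318.65, 4e-4, shoulder_td = 0))
  d2 <- fit_time_delay(ests_cl)
  expect_equal(d2$intercept_b, 254920, tolerance = 0.05 * 254920)
  expect_equal(d2$slope_m, 800, tolerance = 0.05 * 800)

  # all-zero shoulders: null model with a warning
  ests0 <- lapply(c(318, 320), function(temp)
    decay_rate_estimate(temp, 1e-3, shoulder_td = 0))
  expect_warning(d0 <- fit_time_delay(ests0), "zero")
  expect_identical(c(d0$slope_m, d0$intercept_b), c(0, 0))
  expect_true(isTRUE(attr(d0, "all_zero")))

  # a single positive shoulder is underdetermined
  ests1 <- list(decay_rate_estimate(316, 1e-4, shoulder_td = 1500),
                decay_rate_estimate(319, 1e-3, shoulder_td = 0))
  expect_error(fit_time_delay(ests1), class = "thermodose_invalid_argument")
})

test_that("delay line never predicts a positive delay at censored temperatures", {
  # noisy shoulders that would suggest a rising line: censored setpoints
  # (no observed shoulder) must pin the line at or below zero there
  ests <- list(
    decay_rate_estimate(315.65, 1e-4, shoulder_td = 800),
    decay_rate_estimate(317.15, 3e-4, shoulder_td = 1100),
    decay_rate_estimate(319.15, 1e-3, shoulder_td = 0),
    decay_rate_estimate(323.15, 6e-3, shoulder_td = 0))
  d <- fit_time_delay(ests)
  expect_gte(d$slope_m, 0)
  expect_lte(d$intercept_b - d$slope_m * 319.15, 1e-9)
  expect_gt(d$intercept_b - d$slope_m * 315.65, 0)
})

test_that("two-state bilinear regression matches the normal-equations solve", {
  truth <- two_state_params(alpha = 0.005, beta = 300, gamma = 0.94)
  # grid chosen so every logit stays inside the clipping range
  grid <- expand.grid(temperature = c(317.15, 318.15, 319.15, 320.15),
                      duration = c(60, 240, 480, 720, 960, 1200))
  grid$survival <- two_state_survival(grid$duration, grid$temperature, truth)
  fit <- fit_two_state(grid)
  expect_equal(fit$params$alpha, 0.005, tolerance = 1e-9)
  expect_equal(fit$params$beta, 300, tolerance = 1e-9)
  expect_equal(fit$params$gamma, 0.94, tolerance = 1e-9)
  expect_equal(fit$report$rmse_pct, 0, tolerance = 1e-7)

  # independent oracle: explicit 3x3 normal equations on the logits
  X <- cbind(1, grid$temperature, grid$duration)
  y <- qlogis(pmin(pmax(grid$survival, 1e-4), 1 - 1e-4))
  beta_hat <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$params$gamma, beta_hat[2], tolerance = 1e-9)
  expect_equal(-fit$params$alpha, beta_hat[3], tolerance = 1e-9)
  expect_equal(-fit$params$beta, beta_hat[1], tolerance = 1e-9)
})

test_that("two-state fit handles boundary survival and degenerate designs", {
  # survival 1/2 everywhere: zero logits, all coefficients zero
  g <- expand.grid(temperature = c(315, 319), duration = c(300, 900))
  g$survival <- 0.5
  fit <- fit_two_state(g)
  expect_equal(c(fit$params$alpha, fit$params$beta, fit$params$gamma),
               c(0, 0, 0), tolerance = 1e-12)

  # survival of exactly 1 is clipped, not dropped
  g2 <- expand.grid(temperature = c(315, 317, 319), duration = c(300, 900, 1800))
  g2$survival <- two_state_survival(g2$duration, g2$temperature,
                                    two_state_params(0.002, 290, 0.9))
  g2$survival[1] <- 1.0
  fit2 <- fit_two_state(g2)
  expect_equal(nrow(fit2$report$residuals), nrow(g2))

  # rank-deficient design (single temperature after expansion)
  g3 <- data.frame(temperature = 316, duration = c(1, 2, 3, 4),
                   survival = c(0.9, 0.8, 0.7, 0.6))
  expect_error(fit_two_state(g3), class = "thermodose_invalid_argument")
})

test_that("R_CEM from Arrhenius rates agrees with the closed-form isoeffect ratio", {
  temps <- celsius_to_kelvin(c(44, 46, 48, 50))
  ests <- lapply(temps, function(temp)
    decay_rate_estimate(temp, k_direct(137.63, 383112, temp)))
  r_fit <- fit_rcem(ests)
  tbar <- mean(temps)
  r_closed <- exp(-383112 / (8.314 * tbar * (tbar + 1)))
  expect_equal(r_fit, r_closed, tolerance = 0.05)
  expect_true(r_fit > 0 && r_fit < 1)

  # two temperatures 1 K apart: R is exactly the rate ratio
  e2 <- lapply(c(319.15, 320.15), function(temp)
    decay_rate_estimate(temp, k_direct(137.63, 383112, temp)))
  expect_equal(fit_rcem(e2),
               k_direct(137.63, 383112, 319.15) / k_direct(137.63, 383112, 320.15),
               tolerance = 1e-9)

  # temperature-independent rates: R = 1
  eflat <- lapply(c(318.15, 321.15), function(temp) decay_rate_estimate(temp, 5e-4))
  expect_equal(fit_rcem(eflat), 1, tolerance = 1e-12)

  # below-break temperatures are excluded by default
  e_mixed <- c(lapply(c(313.15, 314.15), function(temp) decay_rate_estimate(temp, 1e-6)),
               e2)
  expect_equal(fit_rcem(e_mixed), fit_rcem(e2), tolerance = 1e-12)
  expect_error(fit_rcem(e2[1]), class = "thermodose_invalid_argument")
})

test_that("model evaluation reports pooled RMSE in percentage points", {
  tr <- kpc_truth()
  ds <- generate_viability_dataset(tr, study_setpoints(), study_durations(),
                                   recovery_scale = c("24" = 1),
                                   noise = noise_spec(0, 0, 0))
  # the generating model predicts its own data: RMSE 0
  rep0 <- evaluate_fit(ds, "arrhenius_delayed", tr)
  expect_equal(rep0$rmse_pct, 0, tolerance = 1e-9)

  # constant +10-point offset: RMSE exactly 10
  ds_off <- ds
  wells <- grep("^well_", names(ds_off))
  for (w in wells) ds_off[[w]] <- ds_off[[w]] + 0.1
  ds_off$mean_survival <- ds_off$mean_survival + 0.1
  rep10 <- evaluate_fit(ds_off, "arrhenius_delayed", tr)
  expect_equal(rep10$rmse_pct, 10, tolerance = 1e-9)

  # invariant to condition ordering
  perm <- sample(nrow(ds))
  ds_perm <- ds[perm, ]
  class(ds_perm) <- class(ds)
  rep_p <- evaluate_fit(ds_perm, "arrhenius_delayed", tr)
  expect_equal(rep_p$rmse_pct, rep0$rmse_pct, tolerance = 1e-12)

  expect_error(evaluate_fit(ds[0, ], "arrhenius", tr$arrhenius),
               class = "thermodose_invalid_argument")
})

test_that("delayed model outperforms the simple model on shoulder-bearing data", {
  tr <- kpc_truth()
  for (s in 1:5) {
    ds <- generate_viability_dataset(tr, study_setpoints(), study_durations(),
                                     recovery_scale = c("24" = 1),
                                     noise = noise_spec(seed = s))
    rep <- run_analysis(ds)
    mc <- rep$model_comparison
    expect_lte(mc$rmse_pct[mc$model == "arrhenius_delayed"],
               mc$rmse_pct[mc$model == "arrhenius"])
  }
})
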