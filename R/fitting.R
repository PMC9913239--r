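#' Per-temperature decay-rate estimate
#'
#' Container for the isothermal survival fit S = exp(-k (t - t_d)):
#' the decay rate, the shoulder delay implied by the fit's intercept,
#' and fit diagnostics.
#'
#' @param temperature kelvin.
#' @param rate_k s^-1, > 0.
#' @param shoulder_td seconds, >= 0.
#' @param r_squared coefficient of determination in [0, 1].
#' @param n_points number of observations used in the final regression.
#' @return an object of class `decay_rate_estimate`.
#' @export
decay_rate_estimate <- function(temperature, rate_k, shoulder_td = 0,
                                r_squared = NA_real_, n_points = NA_integer_) {
  if (!is.finite(rate_k) || rate_k <= 0) stop_invalid("rate_k must be > 0")
  if (shoulder_td < 0) stop_invalid("shoulder_td must be >= 0")
  structure(list(temperature = as.numeric(temperature),
                 rate_k = as.numeric(rate_k),
                 shoulder_td = as.numeric(shoulder_td),
                 r_squared = as.numeric(r_squared),
                 n_points = as.integer(n_points)),
            class = "decay_rate_estimate")
}

#' @export
print.decay_rate_estimate <- function(x, ...) {
  cat(sprintf("decay_rate_estimate: T = %.2f K, k = %.4g /s, t_d = %.4g s (R2 = %.4f, n = %d)\n",
              x$temperature, x$rate_k, x$shoulder_td, x$r_squared, x$n_points))
  invisible(x)
}

## collect a list of decay_rate_estimate into a data.frame
estimates_frame <- function(estimates) {
  if (is.data.frame(estimates)) return(estimates)
  if (inherits(estimates, "decay_rate_estimate")) estimates <- list(estimates)
  do.call(rbind, lapply(estimates, function(e)
    data.frame(temperature = e$temperature, rate_k = e$rate_k,
               shoulder_td = e$shoulder_td, r_squared = e$r_squared,
               n_points = e$n_points)))
}

#' Fit an exponential decay rate to isothermal survival data
#'
#' Linear regression of ln S on exposure time; the slope gives -k.
#' In `free_intercept` mode the fit also yields a shoulder delay: the
#' positive x-intercept (intercept / k) of the fitted line, reported as
#' `shoulder_td` (0 when the intercept is non-positive). In
#' `through_origin` mode the line is forced through S(0) = 1 (no
#' intercept), the convention of the simple Arrhenius analysis arm.
#'
#' Survival values are clipped to `[clip_floor, clip_ceiling]` before
#' taking logs; control normalization can push survival slightly above
#' 1, and such points are retained (clipped at 1.5) rather than
#' discarded. Observations sitting at the floor are treated as censored
#' (below the assay's resolvable range) and excluded from the
#' regression. In `free_intercept` mode, points inside the fitted
#' shoulder (t < t_d) are excluded by iterating the fit until the
#' retained set stabilizes, since pre-delay observations carry no rate
#' information.
#'
#' @param durations exposure times, seconds; >= 3 distinct values.
#' @param survival surviving fractions in (0, 1.5].
#' @param mode `"free_intercept"` (default) or `"through_origin"`.
#' @param clip_floor,clip_ceiling clipping bounds for survival.
#' @param temperature optional kelvin temperature stored in the result.
#' @param max_iter maximum shoulder-trimming iterations.
#' @return a [decay_rate_estimate].
#' @examples
#' t <- c(0, 600, 1800, 3600)
#' fit_decay_rate(t, exp(-0.001 * t), mode = "through_origin")
#' @export
fit_decay_rate <- function(durations, survival,
                           mode = c("free_intercept", "through_origin"),
                           clip_floor = 1e-4, clip_ceiling = 1.5,
                           temperature = NA_real_, max_iter = 20L) {
  mode <- match.arg(mode)
  if (length(durations) != length(survival))
    stop_invalid("durations and survival must have the same length")
  if (length(unique(durations)) < 3L)
    stop_invalid("need at least 3 distinct durations")
  if (any(!is.finite(survival)) || any(survival <= 0))
    stop_invalid("survival values must be finite and > 0")
  s <- pmin(pmax(survival, clip_floor), clip_ceiling)
  keep <- s > clip_floor            # floor-clipped points are censored
  if (sum(keep) < 2L)
    stop_degenerate("fewer than 2 observations above the survival floor")
  t <- as.numeric(durations)
  y <- log(s)
  if (length(unique(s[keep])) == 1L)
    stop_degenerate("all survival values identical; decay rate undetermined")

  if (mode == "through_origin") {
    fit <- lm(y ~ 0 + t, subset = keep)
    k <- -coef(fit)[[1]]
    if (!is.finite(k) || k <= 0)
      stop_degenerate("non-decaying survival; fitted rate not positive")
    return(decay_rate_estimate(temperature, k, shoulder_td = 0,
                               r_squared = suppressWarnings(summary(fit)$r.squared),
                               n_points = sum(keep)))
  }

  active <- keep
  best <- NULL
  for (iter in seq_len(max_iter)) {
    fit <- lm(y ~ t, subset = active)
    sl <- coef(fit)[[2]]
    # trimming must never destroy identifiability: if the reduced set
    # is no longer decaying, stand on the previous iterate
    if (!is.finite(sl) || sl >= 0) break
    best <- list(fit = fit, active = active)
    k <- -sl
    td <- max(0, coef(fit)[[1]] / k)
    nxt <- keep & t >= td
    if (sum(nxt) < 2L || identical(nxt, active)) break
    active <- nxt
  }
  if (is.null(best))
    stop_degenerate("non-decaying survival; fitted rate not positive")
  fit <- best$fit
  active <- best$active
  k <- -coef(fit)[[2]]
  td <- max(0, coef(fit)[[1]] / k)
  # a delay shorter than the earliest measured exposure cannot be
  # distinguished from zero: censor it rather than report spurious
  # sub-resolution shoulders (tolerance keeps delays at the boundary)
  if (td < (1 - 1e-6) * min(t[t > 0])) td <- 0
  decay_rate_estimate(temperature, k, shoulder_td = td,
                      r_squared = suppressWarnings(summary(fit)$r.squared),
                      n_points = sum(active))
}

#' Fit Arrhenius coefficients from per-temperature rates
#'
#' Ordinary least squares of ln k on 1/T: the slope is -Ea/R and the
#' intercept is ln A.
#'
#' @param estimates list of [decay_rate_estimate] at >= 2 distinct
#'   temperatures.
#' @param gas_constant J K^-1 mol^-1.
#' @return list with `params` ([arrhenius_params]) and `r_squared`.
#' @export
fit_arrhenius <- function(estimates, gas_constant = 8.314) {
  d <- estimates_frame(estimates)
  if (is.null(d) || length(unique(d$temperature)) < 2L)
    stop_invalid("need decay-rate estimates at >= 2 distinct temperatures")
  x <- 1 / d$temperature
  y <- log(d$rate_k)
  fit <- lm(y ~ x)
  ea <- -coef(fit)[[2]] * gas_constant
  r2 <- if (nrow(d) == 2L) 1 else suppressWarnings(summary(fit)$r.squared)
  list(params = arrhenius_params(coef(fit)[[1]], ea, gas_constant),
       r_squared = r2)
}

#' Fit shoulder-delay coefficients from per-temperature delays
#'
#' Least squares of the estimated shoulder delays on temperature:
#' t_d = b - m T, so b is the intercept and m the negated slope
#' (clamped to >= 0). Estimates whose delay was clamped at zero are
#' censored rather than observed: they do not enter the regression as
#' data points, but they bound the line from above, since the true
#' delay at such a temperature is non-positive. When the unconstrained
#' line has the wrong sign or predicts a positive delay at a
#' zero-delay temperature, the line is refit through
#' (T_c, 0) at the coolest censored temperature T_c, i.e. the steepest
#' delay line consistent with the censoring.
#'
#' @param estimates list of [decay_rate_estimate]; at least two must
#'   carry a positive `shoulder_td`.
#' @return a [delay_params]; when every delay is zero, returns
#'   `delay_params(0, 0)` with attribute `all_zero = TRUE` and a
#'   warning.
#' @export
fit_time_delay <- function(estimates) {
  d <- estimates_frame(estimates)
  if (is.null(d) || nrow(d) < 2L)
    stop_invalid("need >= 2 decay-rate estimates")
  pos <- d$shoulder_td > 0
  if (!any(pos)) {
    warning("all shoulder delays are zero; returning a null delay model")
    out <- delay_params(0, 0)
    attr(out, "all_zero") <- TRUE
    return(out)
  }
  if (sum(pos) < 2L)
    stop_invalid("only one positive shoulder delay; delay line is underdetermined")
  fit <- lm(shoulder_td ~ temperature, data = d[pos, ])
  m <- -coef(fit)[[2]]
  b <- coef(fit)[[1]]
  zero_temp <- d$temperature[!pos]
  violates <- length(zero_temp) > 0 && any(b - m * zero_temp > 0)
  if (!is.finite(m) || m < 0 || violates) {
    if (length(zero_temp) > 0) {
      # anchor the line at zero delay for the coolest censored setpoint
      t_c <- min(zero_temp)
      x <- t_c - d$temperature[pos]
      m <- max(0, sum(d$shoulder_td[pos] * x) / sum(x^2))
      b <- m * t_c
    } else {
      m <- 0
      b <- mean(d$shoulder_td[pos])
    }
  }
  delay_params(m, b)
}

#' Fit the two-state model by bilinear least squares
#'
#' Linear regression of logit(C) on temperature and exposure time:
#' logit C = gamma T - beta - alpha tau, estimated by ordinary least
#' squares (coefficients gamma and -alpha, intercept -beta). Survival
#' is clipped to `[eps, 1 - eps]` before the logit; values of exactly
#' 1 (or above) are clipped, never dropped.
#'
#' @param conditions data.frame with columns `temperature` (kelvin),
#'   `duration` (seconds), `survival` (fraction); >= 4 rows spanning
#'   >= 2 temperatures and >= 2 durations.
#' @param eps logit clipping bound, default 1e-4.
#' @return list with `params` ([two_state_params]) and `report` (a
#'   `fit_report`, see [evaluate_fit()]).
#' @export
fit_two_state <- function(conditions, eps = 1e-4) {
  req <- c("temperature", "duration", "survival")
  if (!all(req %in% names(conditions)))
    stop_invalid("conditions needs columns temperature, duration, survival")
  if (nrow(conditions) < 4L ||
      length(unique(conditions$temperature)) < 2L ||
      length(unique(conditions$duration)) < 2L)
    stop_invalid("need >= 4 conditions spanning >= 2 temperatures and >= 2 durations")
  s <- pmin(pmax(conditions$survival, eps), 1 - eps)
  y <- qlogis(s)
  fit <- lm(y ~ temperature + duration, data = conditions)
  cf <- coef(fit)
  if (any(is.na(cf)))
    stop_degenerate("rank-deficient design; two-state coefficients not identifiable")
  params <- two_state_params(alpha = -cf[["duration"]],
                             beta = -cf[["(Intercept)"]],
                             gamma = cf[["temperature"]])
  pred <- two_state_survival(conditions$duration, conditions$temperature, params)
  resid <- data.frame(temperature = conditions$temperature,
                      duration = conditions$duration,
                      measured_pct = 100 * s,
                      predicted_pct = 100 * pred)
  resid$residual_pct <- resid$predicted_pct - resid$measured_pct
  report <- fit_report("two_state", params,
                       r_squared = suppressWarnings(summary(fit)$r.squared),
                       rmse_pct = sqrt(mean(resid$residual_pct^2)),
                       residuals = resid)
  list(params = params, report = report)
}

#' Estimate the isoeffect factor R_CEM from Arrhenius kinetics
#'
#' Under first-order kinetics the exposure time needed for a fixed
#' isoeffect is proportional to 1/k(T), so
#' ln t_iso(T) = const - ln k(T) and the per-degree isoeffect factor is
#' R = exp(slope) from an OLS fit of ln t_iso on temperature in degC.
#' For pure Arrhenius rates the closed form is
#' R(T) = exp(-Ea / (R_gas T (T + 1))).
#'
#' @param estimates list of [decay_rate_estimate].
#' @param above_break_only use only temperatures strictly above the
#'   break (default TRUE, matching the convention that R above 43 degC
#'   is the quantity of interest).
#' @param break_temperature kelvin, default 316.15.
#' @return the estimated R (numeric scalar in (0, 1) for heat-sensitive
#'   kinetics).
#' @export
fit_rcem <- function(estimates, above_break_only = TRUE,
                     break_temperature = 316.15) {
  d <- estimates_frame(estimates)
  if (!is.null(d) && above_break_only)
    d <- d[d$temperature > break_temperature, , drop = FALSE]
  if (is.null(d) || length(unique(d$temperature)) < 2L)
    stop_invalid("need rates at >= 2 usable temperatures")
  x <- kelvin_to_celsius(d$temperature)
  y <- -log(d$rate_k)          # ln t_iso up to an additive constant
  fit <- lm(y ~ x)
  exp(coef(fit)[[2]])
}

## FitReport constructor (internal)
fit_report <- function(model_name, params, r_squared, rmse_pct, residuals,
                       rmse_by_cell_line = NULL) {
  structure(list(model_name = model_name, params = params,
                 r_squared = r_squared, rmse_pct = rmse_pct,
                 rmse_by_cell_line = rmse_by_cell_line,
                 residuals = residuals),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("fit_report [%s]: RMSE = %.4g%%, R2 = %.4f, %d conditions\n",
              x$model_name, x$rmse_pct,
              if (is.finite(x$r_squared)) x$r_squared else NA,
              nrow(x$residuals)))
  invisible(x)
}

#' Evaluate a fitted model against a viability dataset
#'
#' Predicts the surviving percentage for every condition in the dataset
#' from the forward model at that condition's setpoint and duration, and
#' reports the root-mean-square error in percentage points, pooled
#' across conditions and cell lines (with a per-cell-line breakdown).
#'
#' @param dataset a `viability_dataset` (see
#'   [generate_viability_dataset()] / [read_viability()]).
#' @param model `"arrhenius"`, `"arrhenius_delayed"` or `"two_state"`.
#' @param params model parameters: an [arrhenius_params] for
#'   `"arrhenius"`; a list `list(arrhenius =, delay =)` for
#'   `"arrhenius_delayed"`; a [two_state_params] for `"two_state"`.
#'   Alternatively a named list of such blocks, one per cell line.
#' @return a `fit_report` with `rmse_pct` (pooled),
#'   `rmse_by_cell_line`, squared correlation `r_squared` between
#'   predicted and measured percentages, and a per-condition residual
#'   table.
#' @export
evaluate_fit <- function(dataset,
                         model = c("arrhenius", "arrhenius_delayed", "two_state"),
                         params) {
  model <- match.arg(model)
  d <- as.data.frame(dataset)
  if (nrow(d) == 0L) stop_invalid("empty dataset")
  lines <- unique(d$cell_line)
  per_line <- !is.null(names(params)) && all(lines %in% names(params))
  pred <- numeric(nrow(d))
  for (i in seq_len(nrow(d))) {
    p <- if (per_line) params[[d$cell_line[i]]] else params
    pred[i] <- predict_survival(model, p, d$setpoint[i], d$duration[i])
  }
  measured <- 100 * d$mean_survival
  resid <- data.frame(cell_line = d$cell_line,
                      setpoint = d$setpoint, duration = d$duration,
                      recovery_h = d$recovery_h,
                      measured_pct = measured, predicted_pct = 100 * pred)
  resid$residual_pct <- resid$predicted_pct - resid$measured_pct
  by_line <- vapply(split(resid$residual_pct, resid$cell_line),
                    function(r) sqrt(mean(r^2)), numeric(1))
  r2 <- if (stats::sd(measured) > 0 && stats::sd(pred) > 0)
    stats::cor(measured, 100 * pred)^2 else NA_real_
  fit_report(model, params, r_squared = r2,
             rmse_pct = sqrt(mean(resid$residual_pct^2)),
             residuals = resid, rmse_by_cell_line = by_line)
}

## isothermal forward prediction shared by evaluate_fit and the pipeline
predict_survival <- function(model, params, temperature, duration) {
  switch(model,
    arrhenius = {
      p <- if (inherits(params, "arrhenius_params")) params else params$arrhenius
      exp(-rate_constant(p, temperature) * duration)
    },
    arrhenius_delayed = {
      td <- time_delay(params$delay, temperature)
      exp(-rate_constant(params$arrhenius, temperature) * max(0, duration - td))
    },
    two_state = {
      p <- if (inherits(params, "two_state_params")) params else params$two_state
      two_state_survival(duration, temperature, p)
    },
    stop_invalid(sprintf("unknown model '%s'", model)))
}
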