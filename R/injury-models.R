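#' Arrhenius rate constant
#'
#' First-order injury rate k(T) = exp(ln A - Ea / (R T)). Strictly
#' increasing in temperature.
#'
#' @param params an [arrhenius_params].
#' @param temperature kelvin; vectorized.
#' @return rate in s^-1.
#' @examples
#' kpc <- arrhenius_params(137.63, 383112)
#' rate_constant(kpc, 323.15)   # ~6.96e-3 /s at 50 degC
#' @export
rate_constant <- function(params, temperature) {
  stopifnot(inherits(params, "arrhenius_params"))
  if (any(temperature <= 0)) stop_invalid("temperature must be > 0 K")
  exp(params$ln_frequency_factor -
        params$activation_energy / (params$gas_constant * temperature))
}

#' Shoulder time delay
#'
#' Temperature-dependent delay before injury begins,
#' t_d(T) = max(0, b - m T). The linear form goes negative above
#' T = b / m; a negative delay is physically meaningless, so it is
#' clamped to zero (injury starts immediately).
#'
#' @param delay a [delay_params].
#' @param temperature kelvin; vectorized.
#' @return delay in seconds, >= 0.
#' @examples
#' kpc_d <- delay_params(800, 254920)
#' time_delay(kpc_d, 316.15)  # 2000 s at 43 degC
#' time_delay(kpc_d, 320)     # 0: clamped
#' @export
time_delay <- function(delay, temperature) {
  stopifnot(inherits(delay, "delay_params"))
  if (any(temperature <= 0)) stop_invalid("temperature must be > 0 K")
  pmax(0, delay$intercept_b - delay$slope_m * temperature)
}

## DamageResult constructor (internal): survival and injury probability
## derive deterministically from omega
damage_result <- function(times, omega) {
  omega <- pmax(omega, 0)
  structure(list(times = times,
                 omega = omega,
                 survival_fraction = exp(-omega),
                 injury_probability_pct = 100 * (1 - exp(-omega))),
            class = "damage_result")
}

#' @export
print.damage_result <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("damage_result: %d samples, final omega = %.6g, final survival = %.4g%%\n",
              n, x$omega[n], 100 * x$survival_fraction[n]))
  invisible(x)
}

#' @export
as.data.frame.damage_result <- function(x, ...) {
  data.frame(time_s = x$times, omega = x$omega,
             survival_fraction = x$survival_fraction,
             injury_probability_pct = x$injury_probability_pct)
}

## cumulative trapezoid of y over t, starting at 0
cumtrapz <- function(t, y) {
  n <- length(t)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(t)))
}

#' Arrhenius damage integral
#'
#' Cumulative thermal damage Omega(t) = integral_0^t k(T(tau)) dtau,
#' evaluated by the trapezoidal rule on the profile's samples. The
#' surviving fraction is exp(-Omega) and the injury probability is
#' 100 (1 - exp(-Omega)).
#'
#' @param profile a [temperature_profile].
#' @param params an [arrhenius_params].
#' @return a `damage_result` with fields `times`, `omega`,
#'   `survival_fraction`, `injury_probability_pct`, one value per
#'   profile sample.
#' @examples
#' kpc <- arrhenius_params(137.63, 383112)
#' p <- make_constant_profile(323.15, 600, 1)
#' damage_integral(p, kpc)   # Omega ~ 4.18, survival ~ 1.5%
#' @export
damage_integral <- function(profile, params) {
  stopifnot(inherits(profile, "temperature_profile"))
  k <- rate_constant(params, profile$temperatures)
  damage_result(profile$times, cumtrapz(profile$times, k))
}

#' Time-delayed Arrhenius damage integral
#'
#' The shoulder-corrected model: no damage accumulates until the delay
#' is complete, after which the ordinary Arrhenius integral runs. At
#' constant temperature the delay completes at t = t_d(T) and
#' Omega(t) = k(T) (t - t_d) afterwards. For time-varying profiles the
#' completion time is found with a normalized delay accumulator
#' xi(t) = integral_0^t dtau / t_d(T(tau)): the delay is complete once
#' xi reaches 1, and instants where t_d(T) = 0 complete it immediately.
#' This rule is continuous in the profile and reduces exactly to the
#' constant-temperature definition.
#'
#' @param profile a [temperature_profile].
#' @param params an [arrhenius_params].
#' @param delay a [delay_params].
#' @return a `damage_result` (see [damage_integral()]).
#' @export
damage_integral_delayed <- function(profile, params, delay) {
  stopifnot(inherits(profile, "temperature_profile"))
  t <- profile$times
  temp <- profile$temperatures
  n <- length(t)
  td <- time_delay(delay, temp)
  t_star <- delay_completion_time(t, td)
  if (is.na(t_star) || t_star >= t[n])
    return(damage_result(t, rep(0, n)))
  # integrate k from t_star on an augmented grid containing t_star
  after <- t > t_star
  t_aug <- c(t_star, t[after])
  temp_aug <- c(approx(t, temp, xout = t_star)$y, temp[after])
  k_aug <- rate_constant(params, temp_aug)
  om_aug <- cumtrapz(t_aug, k_aug)
  omega <- numeric(n)
  omega[after] <- om_aug[-1]
  damage_result(t, omega)
}

## first time at which the normalized delay accumulator reaches 1, or at
## which t_d hits 0; NA if the delay never completes within the profile
delay_completion_time <- function(t, td) {
  n <- length(t)
  if (td[1] == 0) return(t[1])
  xi <- 0
  for (i in seq_len(n - 1L)) {
    if (td[i + 1L] == 0) return(t[i + 1L])
    g_mean <- (1 / td[i] + 1 / td[i + 1L]) / 2
    dt <- t[i + 1L] - t[i]
    inc <- g_mean * dt
    if (xi + inc >= 1) return(t[i] + (1 - xi) / g_mean)
    xi <- xi + inc
  }
  NA_real_
}

#' Two-state logistic survival
#'
#' Viable fraction under the two-state model:
#' C(tau, T) = logistic(gamma T - beta - alpha tau). Strictly
#' decreasing in exposure time when alpha > 0 and lies in (0, 1).
#'
#' @param exposure_time tau, seconds, >= 0; vectorized.
#' @param temperature kelvin; vectorized (recycled against
#'   `exposure_time`).
#' @param params a [two_state_params].
#' @return surviving fraction in (0, 1).
#' @examples
#' ts <- two_state_params(alpha = 0.01, beta = 320, gamma = 1)
#' two_state_survival(100, 318, ts)  # logistic(-3) ~ 0.047
#' @export
two_state_survival <- function(exposure_time, temperature, params) {
  stopifnot(inherits(params, "two_state_params"))
  if (any(exposure_time < 0)) stop_invalid("exposure_time must be >= 0")
  plogis(params$gamma * temperature - params$beta -
           params$alpha * exposure_time)
}

#' CEM43 thermal isoeffective dose
#'
#' Cumulative equivalent minutes at 43 degC for an arbitrary profile:
#' t43 = sum_i dt_i R^(43 - T_i), with dt_i in minutes, T_i the
#' midpoint temperature (degC) of each sampling interval, and
#' R = `r_above` when the midpoint exceeds the break temperature
#' (strict >) else `r_below`. Heating at exactly 43 degC for ten
#' minutes yields exactly ten equivalent minutes.
#'
#' @param profile a [temperature_profile].
#' @param dose a [dose_params].
#' @return equivalent minutes at 43 degC (numeric scalar).
#' @examples
#' cem43(make_constant_profile(celsius_to_kelvin(46), 600, 1))  # 80 min
#' @export
cem43 <- function(profile, dose = dose_params()) {
  stopifnot(inherits(profile, "temperature_profile"),
            inherits(dose, "dose_params"))
  t <- profile$times
  temp <- profile$temperatures
  n <- length(t)
  dt_min <- diff(t) / 60
  mid_k <- (temp[-1] + temp[-n]) / 2
  r <- ifelse(mid_k > dose$break_temperature, dose$r_above, dose$r_below)
  sum(dt_min * r^(43 - kelvin_to_celsius(mid_k)))
}
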