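#' Time-temperature profiles
#'
#' A `temperature_profile` is the sampled trajectory T(t) delivered to a
#' cell culture: times in seconds starting at 0, temperatures in kelvin.
#' It is the domain of every forward model in the package (damage
#' integrals, CEM43).
#'
#' @param times numeric, seconds; strictly increasing, first element 0.
#' @param temperatures numeric, kelvin; one per time point, finite and
#'   positive.
#' @param label free-text description carried through to reports.
#' @return an object of class `temperature_profile` with fields `times`,
#'   `temperatures`, `label`.
#' @examples
#' temperature_profile(c(0, 30, 60), c(310.15, 315.15, 319.15), "ramp")
#' @export
temperature_profile <- function(times, temperatures, label = "") {
  times <- as.numeric(times)
  temperatures <- as.numeric(temperatures)
  if (length(times) < 2L)
    stop_invalid("a temperature profile needs at least 2 samples")
  if (length(times) != length(temperatures))
    stop_invalid("times and temperatures must have the same length")
  if (times[1L] != 0)
    stop_invalid("profile must start at time 0")
  if (any(diff(times) <= 0))
    stop_invalid("profile times must be strictly increasing")
  if (any(!is.finite(temperatures)) || any(temperatures <= 0))
    stop_invalid("temperatures must be finite and positive (kelvin)")
  structure(list(times = times, temperatures = temperatures,
                 label = as.character(label)[1L]),
            class = "temperature_profile")
}

#' @export
print.temperature_profile <- function(x, ...) {
  cat(sprintf("temperature_profile%s: %d samples over %.6g s, %.2f-%.2f K\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              length(x$times), max(x$times),
              min(x$temperatures), max(x$temperatures)))
  invisible(x)
}

#' @export
format.temperature_profile <- function(x, ...) {
  sprintf("temperature_profile(%d samples, %g s)", length(x$times), max(x$times))
}

## uniform grid over [0, duration]; the exact endpoint is appended when
## duration is not a multiple of step so integrals cover the full exposure
time_grid <- function(duration, step) {
  g <- seq(0, duration, by = step)
  if (g[length(g)] < duration) g <- c(g, duration)
  g
}

#' Constant-temperature (isothermal) profile
#'
#' The idealized exposure underlying isothermal survival fits: the
#' culture sits at one temperature for the whole duration.
#'
#' @param temperature kelvin.
#' @param duration seconds, > 0.
#' @param step sampling step in seconds, > 0. When `duration` is not a
#'   multiple of `step` the exact endpoint is appended as a final sample.
#' @return a [temperature_profile].
#' @examples
#' make_constant_profile(316.15, 600, 1)
#' @export
make_constant_profile <- function(temperature, duration, step = 1) {
  if (!is.finite(duration) || duration <= 0) stop_invalid("duration must be > 0")
  if (!is.finite(step) || step <= 0) stop_invalid("step must be > 0")
  t <- time_grid(duration, step)
  temperature_profile(t, rep(temperature, length(t)),
                      label = sprintf("constant %.6g K", temperature))
}

#' Water-bath transient specification
#'
#' Describes the three phases of a water-bath hyperthermia exposure as
#' characterized on dummy plates with embedded thermocouples: a ramp from
#' baseline (37 degC incubator) to the setpoint, a constant hold, and a
#' cool-down back toward baseline.
#'
#' @param target_temperature setpoint, kelvin.
#' @param ramp_time seconds to reach the setpoint (linear ramp), >= 0.
#' @param hold_time seconds at the setpoint, >= 0.
#' @param cooldown_time seconds of cool-down, >= 0. The cool-down is an
#'   exponential relaxation toward baseline with time constant
#'   `cooldown_time / 3`, so the profile is within 5% of baseline by the
#'   end of the phase.
#' @param baseline_temperature kelvin, default 310.15 (37 degC).
#' @param sampling_step seconds between samples, > 0.
#' @return an object of class `transient_spec`.
#' @export
transient_spec <- function(target_temperature, ramp_time, hold_time,
                           cooldown_time, baseline_temperature = BODY_TEMP_K,
                           sampling_step = 1) {
  dur <- c(ramp_time, hold_time, cooldown_time)
  if (any(!is.finite(dur)) || any(dur < 0))
    stop_invalid("ramp, hold and cool-down durations must be >= 0")
  if (sum(dur) <= 0)
    stop_invalid("at least one phase must have positive duration")
  if (!is.finite(sampling_step) || sampling_step <= 0)
    stop_invalid("sampling_step must be > 0")
  structure(list(baseline_temperature = baseline_temperature,
                 target_temperature = target_temperature,
                 ramp_time = ramp_time, hold_time = hold_time,
                 cooldown_time = cooldown_time,
                 sampling_step = sampling_step),
            class = "transient_spec")
}

#' Synthesize a water-bath transient profile
#'
#' Builds the piecewise profile described by a [transient_spec]: linear
#' ramp baseline to target over `ramp_time`, exact hold at the target
#' for `hold_time`, then exponential decay back toward baseline with
#' time constant `cooldown_time / 3`. The hold phase equals the setpoint
#' exactly; thermocouple-style measurement noise belongs to the
#' synthetic-data generator, not here.
#'
#' @param spec a [transient_spec].
#' @return a [temperature_profile].
#' @examples
#' sp <- transient_spec(celsius_to_kelvin(46), ramp_time = 75,
#'                      hold_time = 2400, cooldown_time = 267)
#' make_transient_profile(sp)
#' @export
make_transient_profile <- function(spec) {
  stopifnot(inherits(spec, "transient_spec"))
  total <- spec$ramp_time + spec$hold_time + spec$cooldown_time
  t <- time_grid(total, spec$sampling_step)
  b <- spec$baseline_temperature
  tg <- spec$target_temperature
  r <- spec$ramp_time
  h <- spec$hold_time
  cd <- spec$cooldown_time
  temp <- numeric(length(t))
  ramp_ix <- t < r
  temp[ramp_ix] <- b + (tg - b) * t[ramp_ix] / r
  hold_ix <- t >= r & t <= r + h
  temp[hold_ix] <- tg
  cool_ix <- t > r + h
  if (any(cool_ix)) {
    tau <- cd / 3
    temp[cool_ix] <- b + (tg - b) * exp(-(t[cool_ix] - r - h) / tau)
  }
  temperature_profile(t, temp,
                      label = sprintf("transient %.6g K (ramp %g s, hold %g s, cool %g s)",
                                      tg, r, h, cd))
}

#' Read / write a temperature profile as CSV
#'
#' The on-disk format is two columns with header `time_s,temp_K` or
#' `time_s,temp_C`; the temperature unit is taken from the header and
#' Celsius is converted to kelvin on read. Writing uses full double
#' precision so a write-read round trip is an identity well below 1e-6.
#'
#' @param path file path.
#' @param profile a [temperature_profile].
#' @param unit `"K"` or `"C"`; the unit written to file.
#' @return `read_profile` returns a [temperature_profile];
#'   `write_profile` returns `path` invisibly.
#' @export
read_profile <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  header <- trimws(header)
  if (length(header) < 2L || header[1L] != "time_s" ||
      !header[2L] %in% c("temp_C", "temp_K"))
    stop_format(sprintf("line 1: expected header 'time_s,temp_C' or 'time_s,temp_K', got '%s'",
                        paste(header, collapse = ",")))
  d <- read.csv(path, header = TRUE)
  if (nrow(d) < 2L) stop_format("line 2: need at least 2 samples")
  bad <- which(diff(d[[1L]]) <= 0)
  if (length(bad))
    stop_format(sprintf("line %d: times not strictly increasing", bad[1L] + 2L))
  temp <- if (header[2L] == "temp_C") celsius_to_kelvin(d[[2L]]) else d[[2L]]
  temperature_profile(d[[1L]], temp, label = basename(path))
}

#' @rdname read_profile
#' @export
write_profile <- function(profile, path, unit = c("K", "C")) {
  stopifnot(inherits(profile, "temperature_profile"))
  unit <- match.arg(unit)
  temp <- if (unit == "C") kelvin_to_celsius(profile$temperatures) else profile$temperatures
  lines <- c(paste0("time_s,temp_", unit),
             paste(num_chr(profile$times), num_chr(temp), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Resample a profile onto a uniform grid
#'
#' Linear interpolation onto a uniform grid with the given step covering
#' the original span; the final endpoint is always preserved (appended
#' when the span is not a multiple of the step). Resampling at the same
#' step is idempotent.
#'
#' @param profile a [temperature_profile].
#' @param step new sampling step, seconds, > 0.
#' @return a [temperature_profile].
#' @export
resample_profile <- function(profile, step) {
  stopifnot(inherits(profile, "temperature_profile"))
  if (!is.finite(step) || step <= 0) stop_invalid("step must be > 0")
  t_new <- time_grid(max(profile$times), step)
  temp <- approx(profile$times, profile$temperatures, xout = t_new)$y
  temperature_profile(t_new, temp, label = profile$label)
}

## temperature at arbitrary times by linear interpolation (internal)
profile_at <- function(profile, t) {
  approx(profile$times, profile$temperatures, xout = t, rule = 2)$y
}
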