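#' Noise specification for simulated plate experiments
#'
#' The stochastic structure of a simulated 96-well water-bath
#' experiment: multiplicative lognormal well-to-well noise on the
#' viability readout (absorbance noise is scale-proportional and
#' survival must stay non-negative), a shared per-plate normalization
#' error from the 37 degC control plate, and a per-plate temperature
#' jitter around the setpoint (thermocouple-characterized bath error,
#' drawn once per plate and shared across its wells).
#'
#' @param well_cv coefficient of variation of per-well noise (default
#'   0.05).
#' @param control_cv coefficient of variation of the shared control
#'   normalization error (default 0.02).
#' @param temperature_jitter_sd kelvin, SD of the per-plate setpoint
#'   error (default 0.2, the scale of reported bath accuracy).
#' @param seed integer seed; all randomness in the generators flows
#'   from it. `NULL` uses the current RNG stream.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(well_cv = 0.05, control_cv = 0.02,
                       temperature_jitter_sd = 0.2, seed = NULL) {
  v <- c(well_cv, control_cv, temperature_jitter_sd)
  if (any(!is.finite(v)) || any(v < 0))
    stop_invalid("noise magnitudes must be finite and >= 0")
  structure(list(well_cv = well_cv, control_cv = control_cv,
                 temperature_jitter_sd = temperature_jitter_sd,
                 seed = seed),
            class = "noise_spec")
}

## zero-noise spec, used for noiseless round-trip checks
noiseless <- function(seed = NULL) noise_spec(0, 0, 0, seed = seed)

## mean-1 multiplicative lognormal factors at a given CV
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -sigma^2 / 2, sigma))
}

## assemble a viability_dataset from a list of row records
viability_dataset <- function(rows, n_wells) {
  d <- do.call(rbind, rows)
  wells <- as.matrix(d[, grep("^well_", names(d)), drop = FALSE])
  d$mean_survival <- rowMeans(wells)
  structure(d, class = c("viability_dataset", "data.frame"),
            n_wells = n_wells)
}

#' Simulate a water-bath hyperthermia viability dataset
#'
#' Emulates the plate-based study design: for every cell line,
#' setpoint, duration and recovery time, the true surviving fraction is
#' S = exp(-r k(T') max(0, t - t_d(T'))), where T' is the setpoint plus
#' a per-plate temperature jitter, k the Arrhenius rate, t_d the
#' shoulder delay, and r a recovery-time multiplier on log-kill
#' (death keeps progressing between 6 h and 24 h post exposure, so the
#' 6 h multiplier is < 1; the 24 h data define the kinetics and get
#' r = 1). Well values are the true fraction times per-well lognormal
#' noise times a shared control-normalization factor.
#'
#' @param truth kinetic truth per cell line: either a single block
#'   `list(arrhenius = arrhenius_params, delay = delay_params)` (delay
#'   may be omitted for pure Arrhenius kinetics) or a named list of
#'   such blocks, one per cell line.
#' @param setpoints kelvin vector of bath setpoints.
#' @param durations seconds vector of exposure durations.
#' @param recovery_scale named numeric: log-kill multiplier per recovery
#'   time in hours. Default `c("6" = 0.7, "24" = 1)`.
#' @param noise a [noise_spec].
#' @param n_wells wells per condition (default 6).
#' @return a `viability_dataset`: a data.frame with columns
#'   `cell_line`, `setpoint` (kelvin), `duration` (seconds),
#'   `recovery_h`, `well_1` ... `well_n`, `mean_survival`.
#' @examples
#' tr <- cell_line_params("KPC")
#' ds <- generate_viability_dataset(tr, celsius_to_kelvin(c(44, 46, 50)),
#'                                  c(300, 600, 1800),
#'                                  noise = noise_spec(seed = 1))
#' @export
generate_viability_dataset <- function(truth,
                                       setpoints = celsius_to_kelvin(c(42.5, 44, 46, 50)),
                                       durations = 60 * c(3, 5, 10, 15, 20, 30, 45, 60),
                                       recovery_scale = c("6" = 0.7, "24" = 1),
                                       noise = noise_spec(),
                                       n_wells = 6L) {
  if (length(setpoints) == 0L || length(durations) == 0L)
    stop_invalid("setpoints and durations must be non-empty")
  if (!is.null(truth$arrhenius)) truth <- list(synthetic = truth)
  with_seed(noise$seed, {
    rows <- list()
    for (line in names(truth)) {
      blk <- truth[[line]]
      for (rec in names(recovery_scale)) {
        mult <- recovery_scale[[rec]]
        for (tp in setpoints) for (dur in durations) {
          t_true <- tp + rnorm(1, 0, noise$temperature_jitter_sd)
          k <- rate_constant(blk$arrhenius, t_true)
          td <- if (is.null(blk$delay)) 0 else time_delay(blk$delay, t_true)
          s_true <- exp(-mult * k * max(0, dur - td))
          ctrl <- lognormal_factor(1, noise$control_cv)
          wells <- s_true * ctrl * lognormal_factor(n_wells, noise$well_cv)
          row <- data.frame(cell_line = line, setpoint = tp, duration = dur,
                            recovery_h = as.numeric(rec))
          row[paste0("well_", seq_len(n_wells))] <- as.list(wells)
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
    viability_dataset(rows, n_wells)
  })
}

#' Simulate a viability dataset from two-state truth
#'
#' Same plate/noise structure as [generate_viability_dataset()], with
#' the true surviving fraction taken from the two-state logistic model
#' S = logistic(gamma T' - beta - alpha tau). Generated at a single
#' recovery time (24 h).
#'
#' @param truth a [two_state_params].
#' @param setpoints,durations,noise,n_wells as in
#'   [generate_viability_dataset()].
#' @param cell_line label recorded in the dataset.
#' @return a `viability_dataset`.
#' @export
generate_two_state_dataset <- function(truth,
                                       setpoints = celsius_to_kelvin(c(42.5, 44, 46, 50)),
                                       durations = 60 * c(3, 5, 10, 15, 20, 30, 45, 60),
                                       noise = noise_spec(),
                                       n_wells = 6L,
                                       cell_line = "synthetic") {
  stopifnot(inherits(truth, "two_state_params"))
  if (length(setpoints) == 0L || length(durations) == 0L)
    stop_invalid("setpoints and durations must be non-empty")
  with_seed(noise$seed, {
    rows <- list()
    for (tp in setpoints) for (dur in durations) {
      t_true <- tp + rnorm(1, 0, noise$temperature_jitter_sd)
      s_true <- two_state_survival(dur, t_true, truth)
      ctrl <- lognormal_factor(1, noise$control_cv)
      wells <- s_true * ctrl * lognormal_factor(n_wells, noise$well_cv)
      row <- data.frame(cell_line = cell_line, setpoint = tp, duration = dur,
                        recovery_h = 24)
      row[paste0("well_", seq_len(n_wells))] <- as.list(wells)
      rows[[length(rows) + 1L]] <- row
    }
    viability_dataset(rows, n_wells)
  })
}

#' Non-isothermal ablation-periphery profile
#'
#' Emulates the time-temperature history at the periphery of a thermal
#' ablation zone: a saturating-exponential approach from body
#' temperature (37 degC) toward the peak temperature, as seen a few
#' millimetres outside an active applicator during a 10 min, ~50 W
#' delivery.
#'
#' @param peak kelvin, > 310.15.
#' @param rise_constant seconds; exponential time constant of the
#'   approach (default 120).
#' @param duration seconds of heating (default 600).
#' @param step sampling step, seconds.
#' @return a [temperature_profile].
#' @export
generate_ablation_periphery_profile <- function(peak, rise_constant = 120,
                                                duration = 600, step = 1) {
  if (peak <= BODY_TEMP_K) stop_invalid("peak must exceed 310.15 K (37 degC)")
  t <- time_grid(duration, step)
  temp <- peak - (peak - BODY_TEMP_K) * exp(-t / rise_constant)
  temperature_profile(t, temp, label = sprintf("ablation periphery %.4g K", peak))
}

#' Read / write viability datasets as CSV
#'
#' File layout:
#' `cell_line,setpoint_C,duration_min,recovery_h,well_1..well_n,mean_survival`.
#' Temperatures are degC and durations minutes at the file boundary
#' (kelvin and seconds in memory). Numbers are written at full double
#' precision so a write-read round trip reproduces the dataset.
#'
#' @param dataset a `viability_dataset`.
#' @param path file path.
#' @return `read_viability` returns a `viability_dataset`;
#'   `write_viability` returns `path` invisibly.
#' @export
write_viability <- function(dataset, path) {
  d <- as.data.frame(dataset)
  wells <- grep("^well_", names(d), value = TRUE)
  out <- data.frame(cell_line = d$cell_line,
                    setpoint_C = num_chr(kelvin_to_celsius(d$setpoint)),
                    duration_min = num_chr(d$duration / 60),
                    recovery_h = num_chr(d$recovery_h))
  for (w in wells) out[[w]] <- num_chr(d[[w]])
  out$mean_survival <- num_chr(d$mean_survival)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_viability
#' @export
read_viability <- function(path) {
  d <- read.csv(path, header = TRUE)
  req <- c("cell_line", "setpoint_C", "duration_min", "recovery_h")
  if (!all(req %in% names(d)))
    stop_format(sprintf("missing columns: %s",
                        paste(setdiff(req, names(d)), collapse = ", ")))
  wells <- grep("^well_", names(d), value = TRUE)
  if (length(wells) == 0L) stop_format("no well_* columns found")
  out <- data.frame(cell_line = d$cell_line,
                    setpoint = celsius_to_kelvin(d$setpoint_C),
                    duration = d$duration_min * 60,
                    recovery_h = d$recovery_h)
  for (w in wells) out[[w]] <- d[[w]]
  viability_dataset(list(out), length(wells))
}

#' @export
print.viability_dataset <- function(x, ...) {
  d <- x
  class(d) <- "data.frame"
  cat(sprintf("viability_dataset: %d conditions, %d cell line(s), %d wells/condition\n",
              nrow(d), length(unique(d$cell_line)), attr(x, "n_wells")))
  print(head(d))
  invisible(x)
}
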