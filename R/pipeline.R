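#' Analysis configuration
#'
#' Collects every tunable of the end-to-end workflow so a run is fully
#' described by (dataset, config); the config is echoed into the report
#' for provenance.
#'
#' @param gas_constant J K^-1 mol^-1 used throughout the fits.
#' @param recovery_h recovery time whose parameters the report treats
#'   as primary (default 24; kinetic coefficients are conventionally
#'   quoted from 24 h viability).
#' @param clip_floor,clip_ceiling survival clipping for the ln-linear
#'   decay fits (see [fit_decay_rate()]).
#' @param logit_eps clipping bound for the two-state logit fit.
#' @param r_above,r_below,break_temperature CEM43 dose parameters.
#' @param seed optional integer recorded for provenance when the
#'   dataset was simulated.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(gas_constant = 8.314, recovery_h = 24,
                            clip_floor = 1e-4, clip_ceiling = 1.5,
                            logit_eps = 1e-4, r_above = 0.5, r_below = 0.25,
                            break_temperature = 316.15, seed = NULL) {
  structure(list(gas_constant = gas_constant, recovery_h = recovery_h,
                 clip_floor = clip_floor, clip_ceiling = clip_ceiling,
                 logit_eps = logit_eps, r_above = r_above, r_below = r_below,
                 break_temperature = break_temperature, seed = seed),
            class = "analysis_config")
}

## re-raise a condition with the offending cell line / condition named
with_context <- function(context, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(paste0(context, ": ", conditionMessage(e)),
                        class = class(e)))
  })
}

#' Run the full thermal-injury analysis
#'
#' Executes the complete inverse workflow on a viability dataset, per
#' cell line and per recovery time: per-temperature decay-rate fits
#' (through-origin for the simple Arrhenius arm, free-intercept for the
#' shoulder-aware arm), Arrhenius regression of ln k on 1/T, the
#' shoulder-delay line, the two-state bilinear fit, and the R_CEM
#' isoeffect regression; then evaluates all three forward models
#' against the data and tabulates pooled RMSE per model and recovery
#' time. Deterministic given dataset and config.
#'
#' @param dataset a `viability_dataset` spanning >= 2 temperatures and
#'   >= 3 durations per temperature.
#' @param config an [analysis_config].
#' @return an object of class `analysis_report` with elements
#'   `fits[[recovery]][[cell_line]]` (parameter blocks `arrhenius`,
#'   `arrhenius_delayed`, `two_state`, `r_cem`, `decay_rates`),
#'   `model_comparison` (data.frame of `recovery_h`, `model`,
#'   `rmse_pct`), and the echoed `config`.
#' @export
run_analysis <- function(dataset, config = analysis_config()) {
  d <- as.data.frame(dataset)
  if (is.null(d) || nrow(d) == 0L) stop_invalid("empty dataset")
  if (length(unique(d$setpoint)) < 2L)
    stop_invalid("dataset must span >= 2 temperatures")
  for (tp in unique(d$setpoint))
    if (length(unique(d$duration[d$setpoint == tp])) < 3L)
      stop_invalid(sprintf("setpoint %.6g K has < 3 durations", tp))

  fits <- list()
  comparison <- list()
  for (rec in sort(unique(d$recovery_h))) {
    dr <- d[d$recovery_h == rec, , drop = FALSE]
    rec_key <- as.character(rec)
    fits[[rec_key]] <- list()
    simple_par <- list(); delayed_par <- list(); ts_par <- list()
    for (line in unique(dr$cell_line)) {
      dl <- dr[dr$cell_line == line, , drop = FALSE]
      ctx <- sprintf("cell line %s, %g h recovery", line, rec)
      est_to <- list(); est_fi <- list()
      for (tp in unique(dl$setpoint)) {
        di <- dl[dl$setpoint == tp, ]
        ctx_t <- sprintf("%s, %.6g K", ctx, tp)
        est_to[[length(est_to) + 1L]] <- with_context(ctx_t,
          fit_decay_rate(di$duration, di$mean_survival, mode = "through_origin",
                         clip_floor = config$clip_floor,
                         clip_ceiling = config$clip_ceiling, temperature = tp))
        est_fi[[length(est_fi) + 1L]] <- with_context(ctx_t,
          fit_decay_rate(di$duration, di$mean_survival, mode = "free_intercept",
                         clip_floor = config$clip_floor,
                         clip_ceiling = config$clip_ceiling, temperature = tp))
      }
      arr_simple <- with_context(ctx, fit_arrhenius(est_to, config$gas_constant))
      arr_free <- with_context(ctx, fit_arrhenius(est_fi, config$gas_constant))
      # a dataset with a shoulder at fewer than two setpoints cannot
      # support the delay line; degrade to a null delay model so the
      # delayed arm reduces to free-intercept Arrhenius kinetics
      delay <- withCallingHandlers(
        tryCatch(with_context(ctx, fit_time_delay(est_fi)),
                 thermodose_invalid_argument = function(e) {
                   out <- delay_params(0, 0)
                   attr(out, "underdetermined") <- TRUE
                   out
                 }),
        warning = function(w) invokeRestart("muffleWarning"))
      two_state <- with_context(ctx, fit_two_state(
        data.frame(temperature = dl$setpoint, duration = dl$duration,
                   survival = dl$mean_survival), eps = config$logit_eps))
      r_cem <- tryCatch(
        fit_rcem(est_fi, break_temperature = config$break_temperature),
        error = function(e) NA_real_)
      fits[[rec_key]][[line]] <- list(
        arrhenius = arr_simple,
        arrhenius_delayed = list(arrhenius = arr_free$params,
                                 delay = delay,
                                 r_squared = arr_free$r_squared),
        two_state = list(params = two_state$params,
                         r_squared = two_state$report$r_squared),
        r_cem = r_cem,
        decay_rates = estimates_frame(est_fi))
      simple_par[[line]] <- arr_simple$params
      delayed_par[[line]] <- list(arrhenius = arr_free$params, delay = delay)
      ts_par[[line]] <- two_state$params
    }
    ds_rec <- dr
    class(ds_rec) <- c("viability_dataset", "data.frame")
    for (model in c("arrhenius", "arrhenius_delayed", "two_state")) {
      params <- switch(model, arrhenius = simple_par,
                       arrhenius_delayed = delayed_par, two_state = ts_par)
      rep_m <- evaluate_fit(ds_rec, model, params)
      comparison[[length(comparison) + 1L]] <-
        data.frame(recovery_h = rec, model = model, rmse_pct = rep_m$rmse_pct)
    }
  }
  structure(list(fits = fits,
                 model_comparison = do.call(rbind, comparison),
                 validation = NULL,
                 config = unclass(config)),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  recs <- names(x$fits)
  lines <- unique(unlist(lapply(x$fits, names)))
  cat(sprintf("analysis_report: %d cell line(s) [%s], recovery %s h\n",
              length(lines), paste(lines, collapse = ", "),
              paste(recs, collapse = ", ")))
  cat("model comparison (pooled RMSE, percentage points):\n")
  print(x$model_comparison, row.names = FALSE)
  invisible(x)
}

## fetch a cell line's fitted blocks from a report
report_params <- function(report, cell_line, recovery_h) {
  blk <- report$fits[[as.character(recovery_h)]][[cell_line]]
  if (is.null(blk))
    stop_invalid(sprintf("report has no fit for cell line '%s' at %s h",
                         cell_line, recovery_h))
  blk
}

#' Predict survival on a non-isothermal profile and compare to reference
#'
#' Applies each fitted model to an arbitrary time-temperature profile
#' (the ablation-periphery validation setting): the two Arrhenius arms
#' through their damage integrals, and the two-state model at the
#' profile's duration and time-averaged temperature (the model is
#' defined for isothermal exposures; the time average is the natural
#' profile summary for its bilinear logit).
#'
#' @param profile a [temperature_profile].
#' @param report an `analysis_report` from [run_analysis()].
#' @param reference measured (or simulated) end-of-exposure surviving
#'   fraction to compare against.
#' @param cell_line which cell line's parameters to use.
#' @param recovery_h which recovery time's parameters (default: the
#'   config's primary recovery time).
#' @return a data.frame with one row per model: `profile`, `model`,
#'   `predicted_pct`, `reference_pct`, `abs_error_pct`.
#' @export
validate_on_profile <- function(profile, report, reference, cell_line,
                                recovery_h = report$config$recovery_h) {
  stopifnot(inherits(profile, "temperature_profile"),
            inherits(report, "analysis_report"))
  blk <- report_params(report, cell_line, recovery_h)
  n <- length(profile$times)
  dur <- profile$times[n]
  s_simple <- damage_integral(profile, blk$arrhenius$params)$survival_fraction[n]
  s_delay <- damage_integral_delayed(profile, blk$arrhenius_delayed$arrhenius,
                                     blk$arrhenius_delayed$delay)$survival_fraction[n]
  t_mean <- cumtrapz(profile$times, profile$temperatures)[n] / dur
  s_ts <- two_state_survival(dur, t_mean, blk$two_state$params)
  out <- data.frame(profile = profile$label,
                    model = c("arrhenius", "arrhenius_delayed", "two_state"),
                    predicted_pct = 100 * c(s_simple, s_delay, s_ts),
                    reference_pct = 100 * reference)
  out$abs_error_pct <- abs(out$predicted_pct - out$reference_pct)
  out
}

#' Write an analysis report as JSON
#'
#' Serializes the report (including the echoed configuration) with
#' stable key ordering and full numeric precision, so identical inputs
#' produce byte-identical files. A JSON Schema describing the layout is
#' shipped under `inst/schema/`.
#'
#' @param report an `analysis_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @seealso [report_conforms()]
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           force = TRUE, null = "null", dataframe = "rows")
  writeLines(json, path)
  invisible(path)
}

#' Check an analysis report against the shipped schema
#'
#' Structural conformance check of a report (or a JSON file written by
#' [write_report()]) against the layout published in
#' `inst/schema/analysis-report.schema.json`: required top-level keys,
#' per-cell-line parameter blocks with their r-squared values, and
#' non-negative RMSE entries.
#'
#' @param x an `analysis_report` or a path to a report JSON file.
#' @return `TRUE` if conformant, otherwise a character vector of
#'   violations.
#' @export
report_conforms <- function(x) {
  if (is.character(x)) x <- jsonlite::read_json(x, simplifyVector = FALSE)
  x <- unclass(x)
  bad <- character()
  for (key in c("fits", "model_comparison", "config"))
    if (is.null(x[[key]])) bad <- c(bad, sprintf("missing field '%s'", key))
  if (!is.null(x$fits)) for (rec in names(x$fits))
    for (line in names(x$fits[[rec]])) {
      blk <- x$fits[[rec]][[line]]
      for (m in c("arrhenius", "arrhenius_delayed", "two_state"))
        if (is.null(blk[[m]]) || is.null(blk[[m]]$r_squared))
          bad <- c(bad, sprintf("fits[%s][%s]: missing %s block or its r_squared",
                                rec, line, m))
    }
  mc <- x$model_comparison
  if (!is.null(mc)) {
    rmse <- if (is.data.frame(mc)) mc$rmse_pct
            else vapply(mc, function(r) r$rmse_pct, numeric(1))
    if (any(!is.finite(rmse)) || any(rmse < 0))
      bad <- c(bad, "model_comparison: rmse_pct must be finite and >= 0")
  }
  if (length(bad)) bad else TRUE
}
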