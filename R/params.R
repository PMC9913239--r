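#' Arrhenius rate coefficients
#'
#' The two coefficients of the first-order thermal injury rate
#' k(T) = A exp(-Ea / (R T)): the frequency factor A (stored as its
#' natural log, A in s^-1) and the activation energy Ea (J mol^-1).
#'
#' @param ln_frequency_factor ln A, dimensionless (A in s^-1).
#' @param activation_energy Ea, J mol^-1, > 0.
#' @param gas_constant universal gas constant, J K^-1 mol^-1. Default
#'   8.314; configurable so that arithmetic with a rounded constant can
#'   be reproduced exactly.
#' @return an object of class `arrhenius_params`.
#' @examples
#' arrhenius_params(137.63, 383112)
#' @export
arrhenius_params <- function(ln_frequency_factor, activation_energy,
                             gas_constant = 8.314) {
  if (!is.finite(activation_energy) || activation_energy <= 0)
    stop_invalid("activation_energy must be > 0")
  if (!is.finite(gas_constant) || gas_constant <= 0)
    stop_invalid("gas_constant must be > 0")
  structure(list(ln_frequency_factor = as.numeric(ln_frequency_factor),
                 activation_energy = as.numeric(activation_energy),
                 gas_constant = as.numeric(gas_constant)),
            class = "arrhenius_params")
}

#' @export
print.arrhenius_params <- function(x, ...) {
  cat(sprintf("arrhenius_params: ln A = %.4f, Ea = %.6g J/mol (R = %g)\n",
              x$ln_frequency_factor, x$activation_energy, x$gas_constant))
  invisible(x)
}

#' Shoulder time-delay coefficients
#'
#' The temperature-dependent delay t_d(T) = b - m T before Arrhenius
#' injury begins; it models the shoulder region where viability stays
#' near 100% at mild temperatures. Negative predicted delays are clamped
#' to zero by [time_delay()].
#'
#' @param slope_m s K^-1, >= 0.
#' @param intercept_b seconds.
#' @return an object of class `delay_params`.
#' @examples
#' delay_params(slope_m = 800, intercept_b = 254920)
#' @export
delay_params <- function(slope_m, intercept_b) {
  if (!is.finite(slope_m) || slope_m < 0)
    stop_invalid("slope_m must be >= 0")
  structure(list(slope_m = as.numeric(slope_m),
                 intercept_b = as.numeric(intercept_b)),
            class = "delay_params")
}

#' Two-state logistic survival coefficients
#'
#' Coefficients of the two-state model in which the logit of the viable
#' fraction is bilinear in temperature and exposure time:
#' logit C = gamma T - beta - alpha tau.
#'
#' @param alpha s^-1; > 0 for a population that dies with exposure time.
#' @param beta dimensionless offset.
#' @param gamma K^-1 temperature sensitivity.
#' @return an object of class `two_state_params`.
#' @export
two_state_params <- function(alpha, beta, gamma) {
  v <- c(alpha, beta, gamma)
  if (any(!is.finite(v))) stop_invalid("two-state coefficients must be finite")
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 gamma = as.numeric(gamma)),
            class = "two_state_params")
}

#' CEM43 dose parameters
#'
#' Per-degree isoeffect factors for the thermal isoeffective dose:
#' R = `r_above` when the interval temperature exceeds the break
#' (strict >), else `r_below`. Canonical values are 0.5 above 43 degC
#' and 0.25 at or below.
#'
#' @param r_above dimensionless, in (0, 1).
#' @param r_below dimensionless, in (0, 1).
#' @param break_temperature kelvin; default 316.15 (43 degC).
#' @return an object of class `dose_params`.
#' @export
dose_params <- function(r_above = 0.5, r_below = 0.25,
                        break_temperature = 316.15) {
  if (!is.finite(r_above) || r_above <= 0 || r_above >= 1)
    stop_invalid("r_above must be in (0, 1)")
  if (!is.finite(r_below) || r_below <= 0 || r_below >= 1)
    stop_invalid("r_below must be in (0, 1)")
  structure(list(r_above = as.numeric(r_above), r_below = as.numeric(r_below),
                 break_temperature = as.numeric(break_temperature)),
            class = "dose_params")
}

#' Bundled kinetic-coefficient registry
#'
#' Published Arrhenius and shoulder-delay coefficients (24 h recovery)
#' and R_CEM values for the three murine cell lines the package's study
#' design emulates: KPC and Pan02 pancreatic cancer lines and STO
#' fibroblasts. Shipped as a YAML registry under `extdata`.
#'
#' @param line cell line name (`"KPC"`, `"Pan02"`, `"STO"`); `NULL`
#'   lists all entries.
#' @param path optional path to an alternative registry file in the same
#'   flat YAML layout.
#' @return for one line, a list with elements `arrhenius`
#'   ([arrhenius_params]), `delay` ([delay_params]) and `r_cem`
#'   (numeric); for `line = NULL`, a named list of such lists.
#' @examples
#' cell_line_params("KPC")$arrhenius
#' names(cell_line_params())
#' @export
cell_line_params <- function(line = NULL, path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cell_lines.yaml", package = "thermodose",
                        mustWork = TRUE)
  reg <- yaml::read_yaml(path)
  as_block <- function(b) {
    list(arrhenius = arrhenius_params(b$ln_frequency_factor,
                                      b$activation_energy),
         delay = delay_params(b$delay_slope_m, b$delay_intercept_b),
         r_cem = b$r_cem)
  }
  if (is.null(line)) return(lapply(reg, as_block))
  if (!line %in% names(reg))
    stop_invalid(sprintf("unknown cell line '%s' (registry has: %s)",
                         line, paste(names(reg), collapse = ", ")))
  as_block(reg[[line]])
}
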