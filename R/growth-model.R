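#' Cumulative growing degree days from sowing
#'
#' Accumulates daily mean temperature above a base temperature, the standard
#' developmental time scale for warm-season crops. Day of sowing is element 1;
#' days on which the mean temperature falls below the base contribute zero.
#'
#' @param daily_mean_temp Numeric vector of daily mean temperatures (degrees C),
#'   starting at the day of sowing.
#' @param base_temp Base temperature in degrees C below which no thermal time
#'   accumulates. Default 8, the value commonly used for soybean.
#' @return Numeric vector of cumulative degree-days, same length as the input.
#' @examples
#' compute_gdd(c(20, 25, 6))
#' @export
compute_gdd <- function(daily_mean_temp, base_temp = 8) {
  if (length(daily_mean_temp) == 0L) {
    stop("`daily_mean_temp` must contain at least one value", call. = FALSE)
  }
  if (anyNA(daily_mean_temp)) {
    stop("`daily_mean_temp` contains missing values", call. = FALSE)
  }
  cumsum(pmax(daily_mean_temp - base_temp, 0))
}

#' Thermal time per environment
#'
#' Computes cumulative growing degree days for every environment in a daily
#' temperature table, ordered by date from sowing.
#'
#' @param temps A data frame with columns `environment_id`, `date` (Date or
#'   ISO-8601 string) and `tmean_c`. The first date per environment is taken as
#'   the sowing date.
#' @param base_temp Base temperature (degrees C).
#' @return A tibble with columns `environment_id`, `date`, `day` (days after
#'   sowing, sowing day = 0), `tmean_c` and `gdd`.
#' @export
thermal_time <- function(temps, base_temp = 8) {
  stopifnot(all(c("environment_id", "date", "tmean_c") %in% names(temps)))
  temps |>
    dplyr::mutate(date = as.Date(.data$date)) |>
    dplyr::arrange(.data$environment_id, .data$date) |>
    dplyr::group_by(.data$environment_id) |>
    dplyr::mutate(
      day = as.integer(.data$date - .data$date[1]),
      gdd = compute_gdd(.data$tmean_c, base_temp)
    ) |>
    dplyr::ungroup() |>
    tibble::as_tibble()
}

#' Convert leaf area index to green fraction
#'
#' Beer-Lambert light extinction links canopy cover (green fraction, GF) to
#' leaf area index: `gf = 1 - exp(-k * lai)`.
#'
#' @param lai Leaf area index values (dimensionless, >= 0).
#' @param k Extinction coefficient; 0.5 is the value commonly used for soybean.
#' @return Green fraction values in `[0, 1)`.
#' @seealso [gf_to_lai()] for the inverse.
#' @export
lai_to_gf <- function(lai, k = 0.5) {
  1 - exp(-k * lai)
}

#' Convert green fraction to leaf area index
#'
#' Inverse of [lai_to_gf()]: `lai = -log(1 - gf) / k`.
#'
#' @param gf Green fraction values in `[0, 1)`.
#' @param k Extinction coefficient.
#' @return Leaf area index values.
#' @export
gf_to_lai <- function(gf, k = 0.5) {
  if (any(gf >= 1 | gf < 0, na.rm = TRUE)) {
    stop("`gf` must lie in [0, 1)", call. = FALSE)
  }
  -log1p(-gf) / k
}

#' Construct a set of canopy dynamics parameters
#'
#' The five parameters of the LAI dynamics curve: `lai_amp` is the maximum LAI
#' reached; `r_g` the logistic growth rate and `t_g` its inflection point in
#' degree-days; `r_s` the exponential senescence rate and `t_s` the degree-day
#' at which LAI returns to zero.
#'
#' @param lai_amp,r_g,r_s,t_g,t_s Curve parameters; `lai_amp`, `r_g`, `r_s`
#'   strictly positive, `t_s > t_g`.
#' @return A named list of class `dynamics_params`.
#' @export
dynamics_params <- function(lai_amp, r_g, r_s, t_g, t_s) {
  p <- list(lai_amp = lai_amp, r_g = r_g, r_s = r_s, t_g = t_g, t_s = t_s)
  if (!all(vapply(p, is.finite, logical(1)))) {
    stop("dynamics parameters must be finite", call. = FALSE)
  }
  if (lai_amp <= 0 || r_g <= 0 || r_s <= 0) {
    stop("`lai_amp`, `r_g` and `r_s` must be strictly positive", call. = FALSE)
  }
  if (t_s <= t_g) {
    stop("`t_s` must exceed `t_g`", call. = FALSE)
  }
  structure(p, class = "dynamics_params")
}

as_dynamics_params <- function(x) {
  if (inherits(x, "dynamics_params")) return(x)
  x <- as.list(x)
  dynamics_params(x$lai_amp, x$r_g, x$r_s, x$t_g, x$t_s)
}

# logistic(x) evaluated without overflow for large |x|
stable_logistic <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Evaluate the LAI dynamics curve
#'
#' The curve is the difference of a logistic growth term and an exponential
#' senescence term on the growing-degree-day scale:
#' `lai_amp * (1 / (1 + exp(-r_g * (T - t_g))) - exp(r_s * (T - t_s)))`.
#' Values past `t_s` can be negative; [predict_gf_curve()] clamps them before
#' converting to green fraction.
#'
#' @param gdd Growing degree days at which to evaluate the curve.
#' @param params A `dynamics_params` object, or any list/one-row data frame
#'   with fields `lai_amp`, `r_g`, `r_s`, `t_g`, `t_s`.
#' @return LAI values, one per element of `gdd`.
#' @export
lai_curve <- function(gdd, params) {
  p <- as_dynamics_params(params)
  growth <- stable_logistic(p$r_g * (gdd - p$t_g))
  # cap the senescence exponent: beyond ~exp(700) the curve is long past any
  # observable range and exp() would overflow
  sen <- exp(pmin(p$r_s * (gdd - p$t_s), 700))
  p$lai_amp * (growth - sen)
}

#' Predict a green fraction trajectory from dynamics parameters
#'
#' Evaluates the LAI dynamics curve, clamps negative LAI at zero (green
#' fraction is a proportion and cannot be negative; the curve crosses zero at
#' `t_s`), and converts to green fraction by Beer-Lambert extinction.
#'
#' @inheritParams lai_curve
#' @param k Extinction coefficient.
#' @return Green fraction values in `[0, 1)`, one per element of `gdd`.
#' @export
predict_gf_curve <- function(gdd, params, k = 0.5) {
  lai_to_gf(pmax(lai_curve(gdd, params), 0), k = k)
}
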