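#' Percent reduction in cell number
#'
#' `100 * (n_control - n_treated) / n_control`. Reported both at full
#' precision and rounded to the nearest integer, the granularity at which
#' growth-suppression results are usually quoted.
#'
#' @param n_control Cell count in unexposed cultures (> 0).
#' @param n_treated Cell count after exposure.
#' @return List with `percent` (full precision) and `rounded`.
#' @examples
#' percent_reduction(3.6e6, 7.4e5)$rounded  # 79
#' @export
percent_reduction <- function(n_control, n_treated) {
  if (n_control <= 0) stop("control count must be positive")
  pct <- 100 * (n_control - n_treated) / n_control
  list(percent = pct, rounded = round(pct))
}

#' Population doubling time
#'
#' Time for an exponentially growing culture to double:
#' `PDT = delta_t * ln(2) / ln(n2 / n1)`.
#'
#' @param n1,n2 Cell numbers (or proportional activity readings) at the
#'   start and end of the interval; `n2 > n1 > 0`. The ratio alone matters,
#'   so rescaling both by a constant leaves the result unchanged.
#' @param delta_t_h Interval length in hours (> 0).
#' @return Doubling time in hours.
#' @examples
#' doubling_time(1.5e5, 3.6e6, 72)  # 15.7 h
#' @export
doubling_time <- function(n1, n2, delta_t_h) {
  if (n1 <= 0 || n2 <= 0) stop("counts must be positive")
  if (delta_t_h <= 0) stop("interval must be positive")
  if (n2 <= n1) stop("no doubling: n2 must exceed n1")
  delta_t_h * log(2) / log(n2 / n1)
}

#' Coefficient of variation as a percentage
#'
#' @param mean Positive mean.
#' @param sd Non-negative standard deviation.
#' @return List with `percent` (100 * sd / mean) and `rounded`.
#' @examples
#' coefficient_of_variation(19.6, 3.94)$rounded  # 20
#' @export
coefficient_of_variation <- function(mean, sd) {
  if (mean <= 0) stop("mean must be positive")
  if (sd < 0) stop("sd must be non-negative")
  pct <- 100 * sd / mean
  list(percent = pct, rounded = round(pct))
}

#' Ratio of cell-number deficit to dead cells recovered in supernatant
#'
#' Compares the loss of adherent cells under exposure with the dead cells
#' actually found in the culture supernatant. A ratio far above 1 indicates
#' the cell-number reduction is mostly growth arrest rather than death.
#'
#' @param n_control,n_treated Adherent cell counts, `n_control > n_treated`.
#' @param supernatant_dead Dead cells recovered from the supernatant (> 0).
#' @return List with `ratio` (full precision) and `rounded`.
#' @examples
#' death_vs_loss_ratio(3.6e6, 1.3e6, 5.1e4)$rounded  # 45
#' @export
death_vs_loss_ratio <- function(n_control, n_treated, supernatant_dead) {
  if (supernatant_dead <= 0) stop("supernatant dead-cell count must be positive")
  if (n_control <= n_treated) stop("control count must exceed treated count")
  ratio <- (n_control - n_treated) / supernatant_dead
  list(ratio = ratio, rounded = round(ratio))
}

#' Fit a linear calibration curve
#'
#' Ordinary least squares of signal on concentration, e.g. for quantifying
#' melanin against a synthetic-melanin dilution series. Optionally computes
#' a detection limit with the 3.3 sigma/slope convention (residual standard
#' deviation over slope).
#'
#' @param x Known concentrations (>= 2 distinct values).
#' @param y Measured signals, same length.
#' @return List of class `"calibration_curve"`: `slope`, `intercept`,
#'   `r_squared`, `detection_limit` (NA with fewer than 3 points).
#' @export
fit_calibration <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(unique(x)) < 2L) stop("need at least 2 distinct concentrations")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  # summary.lm warns on exact fits; r2 and sigma computed directly
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  sigma <- if (length(x) > 2L) sqrt(rss / (length(x) - 2L)) else NA_real_
  structure(list(slope = unname(cf[2L]), intercept = unname(cf[1L]),
                 r_squared = r2,
                 detection_limit = if (is.na(sigma)) NA_real_ else
                   3.3 * sigma / abs(unname(cf[2L]))),
            class = "calibration_curve")
}

#' Invert a calibration curve
#'
#' @param curve A `"calibration_curve"` from [fit_calibration()].
#' @param y Signal value(s) to convert back to concentration.
#' @return Estimated concentration(s), `(y - intercept) / slope`.
#' @export
invert_calibration <- function(curve, y) {
  if (!inherits(curve, "calibration_curve")) stop("not a calibration_curve")
  if (curve$slope == 0) stop("zero slope: curve cannot be inverted")
  (y - curve$intercept) / curve$slope
}
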