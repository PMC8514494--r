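#' @title Quantification quality control
#' @name quantification
#' @description
#' The quantification helpers mirror the assay's QC workflow: signals are
#' normalized to the co-injected deuterated internal standard, calibration
#' lines are fitted across spiked concentration levels, detection and
#' quantification limits follow the blank-based mean + 3 sd / mean + 10 sd
#' rules, and precision is summarised as percent coefficients of variation.
#' Sample (n - 1) standard deviations are used throughout.
NULL

#' Normalize a raw signal to the internal standard
#'
#' @param raw Raw area(s) under the curve.
#' @param standard Area of the co-injected internal standard (> 0).
#' @return Normalized signal `raw / standard` (nAUC).
#' @export
normalizeToStandard <- function(raw, standard) {
  if (any(!is.finite(standard)) || any(standard <= 0))
    stop("internal-standard signal must be > 0")
  raw / standard
}

#' Fit a linear calibration curve
#'
#' Ordinary least-squares line of signal on spiked concentration, with an
#' optional 1/x^2 weighting for heteroscedastic responses.
#'
#' @param levels Spiked concentrations (e.g. pg/uL), >= 3 distinct values.
#' @param responses Measured signals, same length.
#' @param weighted Use 1/levels^2 weights (levels must then be > 0).
#' @return A list of class `calibrationCurve`: `slope`, `intercept`, `r2`,
#'   `residuals`, `range`.
#' @examples
#' cc <- fitCalibration(c(1, 2, 3), c(2.1, 3.9, 6.0))
#' cc$slope
#' @export
fitCalibration <- function(levels, responses, weighted = FALSE) {
  stopifnot(length(levels) == length(responses))
  if (length(unique(levels)) < 3L)
    stop("need at least 3 distinct calibration levels")
  if (sd(responses) == 0) stop("constant responses: R^2 undefined")
  w <- if (weighted) {
    if (any(levels <= 0)) stop("weighted fit needs positive levels")
    1 / levels^2
  } else NULL
  fit <- lm(responses ~ levels, weights = w)
  r2 <- suppressWarnings(summary(fit)$r.squared)   # exact fits warn
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = r2, residuals = unname(stats::residuals(fit)),
                 range = range(levels)),
            class = "calibrationCurve")
}

#' @export
print.calibrationCurve <- function(x, ...) {
  cat(sprintf("calibrationCurve: signal = %.4g * conc + %.4g, R^2 = %.5f\n",
              x$slope, x$intercept, x$r2))
  cat(sprintf("  calibrated range: %g to %g\n", x$range[1], x$range[2]))
  invisible(x)
}

#' Limit of detection from blank measurements
#'
#' `mean(blanks) + 3 * sd(blanks)` (sample sd).
#'
#' @param blanks Blank signals (>= 2 values for a non-degenerate sd; a
#'   constant vector returns its value).
#' @return LOD threshold in signal units.
#' @export
lod <- function(blanks) {
  stopifnot(is.numeric(blanks), length(blanks) >= 1)
  s <- if (length(blanks) > 1L) sd(blanks) else 0
  mean(blanks) + 3 * s
}

#' Lower limit of quantification from blank measurements
#'
#' `mean(blanks) + 10 * sd(blanks)` (sample sd); always >= [lod()].
#'
#' @inheritParams lod
#' @return LLOQ threshold in signal units.
#' @export
lloq <- function(blanks) {
  stopifnot(is.numeric(blanks), length(blanks) >= 1)
  s <- if (length(blanks) > 1L) sd(blanks) else 0
  mean(blanks) + 10 * s
}

#' Percent coefficient of variation
#'
#' @param values Numeric vector with non-zero mean.
#' @return `100 * sd / mean`.
#' @export
cvPercent <- function(values) {
  m <- mean(values)
  if (m == 0) stop("mean is zero: CV undefined")
  100 * sd(values) / m
}

#' Extraction efficiency
#'
#' Recovery of a spiked-and-processed standard relative to direct
#' injection, in percent.
#'
#' @param processed Signal after the full extraction protocol.
#' @param direct Signal of the directly injected standard (> 0).
#' @return `100 * processed / direct`.
#' @export
extractionEfficiency <- function(processed, direct) {
  if (any(direct <= 0)) stop("direct signal must be > 0")
  100 * processed / direct
}

#' Collected sweat volume range from gland physiology
#'
#' The volume collected in one sampling is sampling duration x contact
#' area x sweat rate; known fingertip sweat rates at rest bracket the
#' per-sample volume.
#'
#' @param duration_min Sampling duration in minutes.
#' @param area_cm2 Skin contact area in cm^2.
#' @param rate_lo,rate_hi Sweat rate bounds in nL/min/cm^2.
#' @return Named numeric `c(lo, hi)` in nL.
#' @examples
#' sweatVolumeRange(2, 2, 50, 500)   # 200 to 2000 nL
#' @export
sweatVolumeRange <- function(duration_min, area_cm2, rate_lo, rate_hi) {
  stopifnot(duration_min >= 0, area_cm2 >= 0, rate_lo >= 0,
            rate_hi >= rate_lo)
  c(lo = duration_min * area_cm2 * rate_lo,
    hi = duration_min * area_cm2 * rate_hi)
}
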