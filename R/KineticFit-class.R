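#' KineticFit: result of fitting one volunteer profile
#'
#' Holds the best multi-start solution: the eight rate constants, the
#' initial state, the fitted sweat volume per time-point, the robust loss
#' at the optimum, the selected loss shape `alpha` and scale, the adjusted
#' R-squared, optional confidence intervals, and the per-start convergence
#' log. All estimates respect the model bounds exactly.
#'
#' @slot rates Named numeric, `k1..k8` (1/h).
#' @slot init Named numeric over [SPECIES], concentrations at t = 0 (ug/L).
#' @slot volumes Named numeric, fitted sweat volume per time-point (uL).
#' @slot times Numeric, the distinct sampling times (h).
#' @slot loss Total robust loss at the optimum.
#' @slot alpha,scale Selected robust-loss settings.
#' @slot adjR2 Adjusted R-squared over non-censored observations.
#' @slot ci `data.frame` of confidence intervals (possibly empty).
#' @slot nObs Number of non-censored observations fitted.
#' @slot dfResidual Residual degrees of freedom, `nObs - (11 + T)`.
#' @slot convergence Per-start log (`alpha`, `start`, `loss`, `converged`,
#'   `message`).
#' @slot seed Master seed of the multi-start draw.
#' @slot params The fixed constants used (as a list).
#' @aliases KineticFit-class
#' @exportClass KineticFit
setClass("KineticFit",
         representation(rates = "numeric", init = "numeric",
                        volumes = "numeric", times = "numeric",
                        loss = "numeric", alpha = "numeric",
                        scale = "numeric", adjR2 = "numeric",
                        ci = "data.frame", nObs = "integer",
                        dfResidual = "integer", convergence = "data.frame",
                        seed = "integer", params = "list"))

setValidity("KineticFit", function(object) {
  msg <- character()
  if (length(object@rates) != 8L) msg <- c(msg, "rates must have length 8")
  if (length(object@volumes) != length(object@times))
    msg <- c(msg, "one volume per time-point required")
  b <- .fitBounds(length(object@volumes))
  est <- c(object@rates, object@init[2:4], object@volumes)
  if (length(est) == length(b$lower) &&
      (any(est < b$lower - 1e-12) || any(est > b$upper + 1e-12)))
    msg <- c(msg, "estimates violate the model bounds")
  if (length(msg)) msg else TRUE
})

#' @describeIn KineticFit-accessors fitted rate constants `k1..k8`
#' @export
fittedRates <- function(fit) fit@rates

#' Accessors for KineticFit
#' @name KineticFit-accessors
#' @param fit A [KineticFit-class] object.
NULL

#' @describeIn KineticFit-accessors fitted sweat volumes (uL), one per
#'   time-point
#' @export
sweatVolumes <- function(fit) fit@volumes

#' @describeIn KineticFit-accessors fitted initial concentrations (ug/L)
#' @export
initialConcentrations <- function(fit) fit@init

#' @describeIn KineticFit-accessors total robust loss of the best start
#' @export
fitLoss <- function(fit) fit@loss

#' @describeIn KineticFit-accessors adjusted R-squared of the fit
#' @export
fitAdjR2 <- function(fit) fit@adjR2

#' @describeIn KineticFit-accessors per-start convergence log
#' @export
startLog <- function(fit) fit@convergence

#' @describeIn KineticFit-accessors fitted concentration trajectory on a
#'   time grid (defaults to the sampling grid)
#' @param times Time grid in hours.
#' @export
fittedTrajectory <- function(fit, times = fit@times) {
  simulateConcentrations(fit@rates, do.call(pkParams, fit@params),
                         fit@init, times)
}

setMethod("show", "KineticFit", function(object) {
  cat("KineticFit:", length(object@times), "time-points,",
      object@nObs, "observations, df =", object@dfResidual, "\n")
  cat(sprintf("  loss = %.6g (alpha = %g, scale = %.4g), adj R^2 = %.4f\n",
              object@loss, object@alpha, object@scale, object@adjR2))
  k <- object@rates
  cat(sprintf("  k1 = %.3g /h; conversion k2..k4 = %.3g, %.3g, %.3g /h\n",
              k[1], k[2], k[3], k[4]))
  cat(sprintf("  elimination k5..k8 = %.3g, %.3g, %.3g, %.3g /h\n",
              k[5], k[6], k[7], k[8]))
  cat(sprintf("  V_sweat in [%.3g, %.3g] uL\n",
              min(object@volumes), max(object@volumes)))
  invisible(object)
})
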