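#' Fitting configuration
#'
#' Settings for [fitProfile()]: parameter bounds are fixed by the model
#' (`k1 <= 10`, `k2..k8 <= 0.2` 1/h, product baselines `<= 1` ug/L,
#' sweat volumes in `[0.05, 4]` uL); the knobs here control the multi-start
#' search and the robust loss.
#'
#' @param nStarts Number of Monte-Carlo restarts; each start draws an
#'   initial parameter vector uniformly within the bounds (default 100).
#' @param seed Master seed for the start draws; the fit is deterministic
#'   given the seed.
#' @param ftol Optimizer convergence tolerance (default 1e-8).
#' @param alphaGrid Shape parameters of the general robust loss tried in an
#'   outer grid search; the fit with the highest adjusted R-squared wins.
#'   `2` is plain least squares, smaller values down-weight outliers.
#' @param scale Robust-loss scale `c`; default (`NULL`) uses the median
#'   absolute non-censored signal.
#'
#' @return A list of class `fitConfig`.
#' @export
fitConfig <- function(nStarts = 100, seed = 1L, ftol = 1e-8,
                      alphaGrid = c(2, 1, 0.5, 0), scale = NULL) {
  stopifnot(nStarts >= 1, is.numeric(seed), ftol > 0,
            length(alphaGrid) >= 1)
  if (!is.null(scale) && scale <= 0) stop("scale must be > 0")
  structure(list(nStarts = as.integer(nStarts), seed = as.integer(seed),
                 ftol = ftol, alphaGrid = alphaGrid, scale = scale),
            class = "fitConfig")
}

#' General robust loss
#'
#' The one-parameter family that interpolates between squared (`alpha = 2`),
#' pseudo-Huber / smooth L1 (`alpha = 1`), Cauchy (`alpha = 0`) and Welsch
#' (`alpha = -Inf`) losses:
#' `rho(x, alpha, c) = (|alpha - 2| / alpha) * (((x/c)^2 / |alpha - 2| + 1)^(alpha/2) - 1)`
#' with the standard analytic limits at `alpha = 2`, `0` and `-Inf`.
#' It is even, zero at zero, and non-decreasing in `|x|`.
#'
#' @param x Residual(s).
#' @param alpha Shape parameter.
#' @param scale Scale `c > 0`.
#' @return Loss value(s), same length as `x`.
#' @examples
#' robustLoss(1, alpha = 2, scale = 1)    # 0.5
#' robustLoss(1, alpha = 1, scale = 1)    # sqrt(2) - 1
#' @export
robustLoss <- function(x, alpha, scale) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a single value > 0")
  z2 <- (x / scale)^2
  if (alpha == 2) return(0.5 * z2)
  if (alpha == 0) return(log1p(0.5 * z2))
  if (is.infinite(alpha) && alpha < 0) return(-expm1(-0.5 * z2))
  b <- abs(alpha - 2)
  (b / alpha) * ((z2 / b + 1)^(alpha / 2) - 1)
}

#' Pack / unpack the fitted parameter vector
#'
#' The optimizer works on one flat vector in the fixed order
#' `[k1..k8, c0_paraxanthine, c0_theobromine, c0_theophylline,
#' V_sweat(t_1)..V_sweat(t_T)]`, i.e. length `11 + T`: the per-time-point
#' sweat volumes are free parameters alongside the kinetics.
#'
#' @param rates Rate constants ([rateConstants()]).
#' @param init Initial state ([initialState()]).
#' @param volumes Sweat volumes, one per time-point.
#' @return `packParameters`: numeric vector of length `11 + T`.
#' @export
packParameters <- function(rates, init, volumes) {
  rates <- rateConstants(rates)
  if (length(init) != 4L) init <- initialState(init)
  volumes <- as.numeric(volumes)
  if (length(volumes) < 1L) stop("need at least one sweat volume")
  c(unname(rates), unname(init[2:4]), volumes)
}

#' @rdname packParameters
#' @param vec Packed parameter vector.
#' @param nTimes Number of time-points `T`.
#' @return `unpackParameters`: list with `rates`, `init`, `volumes`.
#' @export
unpackParameters <- function(vec, nTimes) {
  nTimes <- as.integer(nTimes)
  if (nTimes < 1L) stop("nTimes must be >= 1")
  if (length(vec) != 11L + nTimes)
    stop("expected length ", 11L + nTimes, ", got ", length(vec))
  list(rates = setNames(vec[1:8], paste0("k", 1:8)),
       init = setNames(c(0, vec[9:11]), SPECIES),
       volumes = vec[12:(11L + nTimes)])
}

.fitBounds <- function(nTimes) {
  list(lower = c(rep(0, 11L), rep(.VSWEAT_MIN, nTimes)),
       upper = c(.K1_MAX, rep(.K_MAX, 7L), rep(.C0_MAX, 3L),
                 rep(.VSWEAT_MAX, nTimes)))
}

# residuals r = V(t_j) * C_i(t_j) - signal over non-censored entries;
# ordering: species fastest, then sample column
.profileResiduals <- function(vec, times, timeIdx, sig, keep, params) {
  conc <- .concMatrix(vec[1:8], params, c(0, vec[9:11]), times)
  v <- vec[-(1:11)]
  pred <- t(conc)[, timeIdx, drop = FALSE] * rep(v[timeIdx], each = 4L)
  (pred - sig)[keep]
}

#' Total robust loss of a parameter vector against a measurement table
#'
#' Evaluates the model at the packed parameters and accumulates the robust
#' loss of the residuals `V_sweat(t_j) * C_i(t_j) - signal` over every
#' non-censored observation (technical replicates enter individually).
#'
#' @param vec Packed parameter vector (length `11 + T`).
#' @param x A [SweatMeasurements-class] object.
#' @param params [pkParams()].
#' @param alpha,scale Robust-loss settings ([robustLoss()]); `scale = NULL`
#'   uses the median absolute non-censored signal.
#' @return Total loss, with the residual vector as attribute `"residuals"`.
#' @export
profileObjective <- function(vec, x, params = pkParams(), alpha = 2,
                             scale = NULL) {
  stopifnot(is(x, "SweatMeasurements"))
  times <- sampleTimes(x)
  sig <- signalMatrix(x)
  keep <- !censoredMatrix(x)
  if (!any(keep)) stop("no usable observations: all entries censored")
  if (is.null(scale)) scale <- stats::median(abs(sig[keep]))
  if (scale <= 0) stop("degenerate scale: non-censored signals are all zero")
  timeIdx <- match(SummarizedExperiment::colData(x)$time_h, times)
  r <- .profileResiduals(vec, times, timeIdx, sig, keep, params)
  out <- sum(robustLoss(r, alpha, scale))
  attr(out, "residuals") <- r
  out
}

#' Fit a volunteer profile
#'
#' Estimates the eight rate constants, the three product baseline
#' concentrations and one sweat volume per time-point by bounded
#' least-squares on the robust-loss-transformed residuals, restarted from
#' `nStarts` random initial points and keeping the lowest-loss solution.
#' The minimisation uses the Levenberg-Marquardt implementation in
#' \pkg{minpack.lm} with box constraints; the robust loss is folded into
#' the residuals as `sign(r) * sqrt(2 rho(r))` so that the sum of squares
#' of the transformed residuals equals twice the total robust loss and the
#' two problems share their minimisers. When `alphaGrid` has several
#' entries the whole multi-start search runs per shape parameter and the
#' fit with the highest adjusted R-squared is returned.
#'
#' @param x A [SweatMeasurements-class] profile.
#' @param params Fixed constants, [pkParams()].
#' @param config [fitConfig()].
#' @return A [KineticFit-class] object.
#' @seealso [adjustedR2()], [confidenceIntervals()]
#' @export
fitProfile <- function(x, params = pkParams(), config = fitConfig()) {
  stopifnot(is(x, "SweatMeasurements"), inherits(config, "fitConfig"))
  times <- sampleTimes(x)
  nT <- length(times)
  sig <- signalMatrix(x)
  keep <- !censoredMatrix(x)
  if (!any(keep)) stop("no usable observations: all entries censored")
  nObs <- sum(keep)
  npar <- 11L + nT
  if (nObs <= npar + 1L)
    stop("not enough observations (", nObs, ") for ", npar, " parameters")
  scale <- config$scale
  if (is.null(scale)) scale <- stats::median(abs(sig[keep]))
  if (scale <= 0) stop("degenerate scale: non-censored signals are all zero")
  timeIdx <- match(SummarizedExperiment::colData(x)$time_h, times)
  b <- .fitBounds(nT)

  # all starts drawn up-front so that results for nStarts = m are a prefix
  # of the results for nStarts > m under the same seed
  set.seed(config$seed)
  starts <- matrix(0, config$nStarts, npar)
  for (i in seq_len(config$nStarts))
    starts[i, ] <- runif(npar, b$lower, b$upper)

  # the signal model V(t_j) * C_i(t_j) is conditionally linear in the
  # product baselines c0 (the concentration splits into a dose-driven part
  # plus c0_i exp(-k_elim,i t)) and, for fixed concentrations, in each
  # per-time-point volume. Each start therefore searches only the 8 rate
  # constants, with (c0, V) profiled out by alternating clipped
  # least-squares updates (variable projection), before a joint polish of
  # the full parameter vector under the requested robust loss.
  keepN <- keep * 1
  projectCV <- function(k8) {
    cd <- t(.concMatrix(k8, params, rep(0, 4L), times))  # species x time
    bas <- rbind(0, exp(-outer(k8[6:8], times)))         # baseline decay
    cdS <- cd[, timeIdx, drop = FALSE]                   # per sample column
    basS <- bas[, timeIdx, drop = FALSE]
    c0 <- c(0, 0, 0)
    for (it in 1:8) {
      ccS <- cdS + basS * c(0, c0)
      num <- rowsum(colSums(keepN * ccS * sig), timeIdx)
      den <- rowsum(colSums(keepN * ccS * ccS), timeIdx)
      v <- as.vector(num / den)
      v[!is.finite(v)] <- .VSWEAT_MIN
      v <- pmin(pmax(v, .VSWEAT_MIN), .VSWEAT_MAX)
      vS <- v[timeIdx]
      c0new <- vapply(1:3, function(p) {
        i <- p + 1L
        w <- vS * basS[i, ]
        ki <- keep[i, ]
        num <- sum(w[ki] * (sig[i, ki] - vS[ki] * cdS[i, ki]))
        den <- sum(w[ki]^2)
        if (den == 0) return(0)
        min(max(num / den, 0), .C0_MAX)
      }, 0)
      if (max(abs(c0new - c0)) < 1e-12) { c0 <- c0new; break }
      c0 <- c0new
    }
    c(c0, v)
  }
  ctl <- minpack.lm::nls.lm.control(
    ftol = config$ftol, ptol = config$ftol, gtol = 0,
    maxiter = 1000, maxfev = 100000L)
  # the joint polish per start is capped: stage 1 does the global work and
  # the winning start gets a final tight polish below
  ctl2 <- minpack.lm::nls.lm.control(
    ftol = config$ftol, ptol = config$ftol, gtol = 0,
    maxiter = 150, maxfev = 100000L)

  runOne <- function(start, alpha) {
    fres <- function(p) {
      r <- .profileResiduals(p, times, timeIdx, sig, keep, params)
      if (alpha == 2) r / scale
      else sign(r) * sqrt(2 * robustLoss(r, alpha, scale))
    }
    fresKin <- function(k8) fres(c(k8, projectCV(k8)))
    lmKin <- function(st) try(minpack.lm::nls.lm(
      par = st, lower = b$lower[1:8], upper = b$upper[1:8],
      fn = fresKin, control = ctl), silent = TRUE)
    stage1 <- lmKin(start[1:8])
    if (!inherits(stage1, "try-error")) {
      # soft degeneracy: shifting k1 and all eliminations k5..k8 by delta
      # rescales every concentration by ((k1+delta)/k1) exp(-delta t),
      # which the free volumes absorb until a bound clips. Local minima
      # line up along that direction; a coarse line search with re-polish
      # escapes them.
      kin <- stage1$par
      ss0 <- sum(fresKin(kin)^2)
      tilt <- function(kin, d) {
        kin2 <- kin
        kin2[1] <- min(max(kin2[1] + d, 0), .K1_MAX)
        kin2[5:8] <- pmin(pmax(kin2[5:8] + d, 0), .K_MAX)
        kin2
      }
      grid <- seq(-0.15, 0.15, by = 0.01)
      ssd <- vapply(grid, function(d) sum(fresKin(tilt(kin, d))^2), 0)
      for (d in grid[order(ssd)][1:3]) {
        if (d == 0) next
        s2 <- lmKin(tilt(kin, d))
        if (!inherits(s2, "try-error")) {
          ss2 <- sum(fresKin(s2$par)^2)
          if (ss2 < ss0) { ss0 <- ss2; stage1 <- s2 }
        }
      }
    }
    start2 <- if (inherits(stage1, "try-error")) start
              else c(stage1$par, projectCV(stage1$par))
    fit <- try(minpack.lm::nls.lm(
      par = start2, lower = b$lower, upper = b$upper, fn = fres,
      control = ctl2), silent = TRUE)
    if (inherits(fit, "try-error"))
      return(list(ok = FALSE, loss = Inf,
                  message = attr(fit, "condition")$message))
    r <- .profileResiduals(fit$par, times, timeIdx, sig, keep, params)
    loss <- sum(robustLoss(r, alpha, scale))
    list(ok = is.finite(loss), loss = loss, par = fit$par,
         info = fit$info, message = fit$message)
  }

  bestOverall <- NULL
  logs <- list()
  for (alpha in config$alphaGrid) {
    best <- NULL
    for (i in seq_len(config$nStarts)) {
      res <- runOne(starts[i, ], alpha)
      logs[[length(logs) + 1L]] <- data.frame(
        alpha = alpha, start = i, loss = res$loss, converged = res$ok,
        message = if (is.null(res$message)) "" else res$message,
        stringsAsFactors = FALSE)
      if (res$ok && (is.null(best) || res$loss < best$loss)) best <- res
    }
    if (is.null(best)) next
    p <- unpackParameters(best$par, nT)
    tr <- simulateConcentrations(p$rates, params, p$init, times)
    pred <- t(tr$conc)[, timeIdx, drop = FALSE] *
      rep(p$volumes[timeIdx], each = 4L)
    r2 <- adjustedR2(sig[keep], pred[keep], npar)
    cand <- list(alpha = alpha, loss = best$loss, par = best$par,
                 adjR2 = r2)
    if (is.null(bestOverall) || r2 > bestOverall$adjR2) bestOverall <- cand
  }
  if (is.null(bestOverall))
    stop("all optimizer starts failed; see the per-start log")
  # final polish of the winning solution at tight tolerances: the loss
  # surface is nearly flat along the tilt direction and the default
  # stopping rule can halt short of the floor
  polish <- try(minpack.lm::nls.lm(
    par = bestOverall$par, lower = b$lower, upper = b$upper,
    fn = function(p) {
      r <- .profileResiduals(p, times, timeIdx, sig, keep, params)
      if (bestOverall$alpha == 2) r / scale
      else sign(r) * sqrt(2 * robustLoss(r, bestOverall$alpha, scale))
    },
    control = minpack.lm::nls.lm.control(
      ftol = 1e-15, ptol = 1e-15, gtol = 0,
      maxiter = 1024, maxfev = 100000L)), silent = TRUE)
  if (!inherits(polish, "try-error")) {
    r <- .profileResiduals(polish$par, times, timeIdx, sig, keep, params)
    lp <- sum(robustLoss(r, bestOverall$alpha, scale))
    if (is.finite(lp) && lp <= bestOverall$loss) {
      bestOverall$loss <- lp
      bestOverall$par <- polish$par
      p <- unpackParameters(polish$par, nT)
      tr <- simulateConcentrations(p$rates, params, p$init, times)
      pred <- t(tr$conc)[, timeIdx, drop = FALSE] *
        rep(p$volumes[timeIdx], each = 4L)
      bestOverall$adjR2 <- adjustedR2(sig[keep], pred[keep], npar)
    }
  }
  p <- unpackParameters(bestOverall$par, nT)
  new("KineticFit",
      rates = p$rates,
      init = p$init,
      volumes = setNames(p$volumes, sprintf("t%g", times)),
      times = times,
      loss = bestOverall$loss,
      alpha = bestOverall$alpha,
      scale = scale,
      adjR2 = bestOverall$adjR2,
      ci = data.frame(),
      nObs = nObs,
      dfResidual = nObs - npar,
      convergence = do.call(rbind, logs),
      seed = config$seed,
      params = unclass(params))
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - R^2) (n - 1) / (n - p - 1)` with `R^2` computed against the
#' mean of the observed values; the per-profile goodness-of-fit measure.
#'
#' @param observed,fitted Numeric vectors of equal length.
#' @param nParams Number of fitted parameters `p`.
#' @return Adjusted R-squared.
#' @examples
#' adjustedR2(1:10, 1:10, 3)   # 1
#' @export
adjustedR2 <- function(observed, fitted, nParams) {
  n <- length(observed)
  stopifnot(length(fitted) == n)
  if (n <= nParams + 1L)
    stop("need more observations than parameters + 1")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("observed values are constant")
  r2 <- 1 - sum((observed - fitted)^2) / sst
  1 - (1 - r2) * (n - 1) / (n - nParams - 1)
}

#' Confidence intervals from externally estimated coefficients of variation
#'
#' Each fitted parameter gets a symmetric t-interval
#' `estimate +/- t(0.975, df) * CV * estimate`, with the CVs coming from a
#' separate sensitivity analysis of the fitting procedure (they are not
#' derivable from a single fit).
#'
#' @param estimates Named numeric vector of parameter estimates.
#' @param cv Per-parameter CVs: a single value recycled to all parameters,
#'   or a vector named like `estimates`.
#' @param df Residual degrees of freedom (default taken from `fit` when the
#'   first argument is a [KineticFit-class]).
#' @return `data.frame` with columns `estimate`, `lower`, `upper`.
#' @examples
#' confidenceIntervals(c(k1 = 1), cv = 0.1, df = 93)
#' @export
confidenceIntervals <- function(estimates, cv, df = NULL) {
  if (is(estimates, "KineticFit")) {
    fit <- estimates
    if (is.null(df)) df <- fit@dfResidual
    estimates <- c(fit@rates, setNames(fit@init[2:4],
                                       paste0("c0_", SPECIES[2:4])),
                   setNames(fit@volumes, paste0("V_", names(fit@volumes))))
  }
  if (is.null(df) || df < 1) stop("df must be >= 1")
  if (any(cv < 0) || any(!is.finite(cv))) stop("CVs must be finite and >= 0")
  if (length(cv) == 1L && is.null(names(cv)))
    cv <- setNames(rep(cv, length(estimates)), names(estimates))
  miss <- setdiff(names(estimates), names(cv))
  if (length(miss))
    stop("missing CV for parameter(s): ", paste(miss, collapse = ", "))
  half <- qt(0.975, df) * cv[names(estimates)] * abs(estimates)
  data.frame(estimate = unname(estimates),
             lower = unname(estimates - half),
             upper = unname(estimates + half),
             row.names = names(estimates))
}
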