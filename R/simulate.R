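#' @title Closed-form kinetics of the caffeine network
#' @name kinetics
#' @description
#' The network is a linear first-order cascade: an absorbed caffeine depot
#' (amount `F * dose` at t = 0) drains into the body compartment with rate
#' `k1`; body caffeine is converted to paraxanthine, theobromine and
#' theophylline with rates `k2`, `k3`, `k4` and eliminated directly with
#' `k5`; each product is eliminated with `k6`, `k7`, `k8`. Because the
#' system is linear its solution is a sum of exponentials; the package
#' evaluates it in closed form, with analytic limits where eigenvalues
#' collide. All internal bookkeeping is in moles (demethylation is 1:1
#' molar); concentrations are reported as mass per volume via the species'
#' molar mass and volume of distribution.
NULL

# E(a, b, t) = (exp(-b t) - exp(-a t)) / (a - b), the first divided
# difference of exp(-x t); continuous limit t exp(-a t) at a = b.
# expm1 keeps full precision when (a - b) t is tiny. Vectorized over t.
.edif <- function(a, b, t) {
  d <- abs(a - b)
  if (d < 1e-300) return(t * exp(-a * t))
  # factor out the slower decay so nothing overflows at large t; the
  # expm1 form is cancellation-free for any non-zero spacing
  exp(-min(a, b) * t) * (-expm1(-d * t)) / d
}

# conv(a, b, c, t) = int_0^t E(a, b, s) exp(-c (t - s)) ds
#                  = (E(b, c, t) - E(a, c, t)) / (a - b),
# the second divided difference of exp(-x t). Unlike .edif this does
# subtract like-sized terms; where the products (a-b) t or (m-c) t fall
# below ~1e-5 the difference loses precision and the analytic confluent
# limit at the midpoint takes over (its O((spacing * t)^2) error is
# below 1e-10 at the crossover). Branching is per element of t because
# cancellation is worst at small t.
.edif2 <- function(a, b, c, t) {
  out <- numeric(length(t))
  u <- abs(a - b) * t
  big <- u >= 1e-5
  if (any(big))
    out[big] <- (.edif(b, c, t[big]) - .edif(a, c, t[big])) / (a - b)
  if (any(!big)) {
    m <- (a + b) / 2                 # lim: -d/dm E(m, c, t)
    ts <- t[!big]
    v <- abs(m - c) * ts
    r <- numeric(length(ts))
    b2 <- v >= 1e-5
    if (any(b2))
      r[b2] <- (.edif(m, c, ts[b2]) - ts[b2] * exp(-m * ts[b2])) / (m - c)
    if (any(!b2))
      r[!b2] <- 0.5 * ts[!b2]^2 * exp(-((m + c) / 2) * ts[!b2])
    out[!big] <- r
  }
  out
}

.checkTimes <- function(times) {
  if (!is.numeric(times) || length(times) < 1L || any(!is.finite(times)))
    stop("times must be finite numeric")
  if (any(times < 0)) stop("times must be non-negative")
  if (is.unsorted(times)) stop("times must be sorted increasingly")
  as.numeric(times)
}

# initial molar state: gut depot + body amounts (umol)
.molarInit <- function(params, init) {
  a0 <- params$dose * params$bioavailability * 1e3 /
    params$molarMass["caffeine"]               # mg -> ug -> umol
  x0 <- init * params$vd / params$molarMass    # ug/L * L / (g/mol) = umol
  c(gut = unname(a0), x0)
}

#' Simulate body concentrations of the caffeine network
#'
#' Evaluates the closed-form solution of the linear kinetic cascade on a
#' time grid.
#'
#' @param rates Rate constants from [rateConstants()].
#' @param params Fixed constants from [pkParams()].
#' @param init Initial state from [initialState()].
#' @param times Sampling times in hours, sorted, non-negative.
#'
#' @return An object of class `concTrajectory`: a list with `times` (hours)
#'   and `conc`, a `length(times) x 4` matrix of concentrations in ug/L with
#'   columns [SPECIES].
#' @seealso [odeOracle()] for an independent numerical solution,
#'   [predictedSignal()] to map concentrations to sweat signals.
#' @examples
#' k <- rateConstants(k1 = 3, k2 = 0.08, k3 = 0.03, k4 = 0.02, k5 = 0.02,
#'                    k6 = 0.05, k7 = 0.05, k8 = 0.05)
#' tr <- simulateConcentrations(k, times = seq(0, 24, by = 0.5))
#' matplot(tr$times, tr$conc, type = "l")
#' @export
simulateConcentrations <- function(rates, params = pkParams(),
                                   init = initialState(), times) {
  rates <- rateConstants(rates)
  times <- .checkTimes(times)
  stopifnot(inherits(params, "pkParams"))
  if (length(init) != 4L) init <- initialState(init)

  conc <- .concMatrix(rates, params, init, times)
  structure(list(times = times, conc = conc), class = "concTrajectory")
}

# vectorized closed-form evaluation without argument validation; the fast
# path used inside the optimizer
.concMatrix <- function(rates, params, init, times) {
  m0 <- .molarInit(params, init)
  a0 <- m0[["gut"]]
  kap <- sum(rates[2:5])                    # total caffeine outflow
  kel <- rates[6:8]                         # product eliminations
  x1 <- a0 * rates[1] * .edif(rates[1], kap, times)
  conc <- matrix(0, length(times), 4L, dimnames = list(NULL, SPECIES))
  conc[, 1] <- x1
  for (p in 1:3) {
    conc[, p + 1L] <- m0[2L + p] * exp(-kel[p] * times) +
      rates[1L + p] * a0 * rates[1] * .edif2(rates[1], kap, kel[p], times)
  }
  conc <- sweep(conc, 2L, params$molarMass / params$vd, `*`)
  conc[conc < 0 & conc > -1e-12] <- 0
  conc
}

#' @export
print.concTrajectory <- function(x, ...) {
  cat("concTrajectory:", length(x$times), "time-points,",
      sprintf("t in [%g, %g] h\n", min(x$times), max(x$times)))
  cat("  peak concentrations (ug/L):",
      paste(sprintf("%s=%.3g", SPECIES, apply(x$conc, 2, max)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Explicit Bateman solution for the caffeine channel
#'
#' Caffeine follows first-order absorption feeding first-order outflow
#' (conversion plus direct elimination), i.e. Bateman-type kinetics:
#' `C(t) = F D k1 / (Vd (k1 - kappa)) (exp(-kappa t) - exp(-k1 t))` with
#' `kappa = k2 + k3 + k4 + k5`, and the analytic limit
#' `F D k1 t exp(-k1 t) / Vd` when `k1` equals `kappa`.
#'
#' @inheritParams simulateConcentrations
#' @param t Time(s) in hours, non-negative.
#' @return Caffeine concentration(s) in ug/L.
#' @export
caffeineClosedForm <- function(rates, params = pkParams(), t) {
  rates <- rateConstants(rates)
  t <- .checkTimes(t)
  fd <- params$dose * params$bioavailability * 1e3 / params$vd["caffeine"]
  kap <- sum(rates[2:5])
  unname(fd * rates[1] * vapply(t, function(ti) .edif(rates[1], kap, ti), 0))
}

#' Map body concentrations to measured sweat signals
#'
#' The measured quantity at each time-point is the body concentration scaled
#' by the (unknown, fluctuating) sweat volume collected at that time-point:
#' `M(t_j) = V_sweat(t_j) * C_i(t_j)`, with one shared volume for all four
#' species at a time-point.
#'
#' @param traj A `concTrajectory` from [simulateConcentrations()], or a bare
#'   time x species concentration matrix.
#' @param volumes Sweat volumes in uL, one per time-point.
#' @return Matrix (time x species) of predicted signals.
#' @export
predictedSignal <- function(traj, volumes) {
  conc <- if (inherits(traj, "concTrajectory")) traj$conc else as.matrix(traj)
  volumes <- as.numeric(volumes)
  if (length(volumes) != nrow(conc))
    stop("need one sweat volume per time-point (", nrow(conc), "), got ",
         length(volumes))
  if (any(!is.finite(volumes)) || any(volumes < 0))
    stop("sweat volumes must be finite and non-negative")
  conc * volumes
}

#' Numerical integration oracle for the kinetic network
#'
#' Solves the same molar ODE system with `deSolve::lsoda` at tight
#' tolerances. It exists as an independent cross-check of the closed-form
#' solution and is not used in fitting.
#'
#' @inheritParams simulateConcentrations
#' @param rtol,atol Integrator tolerances.
#' @return A `concTrajectory`, plus attribute `gutMoles` with the depot
#'   amount (umol) at each time for conservation checks.
#' @export
odeOracle <- function(rates, params = pkParams(), init = initialState(),
                      times, rtol = 1e-13, atol = 1e-14) {
  rates <- rateConstants(rates)
  times <- .checkTimes(times)
  if (length(init) != 4L) init <- initialState(init)
  m0 <- .molarInit(params, init)
  kap <- sum(rates[2:5])
  deriv <- function(t, y, p) {
    dg <- -rates[1] * y[1]
    dx1 <- rates[1] * y[1] - kap * y[2]
    dxp <- rates[2:4] * y[2] - rates[6:8] * y[3:5]
    list(c(dg, dx1, dxp))
  }
  t0 <- times
  if (t0[1] > 0) t0 <- c(0, t0)
  sol <- deSolve::lsoda(unname(m0), t0, deriv, NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) stop("ODE integration failed")
  sol <- sol[match(times, t0), , drop = FALSE]
  moles <- sol[, 3:6, drop = FALSE]
  conc <- sweep(moles, 2, params$molarMass / params$vd, `*`)
  colnames(conc) <- SPECIES
  out <- structure(list(times = times, conc = conc), class = "concTrajectory")
  attr(out, "gutMoles") <- sol[, 2]
  attr(out, "bodyMoles") <- moles
  out
}

#' Export a trajectory as a tidy data frame
#'
#' @param traj A `concTrajectory`.
#' @return `data.frame` with columns `time_h`, `species`,
#'   `concentration_ug_per_L`.
#' @export
asTidyTrajectory <- function(traj) {
  stopifnot(inherits(traj, "concTrajectory"))
  data.frame(
    time_h = rep(traj$times, times = 4L),
    species = rep(SPECIES, each = length(traj$times)),
    concentration_ug_per_L = as.vector(traj$conc),
    stringsAsFactors = FALSE
  )
}
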