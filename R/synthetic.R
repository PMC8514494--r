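#' Study sampling designs
#'
#' Returns the sampling grid and design constants of the intervention
#' studies: short observational/coffee grids (A, B) and the two caffeine
#' capsule studies (C1 with 15 time-points over 27 h, C2 with 20
#' time-points over 24 h). All designs use a 200 mg dose equivalent and
#' technical duplicates by default.
#'
#' @param name One of `"A"`, `"B"`, `"C1"`, `"C2"`.
#' @param nReplicates Technical replicates per time-point (default 2).
#' @param dose Dose in mg (default 200).
#' @param fasting_h Caffeine fasting period before dosing, hours; drives
#'   the baseline rule of [generateProfile()] (long fasting implies
#'   near-zero product baselines).
#'
#' @return A list of class `studyDesign` with `grid_min`, `grid_h`,
#'   `nReplicates`, `dose`, `fasting_h`.
#' @examples
#' studyDesign("C2")
#' @export
studyDesign <- function(name = c("C2", "C1", "A", "B"), nReplicates = 2,
                        dose = 200, fasting_h = NULL) {
  name <- match.arg(name)
  grids <- list(
    A  = c(0, 15, 30, 45, 60, 90, 120),
    B  = c(0, 15, 30, 45, 60, 90, 120),
    C1 = c(0, 15, 30, 45, 60, 90, 120, 3 * 60, 4 * 60, 6 * 60, 8 * 60,
           24 * 60, 25 * 60, 26 * 60, 27 * 60),
    C2 = c(0, 15, 30, 45, 60, 90, 120, (3:14) * 60, 24 * 60)
  )
  fast <- list(A = 12, B = 12, C1 = 48, C2 = 72)
  if (is.null(fasting_h)) fasting_h <- fast[[name]]
  grid <- grids[[name]]
  stopifnot(nReplicates >= 1, dose > 0)
  structure(list(name = name, grid_min = grid, grid_h = grid / 60,
                 nReplicates = as.integer(nReplicates), dose = dose,
                 fasting_h = fasting_h),
            class = "studyDesign")
}

#' Noise model for synthetic profiles
#'
#' @param cv Technical coefficient of variation of the multiplicative
#'   log-normal measurement noise (fraction; default 0.10, matching the
#'   observed internal-standard AUC variability).
#' @param volumeProcess `"loguniform"` draws each time-point's sweat volume
#'   independently, log-uniform on `[0.05, 4]` uL; `"ar1"` adds temporal
#'   autocorrelation on the log scale for realism studies.
#' @param ar1Rho Autocorrelation of the AR(1) option.
#' @param lod Censoring threshold in signal units (rows below are flagged
#'   censored; default 0 = no censoring).
#' @param noiseFloor Additive Gaussian noise floor (signal units, sd),
#'   modelling blank-level noise; default 0.
#'
#' @return A list of class `noiseModel`.
#' @export
noiseModel <- function(cv = 0.10, volumeProcess = c("loguniform", "ar1"),
                       ar1Rho = 0.7, lod = 0, noiseFloor = 0) {
  volumeProcess <- match.arg(volumeProcess)
  stopifnot(cv >= 0, lod >= 0, noiseFloor >= 0, abs(ar1Rho) < 1)
  structure(list(cv = cv, volumeProcess = volumeProcess, ar1Rho = ar1Rho,
                 lod = lod, noiseFloor = noiseFloor),
            class = "noiseModel")
}

#' Draw rate constants from a population specification
#'
#' Draws each of `k1..k8` from a normal distribution truncated to the
#' model bounds (rejection sampling). The default population centres put
#' most caffeine flux through paraxanthine, with slower theobromine and
#' theophylline branches -- the qualitative pattern of adult caffeine
#' metabolism -- and sit well inside the bounds.
#'
#' @param n Number of draws.
#' @param mean Named length-8 vector of population means (1/h).
#' @param sd Named length-8 vector of population standard deviations; zero
#'   gives the mean exactly.
#' @return For `n = 1` a named rate vector; otherwise an `n x 8` matrix.
#' @export
sampleRateConstants <- function(n = 1,
                                mean = c(k1 = 3, k2 = 0.08, k3 = 0.03,
                                         k4 = 0.02, k5 = 0.02, k6 = 0.05,
                                         k7 = 0.04, k8 = 0.06),
                                sd = c(k1 = 1, k2 = 0.02, k3 = 0.01,
                                       k4 = 0.008, k5 = 0.008, k6 = 0.015,
                                       k7 = 0.012, k8 = 0.015)) {
  mean <- mean[paste0("k", 1:8)]
  sd <- rep_len(sd, 8L)
  names(sd) <- paste0("k", 1:8)
  rateConstants(mean)   # validates the centres against the bounds
  if (any(sd < 0)) stop("sd must be >= 0")
  lo <- rep(0, 8L)
  hi <- c(.K1_MAX, rep(.K_MAX, 7L))
  draws <- matrix(0, n, 8L, dimnames = list(NULL, paste0("k", 1:8)))
  for (j in 1:8) {
    if (sd[j] == 0) { draws[, j] <- mean[j]; next }
    need <- seq_len(n)
    while (length(need)) {
      cand <- rnorm(length(need), mean[j], sd[j])
      ok <- cand >= lo[j] & cand <= hi[j]
      draws[need[ok], j] <- cand[ok]
      need <- need[!ok]
    }
  }
  if (n == 1L) draws[1, ] else draws
}

.drawVolumes <- function(nT, noise) {
  lo <- log(.VSWEAT_MIN); hi <- log(.VSWEAT_MAX)
  if (noise$volumeProcess == "loguniform")
    return(exp(runif(nT, lo, hi)))
  # AR(1) on the log scale, marginally ~ uniform(lo, hi) via probability
  # integral transform of a stationary Gaussian AR(1)
  z <- numeric(nT)
  z[1] <- rnorm(1)
  for (i in seq_len(nT - 1L))
    z[i + 1L] <- noise$ar1Rho * z[i] + sqrt(1 - noise$ar1Rho^2) * rnorm(1)
  exp(lo + (hi - lo) * stats::pnorm(z))
}

#' Generate one synthetic volunteer profile
#'
#' Simulates the kinetic network at the design's grid, draws one sweat
#' volume per time-point, forms the expected signals
#' `V_sweat(t_j) * C_i(t_j)` (shared volume across species and
#' replicates), applies multiplicative log-normal technical noise at the
#' configured CV plus an optional additive floor, and flags entries below
#' the LOD as censored. Deterministic given `seed`.
#'
#' @param truth List with `rates` ([rateConstants()]), optional `init`
#'   ([initialState()]) and optional `volumes` (per time-point, drawn from
#'   the noise model when absent).
#' @param design [studyDesign()].
#' @param noise [noiseModel()].
#' @param params [pkParams()] (the design's dose overrides `params$dose`).
#' @param seed Integer seed.
#' @return A [SweatMeasurements-class] object carrying the realized ground
#'   truth in its metadata (see [groundTruth()]).
#' @examples
#' k <- sampleRateConstants()
#' sm <- generateProfile(list(rates = k), studyDesign("C1"), seed = 7)
#' groundTruth(sm)$rates
#' @export
generateProfile <- function(truth, design = studyDesign("C2"),
                            noise = noiseModel(), params = pkParams(),
                            seed = 1L) {
  stopifnot(inherits(design, "studyDesign"), inherits(noise, "noiseModel"))
  params$dose <- design$dose
  rates <- rateConstants(truth$rates)
  set.seed(seed)
  init <- if (is.null(truth$init)) {
    # fasting baseline rule: >= 24 h fasting clears the product pool
    if (design$fasting_h >= 24) initialState(0)
    else initialState(runif(3, 0.1, .C0_MAX))
  } else if (length(truth$init) == 4L) truth$init else initialState(truth$init)
  times <- design$grid_h
  nT <- length(times)
  volumes <- if (is.null(truth$volumes)) .drawVolumes(nT, noise)
             else as.numeric(truth$volumes)
  if (length(volumes) != nT) stop("need one volume per time-point")
  if (any(volumes < .VSWEAT_MIN) || any(volumes > .VSWEAT_MAX))
    stop("volumes outside [", .VSWEAT_MIN, ", ", .VSWEAT_MAX, "] uL")

  tr <- simulateConcentrations(rates, params, init, times)
  expected <- predictedSignal(tr, volumes)   # time x species
  sdlog <- sqrt(log1p(noise$cv^2))
  rows <- list()
  for (r in seq_len(design$nReplicates)) {
    eps <- matrix(rlnorm(nT * 4L, -sdlog^2 / 2, sdlog), nT, 4L)
    sig <- expected * (if (noise$cv > 0) eps else 1)
    if (noise$noiseFloor > 0)
      sig <- pmax(sig + matrix(rnorm(nT * 4L, 0, noise$noiseFloor), nT, 4L),
                  0)
    rows[[r]] <- data.frame(
      time_h = rep(times, 4L),
      species = rep(SPECIES, each = nT),
      replicate = r,
      signal = as.vector(sig),
      censored = as.integer(as.vector(sig) < noise$lod),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  SweatMeasurements(tab, groundTruth = list(
    rates = rates, init = init, volumes = volumes,
    params = unclass(params), design = design$name, seed = seed))
}

#' Generate a synthetic cohort
#'
#' Independent volunteer profiles with per-volunteer rate constants drawn
#' from the population specification. Volunteer `i` uses seed
#' `seed + i - 1`, so cohorts are reproducible and individual profiles can
#' be regenerated in isolation.
#'
#' @param n Number of volunteer profiles (>= 1).
#' @param design,noise,params See [generateProfile()].
#' @param popMean,popSd Population location/spread passed to
#'   [sampleRateConstants()].
#' @param seed Integer master seed.
#' @return List of [SweatMeasurements-class] objects.
#' @export
generateCohort <- function(n, design = studyDesign("C2"),
                           noise = noiseModel(), params = pkParams(),
                           popMean = NULL, popSd = NULL, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  args <- list()
  if (!is.null(popMean)) args$mean <- popMean
  if (!is.null(popSd)) args$sd <- popSd
  lapply(seq_len(n), function(i) {
    set.seed(seed + i - 1L)
    k <- do.call(sampleRateConstants, c(list(n = 1), args))
    generateProfile(list(rates = k), design, noise, params,
                    seed = seed + i - 1L)
  })
}
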