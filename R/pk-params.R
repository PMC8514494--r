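#' @importFrom methods new validObject is setClass setGeneric setMethod show
#' @importFrom stats coef cor lm median optim pt qt quantile rnorm runif sd
#'   setNames rlnorm prcomp complete.cases pchisq var dt
#' @importFrom utils read.csv write.csv packageVersion
NULL

#' Metabolite species tracked by the kinetic network
#'
#' The network follows caffeine and its three primary demethylation products.
#' All containers in the package use these names, in this order.
#'
#' @format Character vector of length 4.
#' @export
SPECIES <- c("caffeine", "paraxanthine", "theobromine", "theophylline")

# molar masses, g/mol: caffeine and its three dimethylxanthine products
.MOLAR_MASS <- c(caffeine = 194.19, paraxanthine = 180.16,
                 theobromine = 180.16, theophylline = 180.16)

# hard model bounds (h^-1, ug/L, uL)
.K1_MAX <- 10
.K_MAX <- 0.2
.C0_MAX <- 1
.VSWEAT_MIN <- 0.05
.VSWEAT_MAX <- 4

#' Fixed pharmacokinetic constants
#'
#' Bundles the quantities the model treats as known: the ingested dose, oral
#' bioavailability, the steady-state volumes of distribution and the molar
#' masses of the four species. These are fixed during fitting; only the rate
#' constants, initial product concentrations and sweat volumes are estimated.
#'
#' @param dose Ingested caffeine dose in mg (default 200, one capsule).
#' @param bioavailability Fraction of the dose absorbed, in (0, 1].
#' @param vd Volume of distribution in L, either a single value used for all
#'   four species or a named vector over [SPECIES].
#' @param molarMass Molar masses in g/mol, named over [SPECIES]. The defaults
#'   are the exact values for caffeine (194.19) and the dimethylxanthines
#'   (180.16) and rarely need changing.
#'
#' @return A named list of class `pkParams`.
#' @examples
#' pkParams()
#' pkParams(dose = 100, vd = 42)
#' @export
pkParams <- function(dose = 200, bioavailability = 1, vd = 36,
                     molarMass = .MOLAR_MASS) {
  stopifnot(is.numeric(dose), length(dose) == 1L, is.finite(dose))
  if (dose <= 0) stop("dose must be > 0")
  if (!is.numeric(bioavailability) || length(bioavailability) != 1L ||
      bioavailability <= 0 || bioavailability > 1)
    stop("bioavailability must be in (0, 1]")
  vd <- .expandSpecies(vd, "vd")
  molarMass <- .expandSpecies(molarMass, "molarMass")
  if (any(vd <= 0)) stop("all vd must be > 0")
  if (any(molarMass <= 0)) stop("all molarMass must be > 0")
  structure(list(dose = dose, bioavailability = bioavailability,
                 vd = vd, molarMass = molarMass),
            class = "pkParams")
}

.expandSpecies <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(what, " must be finite numeric")
  if (length(x) == 1L) return(setNames(rep(x, 4L), SPECIES))
  if (length(x) != 4L) stop(what, " must have length 1 or 4")
  if (is.null(names(x))) names(x) <- SPECIES
  if (!setequal(names(x), SPECIES)) stop(what, " names must be the species")
  x[SPECIES]
}

#' @export
print.pkParams <- function(x, ...) {
  cat("pkParams: dose", x$dose, "mg, F =", x$bioavailability, "\n")
  cat("  Vd (L):       ", paste(sprintf("%s=%g", names(x$vd), x$vd),
                                collapse = ", "), "\n")
  cat("  molar mass:   ", paste(sprintf("%s=%g", names(x$molarMass),
                                        x$molarMass), collapse = ", "), "\n")
  invisible(x)
}

#' First-order rate constants of the caffeine network
#'
#' Validates and names the eight first-order rate constants (all in 1/h):
#' `k1` gut-to-body uptake, `k2`--`k4` conversion of caffeine to paraxanthine,
#' theobromine and theophylline, `k5` direct elimination of caffeine, and
#' `k6`--`k8` elimination of paraxanthine, theobromine and theophylline.
#' Bounds mirror the fit constraints: `k1` in \[0, 10\], `k2`--`k8` in
#' \[0, 0.2\].
#'
#' @param k1,k2,k3,k4,k5,k6,k7,k8 Rate constants in 1/h. Alternatively pass a
#'   single numeric vector of length 8 as `k1`.
#'
#' @return Named numeric vector `c(k1, ..., k8)`.
#' @examples
#' rateConstants(k1 = 3, k2 = 0.08, k3 = 0.03, k4 = 0.02, k5 = 0.02,
#'               k6 = 0.05, k7 = 0.05, k8 = 0.05)
#' @export
rateConstants <- function(k1, k2 = NULL, k3 = NULL, k4 = NULL, k5 = NULL,
                          k6 = NULL, k7 = NULL, k8 = NULL) {
  if (length(k1) == 8L && is.null(k2)) {
    k <- as.numeric(k1)
  } else {
    k <- c(k1, k2, k3, k4, k5, k6, k7, k8)
  }
  if (length(k) != 8L || !is.numeric(k) || any(!is.finite(k)))
    stop("rate constants must be 8 finite numbers")
  names(k) <- paste0("k", 1:8)
  if (k[1] < 0 || k[1] > .K1_MAX)
    stop("k1 out of bounds [0, ", .K1_MAX, "] 1/h")
  if (any(k[2:8] < 0) || any(k[2:8] > .K_MAX))
    stop("k2..k8 out of bounds [0, ", .K_MAX, "] 1/h")
  k
}

#' Initial state of the kinetic system
#'
#' The pre-dose state: the absorbed-dose depot (`F * dose`) sits in the gut
#' compartment, the body concentration of caffeine is zero (enforced by the
#' fasting design), and the dimethylxanthines may carry a small residual
#' baseline concentration in \[0, 1\] ug/L.
#'
#' @param c0 Baseline concentrations of the three products (ug/L), either a
#'   single value, or a length-3 vector ordered paraxanthine, theobromine,
#'   theophylline (names optional).
#'
#' @return Named numeric vector of length 4 over [SPECIES] (caffeine entry 0).
#' @examples
#' initialState()              # true fasting baseline
#' initialState(c(0.4, 0.8, 0.1))
#' @export
initialState <- function(c0 = 0) {
  if (!is.numeric(c0) || any(!is.finite(c0))) stop("c0 must be finite numeric")
  if (length(c0) == 1L) c0 <- rep(c0, 3L)
  if (length(c0) == 4L) {
    if (c0[1] != 0) stop("caffeine baseline must be 0 (fasting assumption)")
    c0 <- c0[2:4]
  }
  if (length(c0) != 3L) stop("c0 must have length 1, 3 or 4")
  if (any(c0 < 0) || any(c0 > .C0_MAX))
    stop("product baselines must lie in [0, ", .C0_MAX, "] ug/L")
  setNames(c(0, c0), SPECIES)
}
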