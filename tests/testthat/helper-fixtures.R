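# shared fixtures built in code

# a representative in-bounds rate vector (paraxanthine-dominant phenotype)
refRates <- function() {
  rateConstants(k1 = 2.4, k2 = 0.08, k3 = 0.025, k4 = 0.03, k5 = 0.02,
                k6 = 0.04, k7 = 0.045, k8 = 0.07)
}

# random in-bounds rate draw (uniform over the full box, unlike the
# population sampler, to probe the whole domain)
randomRates <- function() {
  rateConstants(c(runif(1, 0, 10), runif(7, 0, 0.2)))
}

# ground truth whose sweat volumes touch both bounds at late time-points;
# this pins the exponential-tilt ambiguity of the model (see the methods
# vignette) so that all parameters are identified from noise-free data
pinnedTruth <- function(design, volumeSeed = 11) {
  nT <- length(design$grid_h)
  set.seed(volumeSeed)
  v <- exp(runif(nT, log(0.05), log(4)))
  v[nT] <- 4
  v[nT - 1L] <- 0.05
  list(rates = refRates(),
       init = initialState(c(0.3, 0.5, 0.2)),
       volumes = v)
}

relErr <- function(est, truth) abs(est - truth) / pmax(abs(truth), 1e-12)
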