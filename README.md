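# sweatPK

Dynamic metabolic phenotyping from finger-sweat time series.

## The problem

Sweat from a fingertip can be sampled every few minutes and analysed by
LC-MS, but the sweat volume picked up at each sampling (roughly 0.2–2 µL)
is unknown and fluctuates strongly between time-points. A raw metabolite
signal therefore mixes two things: the metabolite's concentration in the
body and the momentary sweat volume. `sweatPK` separates them by kinetic
modelling of caffeine and its three primary metabolites (paraxanthine,
theobromine, theophylline) after a 200 mg caffeine dose.

The model is a one-compartment, first-order network: an absorbed depot
drains into the body with uptake rate *k₁*; caffeine converts to its three
products with rates *k₂, k₃, k₄* and is cleared directly with *k₅*; the
products are eliminated with *k₆, k₇, k₈*. The measured signal is

> M̃ᵢ(tⱼ) = V_sweat(tⱼ) · Cᵢ(tⱼ),

with one unknown sweat volume per time-point shared by all four species.
Fitting all species jointly (robust bounded multi-start least squares)
recovers the individual's kinetic constants, baseline product levels, and
the sweat volume at every sampling — i.e. both a personal metabolic
phenotype and a solution to the normalization problem.

The package also provides the surrounding workflow: a synthetic-data
generator with known ground truth (study designs, technical duplicates,
log-normal technical noise, LOD censoring), quantification QC (calibration
lines, LOD/LLOQ from blanks, CVs, extraction efficiency), and cohort
statistics (exact Wilcoxon signed-rank and paired t tests, normality
tests, Perseus-style s0/permutation-FDR volcano analysis, shared-control
bootstrap effect sizes, PCA of kinetic constants).

## Worked example

```r
library(sweatPK)

# a volunteer with a paraxanthine-dominant phenotype, capsule-study C1
# sampling grid (15 time-points over 27 h, technical duplicates)
k <- rateConstants(k1 = 2.4, k2 = 0.08, k3 = 0.025, k4 = 0.03, k5 = 0.02,
                   k6 = 0.04, k7 = 0.045, k8 = 0.07)
sm <- generateProfile(list(rates = k), studyDesign("C1"),
                      noiseModel(cv = 0.10), seed = 7)
sm
#> SweatMeasurements: 30 samples, 15 time-points, t in [0, 27] h
#>   censored entries: 0 of 120
#>   carries generating ground truth (synthetic profile)

fit <- fitProfile(sm, config = fitConfig(nStarts = 20, seed = 1,
                                         alphaGrid = 2))
fit
#> KineticFit: 15 time-points, 120 observations, df = 94
#>   loss = 336.301 (alpha = 2, scale = 96.37), adj R^2 = 0.9840
#>   k1 = 0.897 /h; conversion k2..k4 = 0.106, 0.0298, 0.0384 /h
#>   elimination k5..k8 = 4.29e-05, 0.0706, 0.0715, 0.104 /h
#>   V_sweat in [0.05, 3.93] uL

round(sweatVolumes(fit), 2)    # recovered per-time-point sweat volumes (uL)
#>    t0 t0.25  t0.5 t0.75    t1  t1.5    t2    t3    t4    t6    t8   t24
#>  0.05  0.60  0.16  0.11  0.24  1.99  0.27  3.93  0.10  0.35  0.11  0.18
#>   t25   t26   t27
#>  1.99  0.11  0.57

# the phenotype readout: which products caffeine branches into
kf <- fittedRates(fit)
round(rbind(fitted = kf[2:4] / sum(kf[2:4]),
            truth = groundTruth(sm)$rates[2:4] / sum(k[2:4])), 3)
#>           k2    k3    k4
#> fitted 0.608 0.171 0.221
#> truth  0.593 0.185 0.222
```

The adjusted R² of 0.984 (120 non-censored observations against 26 fitted
parameters) is the per-profile fit quality a practitioner would report,
and the fitted volume series tracks the generating one (the generating
volume at t = 3 h was 3.54 µL; the low-signal time-points around it are
the "missing sweat" the model corrects for). The branching fractions
k₂:k₃:k₄ — the metabolic phenotype — are recovered to within a few
percent. The absolute uptake and elimination constants, by contrast, are
determined only up to an exponential-tilt family that the free volume
series absorbs (visible above: k₁ and k₅ drift while the fit quality
stays high); see the methods vignette
(`vignettes/sweat-pk-modelling.Rmd`) for the full identifiability
analysis and for the bound-pinned regime in which every parameter is
recoverable.

A thin command-line wrapper covers the same pipeline from a shell
(`simulate`, `fit`, `quantify`, `stats`, `cohort`):

```sh
Rscript inst/scripts/sweatpk simulate --out sim --design C2 --n 5 --seed 4
Rscript inst/scripts/sweatpk fit --input sim/profile_01.csv --out fit1
Rscript inst/scripts/sweatpk cohort --input sim --out cohort
```

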