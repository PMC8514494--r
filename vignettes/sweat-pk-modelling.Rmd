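---
title: "Kinetic modelling of caffeine catabolism in finger sweat"
author: "sweatPK"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling of caffeine catabolism in finger sweat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweatPK)
```

## The problem

Finger sweat can be sampled non-invasively every few minutes, and LC-MS
detects caffeine and its catabolites in single-fingertip samples. The
catch is that the volume of sweat collected at each sampling — on the
order of 0.2–2 µL — is unknown and fluctuates strongly from one
time-point to the next. A raw signal therefore confounds the body
concentration of a metabolite with the momentary sweat volume, and no
single-analyte normalization can separate the two.

The way out is joint kinetic modelling. Caffeine and its three primary
demethylation products (paraxanthine, theobromine, theophylline) are
enzymatically linked, so their body concentrations evolve on a shared,
low-dimensional trajectory, while the unknown sweat volume at a
time-point multiplies *all four* species equally:

$$\tilde M_i(t_j) = V_{\mathrm{sweat}}(t_j)\, C_i(t_j).$$

Fitting the four time-series simultaneously leaves the per-time-point
volumes estimable as nuisance parameters: each extra metabolite
multiplies the number of observations but not the number of volume
parameters.

## The kinetic model

A one-compartment body model with first-order mass-action kinetics: an
absorbed depot of `F * dose` drains into the body with uptake rate
$k_1$; body caffeine is converted to paraxanthine, theobromine and
theophylline with rates $k_2, k_3, k_4$ and cleared directly with
$k_5$; the products are eliminated with $k_6, k_7, k_8$. Uptake is
treated as instantaneous in onset (no lag), and each species has a
fixed, time-independent volume of distribution. Bookkeeping is in
moles — demethylation is 1:1 molar — and concentrations are reported in
µg/L via each species' molar mass and volume of distribution. The
caffeine channel is a Bateman function; the products add one more
convolution layer. All of this is linear, so the package evaluates the
exact closed form (`simulateConcentrations()`, with
`caffeineClosedForm()` for the caffeine channel alone), using divided
differences of decaying exponentials with analytic limits where
eigenvalues collide (the switch happens below a spacing of $10^{-9}$
h$^{-1}$, where cancellation would otherwise dominate). An independent
stiff-safe ODE integration (`odeOracle()`, via **deSolve**) exists
purely as a cross-check and agrees with the closed form to below
$10^{-8}$ relative error.

Default constants: dose 200 mg (one capsule), bioavailability 1, volume
of distribution 36 L for all four species — all configurable via
`pkParams()`. Fitted quantities and their bounds follow the model
definition: $k_1 \in [0, 10]$ h$^{-1}$, $k_2..k_8 \in [0, 0.2]$
h$^{-1}$, product baselines $C_0 \in [0, 1]$ µg/L (caffeine starts at 0
after fasting), and $V_{\mathrm{sweat}}(t_j) \in [0.05, 4]$ µL.

## Fitting

`fitProfile()` estimates, per volunteer profile, the 8 rate constants,
3 product baselines and one sweat volume per time-point — a packed
vector of length $11 + T$. Technical replicates enter the objective as
individual observations (a 15-time-point duplicate design gives
$n = 120$ observations), and below-LOD rows are excluded, not imputed.
Residuals $V(t_j) C_i(t_j) - \tilde M_{ijr}$ are accumulated through a
general robust loss $\rho(x, \alpha, c)$ that interpolates between
squared error ($\alpha = 2$), smooth L1 ($\alpha = 1$), Cauchy
($\alpha = 0$) and Welsch ($\alpha = -\infty$) behaviour. Rather than
learning $\alpha$ through the loss' partition function, the package
grid-searches $\alpha \in \{2, 1, 0.5, 0\}$ (the full multi-start fit
runs per $\alpha$) and keeps the fit with the highest adjusted $R^2$ —
loss values at different shapes are not comparable, adjusted $R^2$ is.
The scale $c$ is fixed at the median absolute non-censored signal.

The optimizer is bounded Levenberg–Marquardt (**minpack.lm**), with the
robust loss folded into transformed residuals
$\mathrm{sign}(r)\sqrt{2\rho(r)}$ whose sum of squares equals twice the
total loss, so both problems share their minimisers. The search is
multi-start: `nStarts` (default 100) initial vectors drawn uniformly
within the bounds from a seeded stream (drawn up-front, so a shorter run
is a prefix of a longer one), lowest final loss wins, and the winner
gets a final polish at tight tolerances. The fit is deterministic given
the seed.

### Variable projection

Random multi-start on the full $11 + T$ vector stalls: the landscape is
riddled with local minima. Two structural observations fix this. First,
for fixed kinetics the optimal volumes are closed-form — each
$V(t_j)$ is an independent clipped one-dimensional regression. Second,
the product baselines also enter linearly (each product's concentration
splits into a dose-driven part plus $C_0 e^{-k_{el} t}$). Each start
therefore searches only the 8 rate constants, with $(C_0, V)$ profiled
out by a few alternating clipped least-squares updates, before a joint
polish of the full vector. This reduces a $11 + T$-dimensional search to
an 8-dimensional one and makes the global basin reachable from a few
tens of starts.

### A structural unidentifiability, and what it means

The model has an exact invariance that deserves to be stated plainly:
shifting $k_1, k_5, k_6, k_7, k_8$ jointly by $\delta$ rescales every
concentration by $\frac{k_1+\delta}{k_1} e^{-\delta t}$, which the free
per-time-point volumes absorb exactly (via
$V'(t) = V(t)\frac{k_1}{k_1+\delta}e^{\delta t}$). Predictions — and
hence the loss, with or without noise — are identical along this
one-parameter family. It is bounded only where a volume or rate hits
its box constraint. Consequences:

* $k_2, k_3, k_4$ (and every conversion ratio at fixed $\delta$) are
  invariant under the family and always identified.
* $k_1$ and the four elimination constants are identified only up to
  the feasible $\delta$-interval; the same holds for the volumes up to
  the exponential tilt. Reported uncertainties for these parameters
  should be read with that in mind.
* When the true volumes touch both bounds at late time-points
  ($t > 1/k_1$), the feasible interval provably collapses to a point
  and every parameter is identified. The package's recovery tests use
  such a ground truth: that is the regime in which "recover the
  generating parameters" is a well-posed demand on the optimizer.
* $V(0)$ is determined only if some concentration at $t = 0$ is
  non-zero; after a long fast all concentrations start at (or near)
  zero, so recovery tests use a small non-zero product baseline.

The optimizer exploits the same structure: after each projected start
converges, a coarse line search along the $\delta$-direction (with
re-polish) escapes the local minima that line up along the tilt.

### Goodness of fit and confidence intervals

`adjustedR2()` implements
$1-(1-R^2)\frac{n-1}{n-p-1}$ over the non-censored observations with
$p = 11 + T$. Confidence intervals
(`confidenceIntervals()`) are t-intervals
$\hat\theta \pm t_{0.975,\,df}\, \mathrm{CV}\,\hat\theta$ built from
externally estimated per-parameter CVs (they come from a sensitivity
analysis of the whole fitting procedure, not from a single fit's
curvature — a single profile cannot see across the flat direction
described above). The default $df = n_{obs} - (11+T)$ and is
user-overridable.

## The synthetic-data generator

`generateProfile()` / `generateCohort()` produce volunteer profiles
with known ground truth under the capsule-study designs
(`studyDesign()`: grids A/B with 7 points over 2 h, C1 with 15 points
over 27 h, C2 with 20 points over 24 h; 200 mg dose; technical
duplicates). Sweat volumes are drawn independently per time-point,
log-uniform on [0.05, 4] µL — the model treats each volume as a free
parameter, so no temporal smoothness is assumed; an AR(1) option exists
for realism studies. Measurement noise is multiplicative log-normal at
a configurable CV (default 10%, matching the observed internal-standard
AUC variability), with an optional additive floor for LOD studies;
entries below a configurable LOD are flagged censored. Baselines follow
the fasting rule: designs with ≥ 24 h caffeine fasting start the
products at zero, shorter fasting draws residual baselines in
(0.1, 1] µg/L. Per-volunteer rate constants come from
`sampleRateConstants()`, truncated normals centred on a
paraxanthine-dominant phenotype (k1 = 3 h⁻¹; k2 = 0.08, k3 = 0.03,
k4 = 0.02, k5 = 0.02; eliminations 0.04–0.06 h⁻¹) — the centres sit
well inside the model bounds and the inter-individual spread is an
arbitrary but documented choice, since no population distribution is
given for them.

What the generator does *not* emulate: chromatographic drift, carryover,
matrix effects, inter-day batch structure, or model misspecification
(the generator and the fitted model share the same kinetics). Passing
recovery tests therefore demonstrate the estimation machinery, not the
adequacy of first-order kinetics for real sweat data.

## Quantification QC

The assay-side helpers mirror standard practice: internal-standard
normalization (`normalizeToStandard()`), unweighted OLS calibration
lines with an optional 1/x² weighting (`fitCalibration()`), detection
and quantification thresholds from blanks as mean + 3 sd and mean + 10
sd (`lod()`, `lloq()`; sample sd throughout — the convention is not
fixed by the rules themselves), percent CVs, extraction efficiency, and
the physiological sweat-volume bracket
(`sweatVolumeRange(2, 2, 50, 500)` = 200–2000 nL per sample).

## Cohort statistics

* `wilcoxonSignedRank()` — exact two-tailed signed-rank test by dynamic
  programming over (mid)ranks up to n = 25, normal approximation with
  continuity and tie corrections above. Zero differences are discarded
  by default (Pratt handling available); the two-tailed p doubles the
  smaller tail. Thirteen concordant pairs give p = 2/2¹³ ≈ 0.000244.
* `pairedT()`, `dagostinoPearson()` (K² omnibus test, own
  implementation of the standard skewness/kurtosis transforms),
  `lillieforsKS()` (Dallal–Wilkinson p, via **nortest**).
* `s0Volcano()` — the Perseus-style paired volcano:
  $t_{s0} = \bar d / (s_{\bar d} + s_0)$ with default $s_0 = 0.1$,
  significance by subject sign-flip permutation FDR at target 0.05
  (10,000 flips or full enumeration when $2^n$ is smaller; flips are
  applied jointly across metabolites, preserving their correlation).
  The reported −log₁₀ p is from the ordinary paired t.
* `sharedControlBootstrap()` — estimation-statistics effect sizes
  against a common pre-dose control, percentile bootstrap (default
  5000 replicates; BCa was not claimed and is not implemented).
* `pcaAnalysis()` — standard-scaled PCA (SVD); rows with missing values
  are dropped rather than imputed. `kCorrelationSummary()` gives the
  Pearson structure of the fitted conversion constants k2–k5, where
  metabolic phenotypes show up (e.g. a paraxanthine-conversion vs
  direct-elimination trade-off).

## Numerical choices and problem sizes

Tolerances: optimizer ftol/ptol 10⁻⁸ (10⁻¹⁵ for the winner's final
polish); divided-difference degeneracy switch at 10⁻⁹ h⁻¹; ODE oracle
at rtol = atol = 10⁻¹². Ties in the signed-rank test get midranks; the
exact null is enumerated by convolution with ranks doubled to integers.
The test-suite and acceptance problem sizes are chosen to keep a full
run on one CPU in minutes: 20-start fits on the 20-point capsule grid,
20 noise seeds for the recovery study, 50 null cohorts of 100
metabolites for FDR calibration, 1000 simulated calibration curves.

## Known limitations

Single-compartment, first-order kinetics only; no enterohepatic
recirculation, no downstream metabolites of the dimethylxanthines, no
saturable enzymes. The adaptive-loss shape is selected by grid rather
than learned. Population-level (mixed-effects) fitting is out of scope:
profiles are fitted independently. And the tilt invariance above is a
property of the model class itself — more confident elimination
estimates require either external volume information or informative
bounds.
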