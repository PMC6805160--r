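---
title: "Methods: models, generator design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, generator design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anttraffic)
```

This vignette is the package's account of its science: the traffic models it
fits, the assumptions behind them, how the synthetic-data generator was
designed, and the numerical decisions inside the fitting routines.

## The macroscopic picture

Trail traffic is summarised per second by a density $k$ (ants cm$^{-2}$,
measured on a fixed section at the trail midpoint) and a per-width flow
$q$ (ants cm$^{-1}$ s$^{-1}$, both directions pooled, counts divided by the
trail width).  The classical speed–density relations — Greenshields
(linear), Pipes–Munjal (power law with exponent $p$), Underwood
(exponential) — all force the flow $q = k\,v(k)$ back to zero at high
density: they encode congestion.  Ant trails empirically do not congest, so
the package adds a two-phase flow function,
$$q(k) = v\,\min(k, k_j),$$
linear up to a breakpoint density $k_j$ and constant beyond it.  The model
set is compared with Akaike weights; with per-second data the sample sizes
are large and the selection is usually decisive.

Assumptions worth keeping in mind: the observations are treated as
independent in the least-squares sense, although consecutive seconds of one
experiment are strongly autocorrelated; and the fit is unweighted, although
counting noise grows with the mean flow.  Neither affects the point
estimates' consistency, but standard errors on real data should be read as
optimistic.

## The microscopic chain

Three elementary relations connect individual behaviour to the macroscopic
curve, over a monitored section of length $L$ (default 2 cm):

1. **Contacts accrue linearly with density**: $C = c\,k$, fitted through
   the origin (zero density can produce no contacts).  Default
   $c = 0.61$ contacts per (ant cm$^{-2}$).
2. **Each contact costs a fixed delay**: $T = T_0 + C\,\Delta T$ by
   ordinary least squares.  Defaults $T_0 = 0.95$ s, $\Delta T = 0.24$ s.
3. **Pheromone speeds ants up at intermediate density**: the multiplier
   $\phi(k) = \alpha + \beta k e^{-\gamma k}$ (defaults $0.812, 0.160,
   0.156$) rises from the unmarked-trail baseline $\alpha$, peaks at
   exactly $k = 1/\gamma \approx 6.4$ ants cm$^{-2}$, and relaxes back.

Combined:
$$v(k) = \frac{L}{T_0 + \Delta T\, c\, k}\,\bigl(\alpha + \beta k
e^{-\gamma k}\bigr), \qquad q(k) = k\,v(k),$$
with the closed-form limit $q_\infty = L\alpha/(\Delta T\, c)$, which is
11.09 ants cm$^{-1}$ s$^{-1}$ at the defaults.  The pheromone factor is
placed as a multiplier on the whole speed (rather than inside the
denominator): this is the only reading under which the analytic limit
$L\alpha/(\Delta T\,c)$ holds, since the bump term dies off exponentially
and the denominator's $1/k$ decay cancels against the density factor.

`free_flow_speed()` inverts relation 2 record-wise,
$v_f = L/(T - C\,\Delta T)$; records whose contact-corrected time is not
positive (possible with measurement noise) are returned as `NA` and
counted rather than silently dropped.  `travel_time_curves()` reproduces
the stratified view — travel time against density at fixed contact count —
with `stats::loess` (degree 2, tricube weights, span 0.75; the span is an
argument because the visual smoothness of these curves is the only thing
it affects).

### Fitting the speed model on the time scale

`fit_speed_model()` estimates $(\alpha, \beta, \gamma)$ with $L, T_0,
\Delta T, c$ held fixed, by Levenberg–Marquardt least squares of the
*observed travel times* against $(T_0 + \Delta T c k)/\phi(k)$, starting
from $(1, 0.1, 0.1)$.  The choice of scale is deliberate.  Measured
crossing times carry additive noise, and the contact count of an
individual crossing scatters around its mean $c\,k$; on the time scale
both effects are mean-zero given $k$, so least squares is unbiased.  Had
the regression been run on reciprocal speeds $L/T$, Jensen's inequality
would inflate every fitted speed (the inflation is largest where crossings
are fastest, i.e. at low $k$, and the contact-count scatter peaks near the
pheromone optimum), biasing $\alpha$ and $\beta$ upward by many standard
errors at realistic noise levels.  At the optimum of the noiseless problem
the two scales give identical parameters, which the test suite checks to
$10^{-6}$.

## The synthetic-data generator

The generator produces data *with the statistical structure the analysis
assumes*, at the study's calibration; it is the package's test bed, not an
agent-based simulation.

**Macroscopic records** (`generate_macroscopic`): density follows a
logistic recruitment ramp
$k(t) = k_{\max}/(1 + e^{-(t - t_{1/2})/\tau})$ with $t_{1/2}$ = half the
ramp time and $\tau$ = ramp time / 8, reaching its ceiling within the ramp
— emulating the build-up to the equilibrium reached about ten minutes into
a recording, without modelling recruitment itself.  The default ceiling is
18 ants cm$^{-2}$, the highest density ever observed (at the measured
4.4 mm$^2$ per Argentine ant this is an occupancy of 0.79, and the
generator's trajectories are clamped so occupancy never exceeds 0.8).
Multiplicative Gaussian jitter (default sd 5% of the current level,
truncated into $[0, k_{\max}]$) stands in for the within-experiment
fluctuation, whose true magnitude is not documented; it is a configurable
guess.  Per-second directional counts are independent Poisson draws around
$q(k) \times \text{width}$ split by the outbound fraction — counts of
discrete crossing events are the one noise form that needs no tuning.  The
outbound fraction drifts from 1 to 0.5 on the same logistic clock
(outbound foragers dominate before the first returns).  With noise off,
counts are rounded means, and the recorded flow always satisfies
$q = (n_{out} + n_{in})/\text{width}$ exactly.

**Tracked records** (`generate_tracked`): local density from a sampler
(default uniform on [0, 16]); contacts $C \mid k \sim
\text{Poisson}(c\,k)$; crossing time $(T_0 + \Delta T\,C)/\phi(k)$ plus
additive truncated-normal noise (default sd 0.3 s, truncated below at
$0.1\,T_0$ so times stay positive); U-turn flag Bernoulli with default
probability 0.01.  U-turners stay in the table — they occupy the trail —
but every fitting function excludes them, mirroring the analysis of
completed crossings only.

What the generator does **not** emulate: temporal autocorrelation within
an experiment, heteroscedastic density measurement error, lane structure
or any spatial organisation, density-dependent U-turns, and the
between-experiment variation of a multi-colony dataset.  Passing recovery
tests therefore shows that the estimators are correct for the assumed
error structure — not that real recordings satisfy that structure.  One
visible consequence: with the default noise the generator's travel-time
regression is much cleaner ($R^2 \approx 0.9$) than field data
($R^2 \approx 0.55$), where unmodelled behavioural variation dominates.
The travel-noise sd is a knob if a messier calibration is wanted.

## Numerical choices

* **Two-phase fitting.**  The breakpoint makes the model non-smooth, which
  defeats plain Gauss–Newton.  The fitter profiles the SSE over a $k_j$
  grid (step 0.1 ants cm$^{-2}$) — at fixed $k_j$ the slope is linear
  least squares in closed form, $\hat v = \sum q\,m / \sum m^2$ with
  $m = \min(k, k_j)$ — then refines the breakpoint by golden-section
  search (tolerance $10^{-9}$) in the bracketing grid cell.  This is
  globally robust and recovers noiseless parameters to $10^{-6}$.
* **Smooth-model fitting.**  Levenberg–Marquardt (`minpack.lm`) with
  positivity bounds, restarting from halved/doubled starting values before
  declaring failure; non-convergence raises a classed error
  (`ant_fit_error`), never a silent bad fit.  Auto-initialisation is
  scale-free: the free slope from the lowest-density decile of $q/k$, jam
  density at 1.2× the observed maximum, Underwood scale at the median
  density, $p = 2$.
* **AIC convention.**  $n\ln(\mathrm{SSE}/n) + 2(p+1)$, the Gaussian
  least-squares correspondence with unknown error variance.  Only AIC
  differences matter for the weights, but the convention is fixed so
  reported AICs are reproducible.
* **Degenerate inputs.**  Fits require at least 10 observations, spread in
  $k$, and not-all-zero flow; the travel-time regression refuses constant
  $C$; the speed-model fit refuses data that do not span $k \ge 10$
  (below that, $\beta$ and $\gamma$ trade off freely).  Single-observation
  bins report an `NA` standard deviation rather than 0.
* **Occupancy rounding.**  Dimension ranges collapse to midpoints (for
  fire ants, the published mean body length with the head-width range
  midpoint).  The species table reports areas at two decimals and computes
  occupancy from the area rounded to one decimal — the precision at which
  per-ant areas are conventionally quoted — which reproduces all four
  published occupancies (0.20, 0.48, 0.13, 0.10).  The wood-ant area is a
  known discrepancy: the published comparison quotes 22.25 mm$^2$, but the
  printed dimensions give $7.7 \times 2.3 \times 1.25 = 22.14$; the
  package reports the reproducible 22.14 and does not force agreement.
* **Standardized response surface.**  Flow is regressed on density and
  asymmetry after z-scoring $k$, $a$ and $q$, with squares and the
  interaction formed *from the z-scores* (so the quoted betas are the
  familiar standardized coefficients and are invariant to rescaling the
  flow).  A thin-plate-spline surface would visualise the same structure
  but carries no coefficients; the quadratic surface is what supports the
  quantitative claim that the isoclines run parallel to the asymmetry
  axis.  Note that with few crossings per second the realised outbound
  fraction is mechanically noisy — extreme values co-occur with small
  counts — so on raw low-flow seconds the quadratic asymmetry term absorbs
  some of that binomial artefact; the independence tests in the suite use
  a construction where the asymmetry is drawn independently of the flow.

## Problem sizes

The test suite and the acceptance script work at desk scale, chosen to
keep every stochastic check comfortably powered: 8,000 tracked records for
the microscopic recoveries (the scale of a real tracked sample), 20,000
per-second records for breakpoint recovery and model selection, and a few
hundred to a few thousand records in the unit tests.  All recovery checks
assert agreement within three standard errors of the planted values, and
all noiseless oracles assert recovery to $10^{-6}$.

## Known limitations

* No heteroscedastic or autocorrelation-aware fitting; standard errors on
  real per-second data will be too small.
* Head-on and rear-end contacts are pooled, as in the underlying
  measurements.
* The generator is statistical: questions about lane formation, spatial
  clustering or explicit collision geometry are outside its scope.
* The exact parameterisations under which the classical diagrams were
  originally fitted to the field data are not fully documented; the
  canonical textbook forms used here match the verbal descriptions but
  fitted values for those three models are not expected to be
  numerically identical to any previously published table.
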