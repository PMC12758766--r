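---
title: "Models and methods: encounters, feeding and electivity of a planktonic ambush predator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaetofeed)
```

`chaetofeed` quantifies the trophic interaction between an ambush-feeding
chaetognath (arrow worm) and its copepod prey: how often predator and prey
meet, how much the predator actually eats, whether it prefers particular
prey taxa, and which environmental variables structure its feeding rates.
This vignette explains each model, its assumptions, the tunable parameters,
and the design choices made where the methods literature leaves the design
open.

## Encounter kernels

In still water, the expected number of prey entering a predator's
perception sphere per unit time, for two populations moving at constant
speeds, is

$$C_{GS} = \frac{\pi R^2 N}{6}\,\frac{(x+y)^3 - |x-y|^3}{x\,y},$$

with $R$ the predator's perception radius (m), $N$ the prey density
(ind/m^3), and $x$, $y$ the prey and predator speeds (m/s). All inputs are
SI; a single factor of 86 400 converts the per-second rate to the
per-day rates used throughout (`gs_rate()`).

The printed form of the kernel divides by $x\,y$, yet the central use
case here is an ambush predator with $y = 0$. The bracketed expression is
continuous there, and `gs_rate()` evaluates its algebraic limit

$$C_{GS}\,\big|_{y=0} = 86\,400\,\pi R^2 N x,$$

the kinetic-theory flux of ballistic particles through a sphere's
cross-section, rather than raising an error. The same limit handles
$x = 0$ by symmetry; only $x = y = 0$ (no relative motion) is a domain
error. An individual-based simulation (`simulate_ambush_encounters()`) —
ballistic prey with isotropic headings in a periodic box around a
stationary perception sphere, with exact segment–sphere crossing
detection — provides a mechanistic check of this flux law and converges to
it within Monte-Carlo error in the test suite.

Wind-driven small-scale turbulence adds a root-mean-square velocity $w$ to
every organism's motion. The turbulent kernel (`ro_rate()`) substitutes
$\sqrt{x^2 + w^2}$ for $x$ and $\sqrt{y^2 + w^2}$ for $y$; for an ambush
predator it reduces to the closed form

$$C_{RO}\,\big|_{y=0} = 86\,400\,\pi R^2 N\,
  \frac{3x^2 + 4w^2}{3\sqrt{x^2 + w^2}},$$

so the enhancement over calm water is the density-free ratio
$f(w) = (3x^2 + 4w^2) / (3x\sqrt{x^2 + w^2})$ (`enhancement_factor()`),
equal to 1 at $w = 0$ and strictly increasing.

**Default parameters.** `encounter_params()` defaults to $R = 3$ mm (the
attack distance measured for a closely related chaetognath by vibrating
probes), $x = 150$ mm/s (the upper range of copepod escape-jump speeds
from high-speed videography), and $y = 0$ (chaetognaths wait motionless
for prey). These defaults reproduce the reference field study's published
calm-water surface rates from its published copepod densities to within
the 1-decimal rounding of its tables.

**Turbulent velocity is calibrated, not predicted.** The transfer function
from wind speed to near-surface $w$ depends on reference depth, sea state
and the chosen turbulence closure, and standard scalings give values far
too small to explain the 1.5–1.8× surface enhancements the reference
study reports for 2.6–3.9 m/s winds. We therefore treat $w_0$ (the
surface value) as a first-class parameter and provide the closed-form
inverse of the enhancement ratio, `calibrate_surface_w()`: writing
$q = \sqrt{1 + (w/x)^2}$, the enhancement is $f = (4q^2-1)/(3q)$, whose
admissible root is $q = (3f + \sqrt{9f^2 + 16})/8$. Calibrated against
the published seasonal rate pairs this gives $w_0 \approx$ 0.13 (summer),
0.14 (fall) and 0.17 m/s (winter), carried with the wind speed as
metadata. This is a deliberate honesty choice: the package reproduces the
published turbulent rates as a *consistency* check of the kernel algebra,
not as an independent prediction of turbulence from wind.

**Depth decay.** Observations show calm and turbulent encounter profiles
converging by roughly 28 m (summer/fall winds) to 40 m (winter winds),
but no functional form for $w(z)$ accompanies them. `turbulence_spec()`
therefore offers exponential decay (default), a linear cutoff, and a
depth-constant mode. The analysis scripts pick the e-folding depth so
that $w$ falls to 10% of its surface value at the observed convergence
horizon ($z_{10\%} = \mathrm{decay\_depth} \times \ln 10$, i.e.
decay depths of ~12 m and ~17 m). This is our design choice, documented
as such, not an assertion about how the original profiles were built.

## Feeding rates from gut contents

The gut-content estimator assumes steady state: a predator holding on
average `NPC` prey in its gut, digesting one prey in `DT` hours, ingests

$$FR = \frac{NPC}{DT} \times 24 \quad \text{prey/day}.$$

Digestion time decreases exponentially with temperature,
$DT(T) = a\,e^{-bT}$, with defaults $a = 10.48$ h and $b = 0.086$ per
degC (`digestion_model()`). Note the coefficient's scale: $b$ on the
order of 0.1 per degC is what produces the observed 0.9–2.1 h digestion
times at 19–29 degC; a coefficient ten times larger would predict
digestion in microseconds, which no field observation supports. The test
suite pins all six published seasonal extremes of $DT$ (to 2 decimals) at
their paired temperature extremes.

Station-level temperature is the trapezoidal mean of the CTD cast over
the upper 50 m (`integrate_upper_layer()`), the standard reduction for
epipelagic covariates; trapezoidal quadrature is exact for the linear
profiles the generator produces and second-order accurate otherwise. A
cast shallower than the integration depth is averaged over its available
span with a warning.

Aggregation is mean-of-ratios: `FR` is computed per station from that
station's `NPC` and `DT`, then averaged across stations. The alternative
— a ratio of stratum-mean `NPC` to stratum-mean `DT` — is *not*
equivalent (extremes rarely co-occur at one station), and the
mean-of-ratios convention is what matches published per-station
summaries. `gut_survey()` stores per-individual counts rather than the
mean alone, so standard errors are available; prey found near the mouth
(possible net-feeding artefacts) are treated as an upstream cleaning
flag, not re-adjudicated here.

## Prey electivity

The Kimmerer–Slaughter index compares a taxon's share of identified gut
contents ($g_i = G_i/N_G$) with its share of the habitat sample
($a_i = A_i/N_A$) on the odds scale:

$$X_i = \frac{O_i}{1 + O_i}, \qquad
  O_i = \frac{g_i/(1-g_i)}{a_i/(1-a_i)}.$$

$X_i \in [0,1]$; 0.5 means no selection, and the index is antisymmetric
under swapping the two roles ($X(g,a) + X(a,g) = 1$). A taxon eaten but
absent from the habitat aliquot has undefined odds and is reported as
`undefined` rather than patched with a continuity correction — matching
the blank cells of published tables.

Uncertainty is propagated by a Beta Monte-Carlo scheme (`beta_mc_ci()`):
10 000 draws of $g^* \sim \mathrm{Beta}(G_i+1,\,N_G-G_i+1)$ and
$a^* \sim \mathrm{Beta}(A_i+1,\,N_A-A_i+1)$, recomputing $X^*$ per draw
and taking the 2.5/97.5 percentile interval. The Beta(count+1,
total−count+1) form is the posterior under a uniform prior; it is
well-defined at zero counts, which Jeffreys-type priors handle less
gracefully, and published intervals computed with unstated Beta
parameterizations are treated as approximate cross-checks, never exact
targets. Percentile intervals (not highest-density) are used as the
plainest reading of a "95% confidence interval". Classification follows
the 0.5-overlap rule (`classify_selection()`): `none` if the interval
contains 0.5, `positive`/`negative` if it lies entirely above/below.

Published composition tables print percentages of known totals;
`counts_from_percent()` reconstructs the integer counts and errors if a
percentage is not consistent with any integer count to within 0.05
percentage points. Working in counts matters: an index computed from the
rounded percentage 11.1% differs in the third decimal from the one
computed from the exact count 1/9.

At the scale of real gut surveys (tens of identified items), these
intervals are wide: the analysis script shows a built-in 4.5-fold
preference going undetected at $N_G = 20$ and flagged positive at
$N_G = 400$. Low power at survey scale is a property of the data, not a
defect of the index.

## Community statistics

**PERMANOVA.** `permanova_two_way()` implements the two-factor crossed
permutational ANOVA on a distance matrix: Gower-centered inner-product
matrix $G = -\tfrac12 C D^{(2)} C$, sequential (Type I) sums of squares
via hat-matrix differences, pseudo-$F$ = term MS over residual MS, and
unrestricted permutation of observations with the add-one convention
$p = (1 + \#\{F^* \ge F\})/(B+1)$. With Euclidean distances on a
univariate response and a balanced design the pseudo-$F$ equals the
classical ANOVA $F$ exactly (to 1e-10 in the tests, which also
cross-check an independent implementation). Sequential SS is the
simplest defensible choice for the mildly unbalanced designs the
generator produces; commercial packages default to Type III, so exact
SS values from unbalanced field analyses are a qualitative, not numeric,
reference. Permutation of residuals under a reduced model is a
recognised alternative scheme, deliberately left out of scope. The
default $B = 9999$ with a seed reports the count of distinct
permutations actually sampled.

**BIOENV.** `bioenv_best()` z-scores each environmental variable, builds
Euclidean distances for every non-empty subset (exhaustive: $\le 6$
variables means $\le 63$ subsets), and ranks subsets by the Spearman
correlation between the unrolled lower triangles of the subset and
response distance matrices. Being rank-based, the criterion is invariant
to monotone transforms of the response distances. Prey density is
excluded from the search wherever an encounter rate is among the
candidates, because the calm-water kernel makes the two proportional
($R^2 = 1$); the exclusion is an explicit argument, honored in the
searched subsets. The optional permutation p-value re-runs the *whole*
search on each shuffle, so it accounts for selection over subsets.

**Size regression.** Ordinary least squares of prey length on predator
length with a two-sided $t$-test on the slope, via `stats::lm`.

## The synthetic study

`generate_station_grid()` and its companions exist so the full pipeline
runs, and is testable, with no field data. The generator's defaults
(`stratum_defaults()`) encode the study conditions of the reference
survey: six season × zone strata with upper-50-m temperatures of
24.4–29.1 degC (summer), 26.3–28.2 (fall) and 18.7–23.1 (winter, cooler
on the shelf); salinity lowest on the winter shelf (river influence) with
chlorophyll peaking there; copepod densities log-normal around stratum
means of 205.2/45.3 (summer neritic/oceanic), 68.6/30.6 (fall) and
151.6/51.6 (winter) ind/m^3 — strictly positive and right-skewed, as
plankton counts are, with a CV of 0.6 preserving the seasonal ordering
summer > winter > fall; mean gut fullness 0.04 (summer/fall) and 0.03
(winter) prey per predator; seasonal winds 2.64, 2.81 and 3.87 m/s.
Gut counts are Bernoulli by default (chaetognath guts typically hold at
most one prey), with a Poisson mode for predators that stack prey. CTD
casts are linear gradients plus noise, shifted so the upper-50-m
trapezoidal mean equals the station's drawn value *exactly*, making the
integration step testable bit-wise. `generate_diet_pair()` tilts gut
multinomial probabilities by per-taxon selection odds
($g_i \propto a_i o_i$), so odds of 1 give an expected index of exactly
0.5 and a single tilted taxon at a 10% habitat baseline lands at the
analytically known $X = 0.818$.

What the generator does **not** emulate: spatial autocorrelation and
fronts, net avoidance and extrusion biases, tow-depth variability,
differential digestion visibility among prey taxa, and any coupling
between turbulence and gut fullness. Tests passing on synthetic data
therefore validate the *computational* pipeline and its statistical
calibration (type-I error, bias, power ordering), not the field
conclusions themselves.

## Numerical choices and problem sizes

All randomized routines take explicit seeds and are bit-reproducible.
Percentile quantiles use R's default type-7 interpolation. The kernel's
removable singularities are evaluated by algebraic limits, never by
epsilon-nudging inputs. The test suite runs the individual-based
encounter check at 1 250 particles for 3 000 steps (~12 000 crossings,
Monte-Carlo error well under the 5% assertion), the PERMANOVA size check
at 500 null datasets of 24 stations with 199 permutations each, the
BIOENV recovery at 100 replicates of 30 stations with 5 decoy variables,
and the feeding-rate bias check at 500 replicates of 200 predators —
sizes at which each statistical assertion has comfortable margin while
the whole suite stays quick on a single CPU.

## Known limitations

- The wind-to-$w_0$ link is calibration, not physics; comparisons across
  sites with different sea states need their own calibration pairs.
- The feeding-rate estimator assumes steady-state feeding and a single
  shared digestion time; satiation cycles and taxon-specific digestion
  are not modelled.
- Electivity intervals depend (weakly) on the Beta prior at zero counts;
  with gut samples of ten items no realistic prior yields narrow
  intervals.
- PERMANOVA uses one permutation scheme and Type I SS; strongly
  unbalanced designs deserve a sensitivity check against Type III.
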