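# chaetofeed

Quantitative tools for the predator–prey interaction between
ambush-feeding chaetognaths (arrow worms) and their copepod prey —
the two most abundant groups of the mesozooplankton. The package is
aimed at plankton ecologists who want to go from station tables, CTD
casts and gut-content counts to encounter rates, feeding rates, prey
electivity and the statistics that compare them across seasons and
zones, with every step reproducible from a seed.

## What it computes

**Encounter rates.** The calm-water kernel for two populations moving at
constant speeds,

    C_GS = (pi R^2 N / 6) * [(x+y)^3 - |x-y|^3] / (x y)   (per second),

converted to encounters per day, with the algebraic limit
`C = 86400 pi R^2 N max(x, y)` when one speed is zero — the relevant
case for an ambush predator that waits motionless (`y = 0`). Defaults:
perception radius `R = 3 mm`, copepod escape speed `x = 150 mm/s`. The
turbulence-augmented kernel substitutes `sqrt(v^2 + w^2)` for each speed,
where `w` is the wind-induced root-mean-square turbulent velocity; the
surface `w0` is calibrated from observed turbulent/calm rate ratios by a
closed-form inverse (`calibrate_surface_w()`), and pluggable vertical
profiles `w(z)` propagate the enhancement down the water column. An
individual-based simulation of ballistic prey around a perception sphere
(`simulate_ambush_encounters()`) independently verifies the kernel's
flux law.

**Feeding rates.** The gut-content estimator `FR = (NPC / DT) * 24`
(prey per predator per day), where `NPC` is mean gut fullness and
`DT(T) = 10.48 exp(-0.086 T)` hours is the temperature-dependent
digestion time, evaluated at the upper-50-m trapezoidal mean temperature
of the station's CTD cast.

**Prey electivity.** The Kimmerer–Slaughter odds-ratio index
`X = O / (1 + O)` with `O = odds(gut share) / odds(habitat share)`,
Beta Monte-Carlo 95% intervals (10 000 draws, uniform prior), and the
0.5-overlap classification into positive / negative / no selection.

**Community statistics.** Two-factor crossed PERMANOVA on Euclidean
distances (sequential SS, unrestricted permutations, seed-deterministic)
with an exact balanced-design equivalence to classical ANOVA; BIOENV
exhaustive best-subset selection by Spearman rank correlation; OLS
predator–prey size regression.

**Synthetic study.** Seed-deterministic generators for station grids
with CTD casts, gut surveys and diet/habitat composition pairs, encoding
realistic seasonal stratum conditions so the full pipeline runs without
any field data.

## Worked example

```r
library(chaetofeed)

p <- encounter_params()        # R = 3 mm, x = 150 mm/s, ambush (y = 0)
gs_rate(p, N = 205.2)          # summer shelf copepod density
#> [1] 75.19254

w0 <- calibrate_surface_w(115.1 / 75.4, x = 0.150)
w0                             # surface turbulent velocity implied by a
#> [1] 0.1321007               # 1.53x observed surface enhancement
ro_rate(p, N = 205.2, w = w0)
#> [1] 114.7833

m <- digestion_model()         # DT = 10.48 exp(-0.086 T) hours
digestion_time(m, c(29.12, 18.72))
#> [1] 0.8565425 2.0949898     # warm summer vs cold winter water
feeding_rate(NPC = 0.04, DT = 1.09)
#> [1] 0.8807339               # copepods per chaetognath per day

electivity_index(g = 1/9, a = 2/40)   # taxon: 1 of 9 gut items,
#> [1] 0.7037037                       # 2 of 40 in the habitat
beta_mc_ci(1, 9, 2, 40, seed = 1)
#>    ci_low   ci_high
#> 0.2266024 0.9551896            # interval spans 0.5: no selection
```

A chaetognath sitting in 205 copepods/m^3 meets about 75 of them per
day in calm water and ~115 when wind-driven turbulence at the calibrated
intensity stirs the surface layer; warm water digests a copepod in under
an hour versus two in winter, which is what drives the seasonal feeding
pattern; and a taxon over-represented in guts (11% vs 5%) still cannot
be called "selected" from nine identified gut items — the interval is
far too wide.

The same workflow at survey scale lives in `analysis/01_simulate.R`
through `analysis/05_community_stats.R`: generate a 64-station synthetic
survey, compute per-station encounter and feeding rates, run the
electivity and PERMANOVA/BIOENV analyses, and write all tables plus a
summary report under `results/`. The methods vignette
(`vignettes/methods.Rmd`) documents the models, parameter choices and
limitations.

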