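# leafcarbon

Whole-plant carbon-balance simulation of *Arabidopsis thaliana* leaf area
growth, with multi-objective calibration of the carbon partition
coefficients and a one-at-a-time sensitivity protocol.

## The problem

Leaf area is the standard optical surrogate for plant growth in
high-throughput phenotyping, but how well it predicts biomass depends on
where the plant sends its carbon.  `leafcarbon` implements an hourly
carbon-balance model that follows fixed and stored carbon from seed
germination through 90 days of growth, partitioning the net assimilation
rate (NAR) among four sinks per developmental phase:

- leaf area growth (coefficient λs),
- leaf thickening (λt),
- root growth (ρ),
- inflorescence/stem growth (ι),

with ι + ρ + λs + λt = 1 in each of four phases (germination, early
vegetative, late vegetative, reproductive) — 16 coefficients in all.

During the photoperiod *P* the plant fixes `A · s_eff` carbon per hour over
its effective (overlap-corrected) leaf area, diverts a fraction σ to a
transient starch pool and spends the rest, net of maintenance respiration
and exudation:

    NAR_day   = A · s_eff · (1 − σ) · 3600 − ŕm_i · M_i · 3600 − ŕm_r · M_r · 3600 − E
    Σ         = Σ_daylight A · s_eff · σ · 3600
    NAR_night = Σ / (24 − P) − Rm_L · s · 3600 − ŕm_i · M_i · 3600 − ŕm_r · M_r · 3600 − E

Growth carbon `G = max(NAR, 0) / C` (C = 37,500 µmol C g⁻¹ dry mass) is
split by the phase coefficients, each organ's share discounted by its
growth respiration coefficient, and new leaf area is linear in the
area-directed leaf mass increment with slope SLA = s / M_L:

    Δs = SLA · (1 − ŕg_L) · G · λs

Calibration fits all 16 coefficients to sparse harvest measurements
(leaf area, leaf, root and stem mass; mean ± SD) by minimizing four
sigmoid weighted-difference objectives `Σ 1/(1 + exp(−10·|dif|/SD + 5))`
simultaneously with a built-in NSGA-II, then clusters and ranks the
qualified settings (all four objectives ≤ 1).

## Worked example

```r
library(leafcarbon)

cfg  <- col0_config()        # published constants + calibrated coefficients,
                             # synthetic fixture drivers (see vignette)
traj <- simulate_plant(cfg)
traj
#> Growth trajectory: 90 days
#>   final leaf area 0.01905 m2 (190.5 cm2), leaf 0.5328 g, plant 0.7393 g
#>   carbon closure residual: 0 (relative)

subset(traj$daily, das %in% c(26, 44, 66, 86),
       select = c(das, s, M_L, M_i, M_r, M_P, sla))
#>    das      s    M_L    M_i    M_r    M_P    sla
#> 26  26 0.0009 0.0119 0.0001 0.0007 0.0127 0.0797
#> 44  44 0.0049 0.0921 0.0009 0.0058 0.0988 0.0537
#> 66  66 0.0143 0.3260 0.0161 0.0354 0.3775 0.0439
#> 86  86 0.0184 0.5034 0.1177 0.0667 0.6878 0.0366
```

The wild-type fixture plant ends near 190 cm² of leaf area and 0.74 g dry
mass; SLA falls with age (leaves thicken) and the carbon ledger closes to
machine precision.  The daily partition summary shows maintenance
respiration claiming an increasing share of the available carbon — about
20% at 26 DAS and nearly half at 86 DAS:

```r
subset(partition_summary(traj), das %in% c(26, 86),
       select = c(das, maintenance, leaf_area_growth, leaf_thickening))
#>    das maintenance leaf_area_growth leaf_thickening
#> 26  26       0.195            0.541           0.130
#> 86  86       0.477            0.152           0.109
```

A full calibration round trip on synthetic harvests:

```r
meas <- generate_measurements(
  synthetic_study(truth = partition_table2("gi2", 1), cv = 0.1),
  gi2_config(), seed = 7)
fit <- fit_nsga2(gi2_config(), meas, pop_size = 64, generations = 80, seed = 42)
fit
#> NSGA-II calibration: 5184 evaluations (pop 64 x 80 generations, seed 42)
#>   Pareto front size: 64
#>   qualified settings: 440
ranked <- cluster_and_rank(fit$qualified)
```

The sensitivity protocol (`sensitivity_table(col0_config())`) reproduces
the model's headline behaviour: shifting one percentage point of early
vegetative NAR from leaf thickening to leaf area growth raises final leaf
area by tens of percent, an order of magnitude more than a 1% change in
photosynthesis, while the starch split σ barely matters.

A thin command line sits over the same functions:

```sh
inst/cli/leafcarbon simulate --out runs/col0 --profile col0
inst/cli/leafcarbon calibrate --measurements meas.csv --seed 1 --out runs/cal
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch
— both packaged genotype simulations with ledger verification, the
standard sensitivity battery, and a synthetic-measurement calibration
round trip — and writes its JSON summary to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

- `R/` — simulator (`simulate_plant`), drivers, metrics, calibration
  (`fit_nsga2`, `cluster_and_rank`), sensitivity, synthetic data, CLI
  wrappers; `src/` holds the compiled fast path used during calibration.
- `vignettes/leafcarbon-methods.Rmd` — model description, assumptions,
  parameter choices and limitations.
- `tests/testthat/` — unit, property and acceptance tests.
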