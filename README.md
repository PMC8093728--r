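# cpforage

Biologging analysis of central-place foraging consistency: from raw GPS and
time-depth-recorder (TDR) streams to foraging trips, benthic/pelagic dive
classification, site-fidelity and foraging-success indices, and
mixed-model repeatability of individual behaviour.

## The problem

Central-place foragers — the motivating system is lactating female fur
seals provisioning pups from a breeding colony over a 60–70 m continental
shelf — return repeatedly to sea on multi-day foraging trips. Two questions
structure the analysis:

1. **Repeatability.** How much of the variation in each foraging behaviour
   (trip range, duration, distance, dive rate, modal dive depth, benthic
   and daylight diving fractions) lies *between* individuals? For a
   behaviour with between-individual variance σα² and within-individual
   (residual) variance σε², the population-level repeatability is

   R = σα² / (σα² + σε²),

   estimated from linear mixed models with an individual random intercept
   (binomial logit GLMMs with an observation-level random effect for the
   proportion behaviours, where R = σα²/(σα² + σ_OLRE² + π²/3) on the link
   scale). Morphometric fixed effects are screened for collinearity
   (|r| > 0.7) and selected by all-subsets AICc (Δ < 4); permutation tests
   and parametric bootstrap give inference. The individual-level
   repeatability is R′ = 1 − R.

2. **Consistency and payoff.** Per individual: coefficients of variation
   of each behaviour across trips, the circular SD of trip bearings, and a
   **Foraging Site Fidelity Index** — the mean Bhattacharyya affinity
   BA = Σ√(pᵢqᵢ) between the 95% kernel utilization distributions of dive
   time (1 km grid) of all trip pairs. Per-trip success indices from
   logistic prey-capture probabilities over benthic dives: **FTSI**
   (Σp / benthic dive hours) and **FTEI** (Σp / benthic dive rate). Four
   linear models then relate consistency to success and efficiency.

A synthetic-data generator (`simulate_population()`) emulates the full
deployment — correlated-random-walk trips, trapezoid dive profiles over a
60–70 m shelf, ~75% benthic diving, individual-specific latent bearing /
trip duration / benthic propensity with configurable variance components —
and records the ground truth every stage is validated against.

## Worked example

```r
library(cpforage)

cfg <- sim_config(n_individuals = 5, trips_per_individual = 4,
                  trip_duration_meanlog = log(18),
                  trip_duration_range_h = c(12, 30), seed = 42)
sim <- simulate_population(cfg)
write_fixtures(sim, "demo")

res <- run_pipeline(pipeline_config("demo", "demo-out",
                                    colony = cfg$colony,
                                    n_perm = 199, n_boot = 199, seed = 1))
res$fidelity
#>   individual_id  fsfi n_trips
#> 1          ID01 0.296       4
#> 2          ID02 0.293       4
#> 3          ID03 0.436       4
#> 4          ID04 0.520       4
#> 5          ID05 0.508       4
```

Each individual's FSFI is the mean pairwise overlap of its four trips'
dive-time utilization distributions: ~0.3 means patches are revisited
loosely, ~0.5 strong site fidelity (1 would be identical space use, 0 no
overlap at all).

```r
res$repeatability[, c("behavior", "r", "ci_low", "ci_high", "p_perm", "band")]
#>         behavior       r ci_low ci_high p_perm         band
#> 1      max_range 4.8e-01      0    0.84  0.015 considerable
#> 2 total_distance 4.8e-01      0    0.82  0.005 considerable
#> 3       duration 4.9e-01      0    0.85  0.020 considerable
#> 4      dive_rate 1.6e-01      0    0.60  0.165          low
#> 5    modal_depth 0.0e+00      0    0.51  1.000          low
#> 6   prop_benthic 7.1e-11     NA      NA     NA          low
#> 7  prop_daylight 0.0e+00     NA      NA     NA          low
```

With only 5 simulated individuals the spatial behaviours (range, distance,
duration — driven by each individual's latent bearing and trip-duration
mean) already show considerable repeatability with significant permutation
tests, while behaviours with little simulated between-individual variance
sit near 0; proportion behaviours are fitted on the logit link and report
no CI by design. `demo-out/` also holds `trips.csv` (one row per trip with
all eight behaviour metrics plus FTSI/FTEI), `dives.csv`, `indices.csv`,
`consistency_models.json` (the four consistency models) and a
`manifest.json` that attributes every dropped fix, dive and bout to a
named rule.

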