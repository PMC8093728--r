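---
title: "Methods: from raw biologging records to repeatability and consistency of foraging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw biologging records to repeatability and consistency of foraging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cpforage` analyses GPS and time-depth-recorder (TDR) deployments from
central-place foraging marine predators — the motivating system is lactating
female fur seals making multi-day benthic foraging trips over a 60--70 m
continental shelf — and asks two questions: how much of the variation in
foraging behaviour lies *between* rather than *within* individuals
(repeatability), and whether individuals that behave more *consistently*
also forage more successfully.

This vignette explains the models and procedures stage by stage, the
tunable parameters and their defaults, the numerical choices made where the
methodology is genuinely open, and what the synthetic-data generator does
and does not emulate.

## 1. Dive processing

**Zero-offset correction.** TDR pressure sensors drift, so the raw
"surface" reading wanders away from 0 m. `zero_offset_correct()` estimates
the surface baseline as the 5th percentile of depth over successive 3 h
windows, interpolated linearly between window centres, then subtracts it
and clips at 0 m. The percentile must lie below the fraction of time spent
at the surface (about a third of the time for a ~155 s dive / ~90 s
surface-interval duty cycle, so 0.05 is safe). A block-interpolated
baseline rather than an exact sample-by-sample rolling quantile is the
package's own choice: at 1--5 s sampling it is orders of magnitude cheaper
and recovers a 3 m / 6 h drift ramp to well under 0.5 m (tested).

**Dive detection.** A dive is a maximal contiguous run of samples at or
below the 5 m threshold; excursions that never reach 5 m are surface
activity and are discarded. Within a dive, the *bottom phase* is the set of
samples at or deeper than 80% of the dive's maximum depth — a deterministic
rule standing in for the descent/ascent inflection heuristics used by
interactive dive software. Descent rate is maximum depth divided by the
time from dive start to the first bottom-phase sample; vertical distance is
twice the maximum depth (robust to sampling interval, unlike summed
|depth differences|). One- and two-sample spike dives are retained with the
whole excursion treated as bottom phase.

**Per-trip dive metrics.** Proportion of benthic dives, proportion of dives
starting inside the local-clock daylight window (07:00--18:00 by default;
assignment uses the dive *start* time, an unambiguous convention), dive
rate (summed vertical distance over time at sea, m/h), and modal dive depth
(mode of 1-m-binned maximum depths, ties broken toward the deeper bin —
binning is required because "modal depth" of continuous data is otherwise
undefined).

## 2. Track processing

Fixes pass a single forward McConnell-style speed filter at 6 m/s: each fix
is dropped when the great-circle speed implied from the previous *retained*
fix exceeds the ceiling. Retained fixes are linearly interpolated at 10 s in
a local azimuthal-equidistant projection centred on the colony — this
projection preserves distance and bearing from the colony exactly, which is
what the range/bearing metrics and the shared 1 km grid need; no projection
is distortion-free, but over a few hundred km the segment-length error is
below 0.1% (tested).

Haul-out handling uses two rules: any fix within 1 km of a known haul-out
site (the colony included) is excluded, and any stationary dry period of at
least 10 min — "dry" inferred from the depth record showing nothing deeper
than 0.5 m near the fix — is flagged as a haul-out. A foraging trip is a
continuous at-sea period of at least 6 h containing at least one dive;
departure and return are defined by crossing the colony's own 1 km buffer
(consistent with the haul-out buffer treatment), and bouts separated only
by a mid-trip haul-out are merged back with the haul-out time *excluded*
from trip duration. Each dive is joined to its nearest-in-time interpolated
fix.

Trip spatial metrics: maximum great-circle range from the colony, initial
bearing to the most distal fix (degrees clockwise from true north), and
total distance = horizontal path length plus the summed per-dive vertical
distances.

## 3. Benthic / pelagic classification

Each dive gets a bottom-time-weighted depth index,

$$ I = \text{max depth} \times \frac{\text{bottom time}}{\text{duration}}. $$

For a shelf forager this index is bimodal: benthic dives are deep with long
flat bottoms, pelagic dives shallower with brief bottoms.
`fit_benthic_split()` fits a Gaussian kernel density to one individual's
index values (Silverman's reference bandwidth — the classical source for
this split does not print one), selects the two highest local maxima, and
places the nadir at the density minimum between them; dives at or right of
the nadir are benthic. The fit is per individual because the split is
relative to the individual's own dive distribution. If the density has no
interior minimum the split is undefined; the documented fallback labels the
single mode benthic when its mean bottom-time fraction is at least 0.4
(flat-bottomed dives), pelagic otherwise. Labels are invariant to affine
rescaling of the index (the KDE bandwidth is scale-equivariant); nonlinear
monotone transforms can in principle reshape the density and are not
claimed.

## 4. Spatial fidelity

Dive time is accumulated on a 1 x 1 km grid anchored at the colony (all
trips and individuals share cell boundaries), then smoothed into a
utilization distribution (UD) by a bivariate Gaussian kernel with kernels at
occupied cell centres weighted by their dive seconds. The reference
bandwidth is generalized to weighted data as

$$ h_{ref} = \hat\sigma\, n_{eff}^{-1/6}, \qquad
   \hat\sigma = \sqrt{\tfrac{1}{2}(\mathrm{var}_w(x) + \mathrm{var}_w(y))},
   \qquad n_{eff} = (\textstyle\sum w)^2 / \sum w^2 , $$

reducing to the usual normal reference rule for equal weights. The UD is
truncated to the smallest cell set holding 95% of the mass and
renormalized *before* overlap is measured — the isopleth-first convention;
truncating after overlap is the main alternative reading of "95% kernel
overlap" and is switchable via the `isopleth` argument. A single occupied
cell (or zero spread) degenerates to a point mass.

Overlap between two trips is the Bhattacharyya affinity
$BA = \sum_i \sqrt{p_i q_i} \in [0, 1]$, and the **Foraging Site Fidelity
Index (FSFI)** of an individual is the mean BA over all unordered pairs of
its trips: 0 = no overlap between any trips, 1 = identical space use.

## 5. Foraging success and efficiency

Per-dive prey-capture probabilities come from a logistic model in descent
rate and dive duration, `p = plogis(b0 + b1 * descent_rate + b2 *
duration)`, applicable to *benthic* dives only (the calibration of such
models is video-validated on benthic dives). The shipped default
coefficients (−2, 1.2 per m/s, 0.004 per s) are **unvalidated synthetic
placeholders**, chosen so that default synthetic trips produce success
indices of the order of magnitude reported for shelf-foraging otariids
(roughly 6--18 per hour); any real analysis must substitute calibrated
coefficients via `capture_model()`.

Per trip, with capture probabilities $p_i$ over its benthic dives:

- **FTSI** (success) $= \sum_i p_i \,/\, \sum_i d_i$ with $d_i$ benthic
  dive durations in hours — expected captures per hour of benthic diving;
- **FTEI** (efficiency) $= \sum_i p_i \,/\, \text{benthic dive rate}$,
  the benthic dive rate being summed benthic vertical distance (m) over
  time at sea (h) — captures per unit of vertical effort.

The hour denominator for FTSI is a unit convention exposed through the trip
duration argument rather than hard-coded deeper, because the index scale is
convention-dependent.

## 6. Repeatability

For each behaviour, the population-level repeatability is

$$ R = \frac{\sigma_\alpha^2}{\sigma_\alpha^2 + \sigma_\epsilon^2}, $$

the between-individual share of variance from a mixed model with an
individual random intercept (REML, via `lme4`). Total distance, trip
duration and dive rate are cube-root transformed toward Gaussian residuals
before fitting. Candidate morphometric fixed effects (standard length,
flipper length, axillary girth, axis length, mass) are first screened for
collinearity — from any pair with |Pearson r| > 0.7 one member is dropped,
mass and standard length first (they are near-duplicates of girth and axis
length) — then selected by all-subsets AICc under maximum likelihood: among
models within ΔAICc < 4 of the best, the most parsimonious is chosen and
refitted with REML. With fixed effects present the estimate is an
*adjusted* repeatability. Non-positive variance estimates are floored at 0.

Inference, Gaussian case: a permutation test (individual labels permuted
across trips, default N = 1000; p computed with the +1 finite-sample
correction) and a parametric bootstrap percentile 95% CI (responses
simulated from the fitted model, default N = 1000; `lme4::refit` keeps this
cheap). The bootstrap is parametric because the grouped design makes naive
nonparametric resampling ill-defined at small individual counts. The
permutation *statistic* is the one-way ANOVA F for the individual grouping
on the covariate-adjusted response, not the REML R itself: the REML
estimate of σα² sits exactly on the 0 boundary in a large fraction of null
fits, so an R-based permutation p would carry an atom at 1 and be
conservative, whereas F is a continuous, monotone transform of the
unconstrained between/within variance ratio and yields exactly uniform
null p-values (verified by simulation in the test suite).

Proportion behaviours (benthic fraction, daylight fraction) use a binomial
logit GLMM with the per-trip dive count as denominator and an
observation-level random effect (OLRE) absorbing overdispersion; the
link-scale repeatability is
$R = \sigma_\alpha^2 / (\sigma_\alpha^2 + \sigma_{OLRE}^2 + \pi^2/3)$,
with $\pi^2/3 \approx 3.290$ the logistic distribution-specific variance.
No CI or permutation test is produced for proportions.

The individual-level repeatability is the complement $R' = 1 - R$, and
estimates are banded low (0--0.25], considerable (0.25--0.5], moderate
(0.5--0.75], high (> 0.75), boundaries falling in the lower band.

## 7. Consistency and its payoff

Per individual (≥ 3 trips): coefficients of variation (SD/mean) of each
behaviour, the circular SD of trip bearings
$\sqrt{-2\ln \bar R}\cdot 180/\pi$ (with $\bar R$ the mean resultant
length; a CV is meaningless for angles), and the mean and CV of FTSI and
FTEI. FTSI/FTEI enter at the individual level as across-trip *means* — the
aggregation has to be chosen, and the mean is the documented choice.

Four linear models relate consistency to payoff: responses mean FTSI, mean
FTEI, CV(FTSI), CV(FTEI); predictors the behaviour CVs plus bearing
circular SD and FSFI, with the CVs of total and horizontal distance
excluded a priori (they duplicate trip-duration variability). Selection is
the same all-subsets AICc procedure; reports carry AIC, the
likelihood-ratio test against the intercept-only null (ML), r², and
per-covariate estimates with SE, t and 95% CI.

## 8. The synthetic-data generator

`simulate_population()` emulates the study design so that every stage has
ground truth: ~34 individuals × 3--12 trips of 2--11 days (defaults),
10-min GPS, 5 s depth. Each trip is an outbound correlated-random-walk leg
along the individual's latent bearing (turning noise 4° per 10-min step,
transit speed log-normal around 0.8 m/s capped at 2 m/s — below the 6 m/s
filter, so clean tracks pass untouched and filter tests stay independent of
the generator), an area-restricted random-walk loop at the distal patch,
and a return leg with Brownian-bridge wiggle. Dive cycles draw durations
N(155 s, 35 s), log-normal surface intervals (median 90 s — a realistic
duty cycle, chosen by the package), and Bernoulli benthic labels from the
individual's propensity; benthic dives are trapezoids to the local seafloor
(smooth 60--70 m shelf) with bottom fraction 0.5, pelagic dives reach
30--70% of the seafloor with bottom fraction 0.15, making the classifier's
index bimodal by construction. Morphometrics are drawn around published
colony means (mass 70.4 kg, standard length 151.4 cm, flipper 42.5 cm,
axis 63.2 cm, girth 99.2 cm) with a built-in factor structure that makes
mass and standard length collinear (|r| > 0.7) with girth and axis length,
so the screening rule fires the way it does on real morphometrics.

Individual heterogeneity enters through latent per-individual means for
bearing, log trip duration and logit benthic propensity with configurable
between- (σα²) and within-individual (σε²) variances; the implied R values
are the recovery targets for the repeatability machinery. Defaults (bearing
35²/25² deg², log duration 0.14/0.06, logit propensity 1.2/0.30) give
individual-level variance shares in the 0.6--0.8 band typical of this kind
of deployment data. The `benthic_propensity_mean` is a *population mean on
the probability scale*: the logit intercept is solved numerically so the
logistic-normal mixture has exactly that mean (otherwise the latent
variance would shrink the realized benthic fraction by ~5 points). The
generator writes plain-CSV fixtures and a truth table (latent means, dive
labels, trip boundaries, realized variance ratios by direct decomposition
of the simulated draws).

What it does **not** emulate: oceanography and tides, prey-field dynamics,
Argos-style location error classes, device failure/duty-cycling gaps, sex
or age structure (a homogeneous adult-female population is assumed), or
depth-sensor noise beyond drift. Passing tests on synthetic data therefore
demonstrate algorithmic correctness and statistical calibration under the
stated generative assumptions, not field performance on any real
deployment.

## 9. Numerical choices, problem sizes, and limitations

- Degenerate inputs: all-zero depth traces are identity under correction;
  single-cell UDs are point masses; unimodal index distributions use the
  explicit fallback; constant behaviours give CV 0 (CV of a zero-mean
  behaviour is flagged NA); boundary repeatability values classify into the
  lower band; ties in the benthic split go to benthic, in modal depth to
  the deeper bin.
- Permutation p-values use (1 + #{r* ≥ r}) / (N + 1), so they are never 0
  and are uniform on a discrete grid under the null.
- Test problem sizes are chosen to exercise each property at the smallest
  scale where it is statistically identifiable: e.g. repeatability recovery
  at 50 individuals × 8 trips, bootstrap coverage over 80 replicates × 300
  draws, classifier calibration on populations with > 2,000 dives, and
  short (12--30 h) synthetic trips for end-to-end pipeline checks.
- Known limitations: the wet/dry proxy infers "dry" from absence of depth
  activity, which misreads long surface-transit bouts as dry when diving is
  patch-restricted (use spatial buffers only in that case); the index split
  needs ≥ 30 dives per individual; proportion repeatability is reported on
  the link scale only; and AICc selection with individual-level covariates
  is mildly anti-conservative at small individual counts — the selection
  tests quantify this.
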