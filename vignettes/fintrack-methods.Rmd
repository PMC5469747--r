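---
title: "Movement analysis for Argos-tracked whales: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement analysis for Argos-tracked whales: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fintrack)
```

# Overview

`fintrack` takes raw Argos satellite locations for tagged whales through
a complete movement analysis: track assembly and segmentation, a
Bayesian two-state switching state-space model that separates directed
transit from area-restricted search (ARS, the standard telemetry proxy
for foraging), behavioural classification and per-tag percentage
reports, kernel utilisation distributions (UD) with 50%/90% isopleth
home ranges, chlorophyll-front habitat suitability with proximity
statistics, and overlap of home ranges with shipping-traffic density.
Because real Argos tracks, satellite chlorophyll and vessel-density
rasters are proprietary or volatile, the package also ships a
first-class synthetic-data generator that emulates all three inputs
with known ground truth; every claim the test suite makes is evaluated
against that ground truth.

# Track ingestion

Argos fixes carry a platform id (PTT), a timestamp, a lon/lat position
and a location class in \{3, 2, 1, 0, A, B\}, ordered from most to
least precise. Class "Z" (invalid) is rejected at parse time. Within a
platform, fixes sharing a timestamp are reduced to the one with the
best class — the most precise observation is retained. Tracks are
split into segments wherever the gap between consecutive fixes strictly
exceeds 4 days (segments labelled "a", "b", ... in temporal order), and
platforms are excluded when they return no locations at all, or when
their total tracked duration is below 3 days or they carry fewer than
10 fixes. The duration/fix-count cut-offs are deliberately
config-exposed: published analyses describe excluding tags of "short
duration" without a numeric rule, so the defaults here are declared
choices, not established constants.

# The switching state-space model

## Process model

The movement model is a first-difference correlated random walk (DCRW)
on a regular time grid with step $\Delta$ (default 12 h), switched by a
two-state Markov behavioural process $b_t \in \{1, 2\}$ (1 = transit,
2 = ARS):

$$\mathbf{x}_{t+1} \;=\; \mathbf{x}_t + \gamma_{b_t}\,
T(\theta_{b_t})\,(\mathbf{x}_t - \mathbf{x}_{t-1}) + \boldsymbol\varepsilon_t,
\qquad \boldsymbol\varepsilon_t \sim \mathcal N_2(\mathbf 0, \Sigma),$$

where $T(\theta)$ is the rotation matrix for mean turning angle
$\theta$ and $\gamma_k \in (0,1)$ is the move persistence of state
$k$. Transit is the persistent, low-turning regime
($\gamma_1 > \gamma_2$, $|\theta_1| < \pi/4$); ARS has low persistence
and free turning ($\theta_2 \in (-\pi, \pi]$). The behavioural chain
has switching probabilities $\alpha_k = \Pr(b_t = 1 \mid b_{t-1} = k)$.
The first difference of each segment gets a $\mathcal N_2(\mathbf 0,
\Sigma)$ prior: without it the first grid node enters the likelihood
only through $\gamma_b\,\mathbf d_1$ and becomes unidentified whenever
$\gamma$ is small, which in turn pins $\gamma_2$ spuriously against
zero.

The model operates in planar degrees, which is acceptable at
Mediterranean scale; an optional longitude-compression correction is
deliberately omitted from the default path because all downstream area
computation happens in a true equal-area projection.

## Observation model

Fix $i$, observed at an arbitrary time inside grid interval $t_i$ with
fractional position $j_i \in [0, 1)$, is modelled as the linear
interpolation $(1-j_i)\mathbf{x}_{t_i} + j_i \mathbf{x}_{t_i+1}$ plus
independent per-coordinate Student-$t$ noise with class-specific scale
$\tau_{lc}$ and degrees of freedom $\nu_{lc}$. The heavy $t$ tails
absorb the occasional multi-degree Argos outlier without prefiltering,
which is why the package applies no speed or angle filters. The
default error table (degrees) is $\tau = (0.01, 0.02, 0.04, 0.08,
0.12, 0.25)$ for classes $(3, 2, 1, 0, A, B)$ with $\nu = 4$
throughout — declared constants matching the synthetic generator so
that validation closes the loop; analyses of real data should
substitute literature values via the `error_table` argument.

## Priors

* $\gamma_1 \sim \mathrm{Beta}(5, 2)$, $\gamma_2 \sim \mathrm{Beta}(2,
  5)$, jointly truncated to $\gamma_1 > \gamma_2$. Weakly-informative
  shapes (transit persistent, ARS not) are used instead of flat
  priors for an identifiability reason found during development: with
  flat priors and a track containing a single regime, the second state
  can drift up to mimic the first ($\gamma_2 \to \gamma_1$) and the
  state labels then flip freely, leaving behavioural means near 1.5.
  The Beta shapes break that plateau while placing ample mass over the
  plausible range; `c(1, 1)` restores flat priors via the `priors`
  argument.
* $\theta_1 \sim \mathrm U(-\pi/4, \pi/4)$, $\theta_2 \sim \mathrm
  U(-\pi, \pi]$.
* $\alpha_k \sim \mathrm{Beta}(1, 1)$; the initial state of each
  segment is uniform on \{1, 2\} (rather than the chain's stationary
  distribution) so the $\alpha$ full conditionals remain exactly Beta.
* $\Sigma$ via independent half-Normal scales (scale 1 degree) and a
  uniform correlation on $(-1, 1)$.

## Sampler

A purpose-written Metropolis-within-Gibbs sampler (C++ via Rcpp; all
randomness from R's RNG, so `set.seed` gives bit-identical output):

* $b_t$: exact full-conditional draws given neighbours and locations.
* $\mathbf{x}_t$: per-node bivariate random-walk Metropolis with
  per-node scales adapted toward a 30% acceptance rate in batches of
  50 during burn-in only.
* $\gamma_k$, $\theta_k$: random-walk Metropolis with reflecting
  proposals at the support boundaries (reflection keeps the kernel
  symmetric and prevents the adaptive scales from trapping a chain
  against a bound), plus a joint Cartesian update of
  $(\gamma_k\cos\theta_k, \gamma_k\sin\theta_k)$. The polar
  parameterisation is degenerate at $\gamma = 0$ — the turning angle
  is then unidentified — and the Cartesian move lets a chain pass
  through the origin and flip the turning angle; the uniform
  $(\gamma, \theta)$ prior contributes a $1/\gamma$ Jacobian to its
  acceptance ratio.
* $\alpha$: conjugate Beta draws from state-transition counts.
* $\Sigma$: blocked random-walk on (scales, correlation).

Movement parameters are pooled across all segments — the hierarchical
sharing that lets short tracks borrow strength from long ones — while
latent paths and states are per-segment. Defaults are 2 chains of
5,000 burn-in plus 10,000 retained iterations thinned by 10;
convergence is flagged by split-$\hat R < 1.1$ and effective sample
sizes computed from the pooled parameters. The desk-scale runs in the
test suite use shorter chains (stated per test) chosen so the full
suite completes in minutes.

The regular grid of each segment is anchored at its first fix by
default; the pipeline anchors at the preceding UTC step boundary
(00:00, 12:00, ...) so that state intervals are canonical rather than
tied to the arbitrary arrival time of the first fix.

# Behavioural classification

The posterior mean state $\hat b_t \in [1, 2]$ is classified with the
conservative cut-offs 1.25 / 1.75: below 1.25 is transit, above 1.75
is ARS, and the closed interval in between — including the boundary
values — is "uncertain". Per-track reports convert label counts to
integer percentages with largest-remainder rounding (remainder ties
broken in the order transit, ARS, uncertain), so every printed row
sums to exactly 100. Region-level ARS rates pool label counts over all
locations of all segments rather than averaging per-segment
percentages.

# Home ranges

All positions are pooled (per-whale UDs are available by subsetting)
and projected with a Lambert azimuthal equal-area projection centred
on the position centroid, so probability masses and km² areas are
area-true. The UD is a Gaussian product-kernel density on a regular
grid (default 128 × 128, margin 3.5 bandwidths), with Silverman's
per-axis reference rule $h_j = 0.9\,\min(\mathrm{sd}_j,
\mathrm{IQR}_j/1.34)\, n^{-1/5}$ as the default bandwidth. Physical
barriers are handled by mask-and-renormalise: density on barrier cells
is zeroed and the remainder rescaled to unit mass, which preserves
testable bookkeeping exactly. Isopleths take cells in decreasing
density order (ties broken by cell index for determinism) until the
requested mass is reached; the 50% and 90% superlevel sets are the
core (CHR) and total (THR) home ranges. The minimum bounding geometry
(MBG) is the convex hull of the positions in the projected plane.

Home-range regions are represented as grid cell sets rather than
traced vector polygons: cell sets are exact with respect to the UD
discretisation, nest by construction, and make the overlap arithmetic
below reproducible to the last cell. The GeoJSON writers emit the cell
polygons for mapping.

# Habitat suitability and proximity

Daily potential feeding habitat is the conjunction of four criteria:
front-adjacency (within a 2-cell dilation of a detected front),
chlorophyll-a in a window (defaults 0.05–0.5 mg m⁻³; only the upper
bound is established, the lower bound is a declared default), depth of
at least 200 m, and being a sea cell. The front detector flags cells
where the centred-finite-difference gradient magnitude of log
chlorophyll-a reaches a threshold (default 0.5 per 100 km); working on
the log field makes the mask invariant to uniform rescaling of the
field, and the synthetic scene's fronts are sigmoidal in log space so
the analytic maximum-gradient line is available as an oracle. The full
published multi-scale front-detection machinery is out of scope; this
log-gradient proxy is the package's own simplification.

Daily positions (per-platform daily means of the estimated locations)
are matched to the same day's mask; the proximity statistic is the
great-circle (haversine, R = 6371 km) distance to the nearest suitable
cell centre, zero when the position's own cell is suitable, and the
summary fraction counts distances strictly below the threshold
(default 7 km). Days with an empty mask yield missing distances that
are excluded from the fraction and reported separately.

# Traffic overlap

Vessel-density rasters carry integer values in [0, 409]. "High
traffic" is, by default, the cells inside the MBG whose nonzero value
reaches the 90th percentile of the nonzero in-MBG values — the source
analyses never state their threshold, so the rule is data-adaptive and
config-exposed, with an absolute-threshold alternative. Overlap
percentages are area(THR ∩ high-traffic)/area(THR) (likewise CHR),
clipped to the MBG, computed on the UD grid's cells with traffic
looked up through the inverse equal-area projection. A direct
cell-mask pathway exists for constructed geometries and for testing;
both pathways agree to the cell level on aligned scenes.

# The synthetic generator

`simulate_dcrws` draws states and the path from exactly the process
model above (initial state from the chain's stationary distribution;
initial displacement 0.05° plus process noise). `observe_argos` draws
observation times from a Poisson process (default 3 fixes/day,
mimicking irregular Argos duty cycles), samples location classes from
a realistic whale-tag mix weighted toward the poor classes
(frequencies 0.08/0.12/0.18/0.22/0.22/0.18 for 3/2/1/0/A/B), and adds
per-coordinate $t$ noise from the error table. `simulate_scene` builds
daily chlorophyll fields with a sigmoidal (in log space) meridional
front that can drift by day, a bathymetry ramp monotone offshore with
an optional land margin, and integer traffic rasters with values only
along specified lanes.

What the generator does *not* emulate: habitat-driven movement (tracks
and chlorophyll are independent, so synthetic proximity fractions are
properties of the scene geometry, not of behaviour), ocean-circulation
realism, seasonal climatology, or AIS-derived lane structure. Passing
tests therefore demonstrate that the estimators recover what the model
family encodes — not that the model family captures everything in real
tracks.

The end-to-end pipeline demo simulates whales with long ARS bouts and
roughly two-thirds ARS occupancy ($\alpha = (0.9, 0.05)$), emulating
the ARS-dominated behaviour reported for Mediterranean feeding
grounds; the parameter-recovery validation instead uses the sharper
two-regime setting $(\gamma_1, \gamma_2, \theta_2, \alpha_1, \alpha_2)
= (0.85, 0.15, \pi, 0.9, 0.3)$ with 3 segments of 150 steps and 10
seeded replicates, a size chosen to make posterior coverage checks
meaningful on a single CPU.

# Numerical choices and degenerate inputs

* Gap splitting is strict (`> 4` days), duplicate timestamps keep the
  best class, and empty tracks are errors.
* `regularise` requires at least two steps of span and places a fix
  falling exactly on the final node at that node with fractional
  position 0.
* Collinear position sets are rejected before hull construction using
  the singular values of the centred coordinates (the projection's
  curvature would otherwise hide exact collinearity).
* Isopleth and high-traffic ties are broken by cell index, making all
  raster outputs deterministic.
* Percentages that must sum to 100 use largest-remainder rounding.
* Sample standard deviations use the $n-1$ denominator everywhere; a
  single duration reports SD as not applicable.

# Known limitations

* Two behavioural states only; no covariate-dependent switching, no
  continuous-time formulation.
* Planar-degree process model; adequate for Mediterranean latitudes,
  inappropriate near the poles.
* Single-site latent-location updates mix slowly for very long
  segments; raise iterations via `mcmc` for production analyses.
* The front proxy is a single-scale gradient threshold; published
  multi-scale detectors will flag different (generally larger) front
  sets.
* Barrier handling redistributes masked mass globally rather than
  locally, which can understate density immediately adjacent to a
  barrier.
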