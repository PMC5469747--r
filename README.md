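# fintrack

Movement analysis for Argos-tracked whales: behavioural state
estimation, home ranges, habitat suitability and shipping-traffic
overlap, in one tested R package.

## The problem

Satellite telemetry of large whales produces sparse, irregular Argos
fixes with heavy-tailed, class-dependent position errors. Conservation
questions hang on what can be extracted from those tracks: where do the
animals forage (area-restricted search, ARS, versus directed transit)?
What area do they use (core and total home ranges)? How close do they
stay to suitable feeding habitat, and how much of their range overlaps
busy shipping lanes — the leading source of human-caused mortality for
Mediterranean fin whales?

`fintrack` implements that full analysis chain for movement ecologists:

1. **Ingestion** — parse and validate Argos tables, assemble per-tag
   tracks, split at temporal gaps longer than 4 days, exclude tags with
   no locations or too little data.
2. **State-space model** — a Bayesian hierarchical switching
   first-difference correlated random walk (DCRWS), fitted by a
   purpose-written Metropolis-within-Gibbs sampler (Rcpp). For
   behavioural state $b_t \in \{1 =$ transit, $2 =$ ARS$\}$:

   $$\mathbf{x}_{t+1} = \mathbf{x}_t + \gamma_{b_t}
   T(\theta_{b_t})(\mathbf{x}_t - \mathbf{x}_{t-1}) +
   \boldsymbol\varepsilon_t, \quad
   \boldsymbol\varepsilon_t \sim \mathcal N_2(\mathbf 0, \Sigma)$$

   with Markov switching $\alpha_k = \Pr(b_t = 1 \mid b_{t-1} = k)$,
   per-location-class Student-t observation errors at linearly
   interpolated fix times, and movement parameters pooled across all
   track segments so short tracks borrow strength from long ones.
3. **Classification** — posterior mean states $\hat b_t \in [1, 2]$
   labelled transit / ARS / uncertain under the conservative 1.25/1.75
   cut-offs; per-tag integer percentage reports (largest-remainder
   rounding, rows sum to 100) and pooled regional ARS rates.
4. **Home ranges** — Gaussian-kernel utilisation distribution in an
   equal-area projection with barrier masking; 50% (core, CHR) and 90%
   (total, THR) isopleths; convex-hull minimum bounding geometry (MBG).
5. **Habitat** — daily suitability masks from chlorophyll-a front
   detection (log-gradient threshold), a chlorophyll window
   (0.05–0.5 mg m⁻³), and a 200 m minimum depth; frequency-of-occurrence
   maps; haversine distance from daily positions to nearest suitable
   habitat.
6. **Traffic overlap** — high-traffic extraction from vessel-density
   rasters (90th percentile of nonzero in-MBG values by default) and
   percentage overlap with THR and CHR.
7. **Synthetic data** — generators for switching-CRW tracks observed
   through the Argos error model, frontal chlorophyll/bathymetry
   scenes, and lane-structured traffic rasters, all pure functions of
   (spec, seed) with known ground truth.

A single-config pipeline (`run_pipeline()`) chains the stages and
writes a manifest with per-file digests; identical config and seed give
byte-identical outputs.

## Worked example

A complete synthetic study — simulate two tagged whales and their
environment, ingest, fit, classify, estimate home ranges, habitat
proximity and traffic overlap — from one config:

```r
library(fintrack)
out <- file.path(tempdir(), "whale_run")
cfg <- default_pipeline_config(out, seed = 501)
cfg$simulate$n_steps <- 120          # 60 days per platform at 12-h steps
cfg$simulate$scene$n_days <- 70
cfg$fit$mcmc <- list(chains = 2, iter = 4000, burn = 4000, thin = 10)
run_pipeline(cfg)
rep <- pipeline_report(out, tag_types = c("transdermal", "LIMPET"))
writeLines(rep$text)
```

```
== fintrack run summary ==
LIMPET tags: mean duration 58.0 days, SD not applicable (n=1)
transdermal tags: mean duration 58.0 days, SD not applicable (n=1)
per-segment behaviour (%):
  SIM01a: 58 days, transit 8 / ARS 66 / uncertain 26
  SIM02a: 58 days, transit 18 / ARS 44 / uncertain 38
pooled: ARS 55.1%, transit 13.2%, uncertain 31.6% (n=234)
habitat proximity: 52.5% of 118 positions within 7 km
traffic overlap: THR 19.0%, CHR 26.7%
```

Reading the output: each simulated tag gets a Table-style row — days of
transmission and the percentage of locations classified as transit, ARS
or uncertain (the integer percentages sum to 100 by construction). The
pooled line counts locations across all segments. The substantial
uncertain share is expected behaviour of the conservative cut-offs
under realistic Argos noise, not a failure mode. The proximity line is
the fraction of daily positions strictly within 7 km of that day's
suitable habitat; the overlap line gives the percentage of the total
(90%) and core (50%) home-range areas lying in high-traffic cells
within the MBG. Because the run is seeded, repeating it reproduces
every number exactly.

The per-stage outputs (posterior locations with credible bounds,
Table-style CSV reports, UD grids, GeoJSON home ranges, proximity and
overlap JSON) are written under `out`; see
`vignettes/fintrack-methods.Rmd` for the model, priors, sampler and
every numerical convention.

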