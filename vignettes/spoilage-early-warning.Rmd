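---
title: "Early warning of apple spoilage from warehouse gas sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Early warning of apple spoilage from warehouse gas sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spoilwarn)
```

## The problem

Apples in storage spoil mainly through fungal infection (dominantly
*Aspergillus niger*); as spoilage progresses, the gas composition of the
storage micro-environment shifts — volatile organic compounds (VOC) and
ethylene (C2H4) accumulate, while respiration-driven CO2 release and O2
consumption decline as tissue metabolism collapses. A six-channel sensor
array (temperature, humidity, CO2, C2H4, O2, broadband VOC) sampled at
1 Hz for 500 s per acquisition turns that shift into a 500 × 6 recording,
which is flattened sensor-major into a 3000-element feature vector:
positions 1–500 hold the temperature trace, 501–1000 humidity,
1001–1500 CO2, 1501–2000 C2H4, 2001–2500 O2, 2501–3000 VOC.

The modelling target is the storage day (1–8; days 1–2 fresh, 3–8 after
inoculation), a proxy for spoilage progression. Because only a small
fraction of the 3000 sensor-timepoints carries day-discriminating
information, the package wraps partial least squares (PLS) regression in
four metaheuristic variable selectors — genetic algorithm (GA), simulated
annealing (SA), ant colony optimization (ACO) and competitive adaptive
reweighted sampling (CARS) — and refits a sparse linear *warning model*

$$ Y = b_0 + \sum_{j} b_j\, x_{i_j} $$

on the selected indices $i_j$. The continuous score $Y$ is interpreted
through spoilage grade bands: fresh (1–2), mild (3–4), medium (5–6),
severe (7–8).

The package also ships the published 20-term reference model (indices and
coefficients plus intercept 38.9899) as an evaluable
`paper_reference_model()`. Its coefficients are stored verbatim; whether
they apply to raw or autoscaled sensor values is not derivable without the
original recordings, so scoring is deliberately scale-agnostic and no
claim is made that scoring simulated data with it reproduces the published
calibration statistics.

## The simulator

No public recordings exist, so the generator is a first-class module and
every downstream stage is exercised on simulated warehouses:

* **Design**: 9 warehouses × 8 days, one acquisition each → 72 samples.
* **Day structure**: only the across-day *ordering* of mean responses per
  gas channel is an observed constraint (e.g. VOC responds most strongly
  on day 7, then 8, 4, 6, 5, 1, 3, 2). `default_day_level_table()` assigns
  evenly spaced equilibrium levels inside a plausible operating band per
  channel (CO2 400–3000 ppm, C2H4 5–80 ppm, O2 5–25 %VOL, VOC 2–40 ppm),
  ordered to match. The published CO2 narrative is internally inconsistent
  (the prose describes declining release while the printed ranking rises
  toward day 8); the generator encodes the printed ranking only.
* **Within-acquisition dynamics** are unspecified in the source; a
  first-order saturating rise from an ambient baseline toward the day
  level (time constant 60 s by default) is used because electrochemical
  and infrared gas sensors approach equilibrium monotonically. Setting the
  time constant to 0 gives an instant plateau, which makes ordering
  assertions exact.
* **Noise**: i.i.d. Gaussian per timepoint per channel, sd defaulting to
  1% of each channel's full scale (the sensors' stated ±2% FS precision
  class); readings are clipped to the detection ranges
  (C2H4 0–100 ppm, O2 0–30 %VOL, VOC 0–50 ppm, CO2 0–5000 ppm,
  temperature −20–80 °C, humidity 0–100 %rh).
* **Embedded signal**: for parameter-recovery experiments,
  `embed_signal = TRUE` regenerates the response as a known sparse linear
  function of chosen flattened indices plus Gaussian label noise
  (sd 0.3 by default); `default_embedded_signal()` picks indices across
  the four gas channels and scales coefficients so the response spans
  roughly the 1–8 range. The ground truth is returned alongside the
  dataset.

What the simulator does **not** emulate: fungal growth kinetics, apple
physiology, gas transport through the pump/air-chamber, inter-channel
correlation beyond the shared day structure, drift, or autocorrelated
sensor noise. Passing recovery tests therefore demonstrates that the
algorithms work when the assumed sparse linear day↔signal structure holds;
they say nothing about model transfer to real warehouses.

## Chemometrics core

`fit_pls()` is a single-response NIPALS implementation: predictors and
response are autoscaled internally (the channels carry incommensurate
units), each component's weight vector is the normalised covariance
between the deflated predictors and response, and the composite
coefficients are folded back to raw units so a model is a plain affine
map. With the full number of components on a full-rank matrix, PLS
coincides with ordinary least squares — the test suite uses `lm()` as the
independent oracle for exactly this case. Model size is chosen by k-fold
RMSECV (`kfold_rmsecv()`), with pooled out-of-fold residuals and divisor
*n* in every RMSE. Fold assignment is seeded and shared across all
selectors so their fitness values are comparable.

The calibration/prediction split is stratified by day (default 2:1,
seeded); the original split rule is unpublished, so this is a package
policy, configurable, with leave-warehouses-out achievable by splitting
manually. Reported statistics follow the chemometrics convention:
Rc/RMSEC on calibration rows, Rp/RMSEP on prediction rows.

## The four selectors

All four minimise the same RMSECV fitness and return a `selection_result`
(sorted indices, fitness trace, per-variable score, config echo, seed).
Published parameter values are the defaults; choices the source leaves
open are listed here as package decisions:

* **GA** (30 chromosomes, deletion group 5, mutation 0.01, crossover 0.5,
  100 generations): "deletion group" is read as generational replacement
  of the five worst chromosomes, with tournament (size 2) parent
  selection and uniform crossover. Final selection keeps variables whose
  inclusion frequency across the final population reaches 0.5 (the
  published threshold is unprinted; configurable).
* **SA** (T 10 → 1, cooling 0.95, chain length 10, window widths 10–20
  step 1, 2 points swapped per move, ≤ 12 components): the window width is
  interpreted as the selected-set size of one annealing pass, initialised
  as a random contiguous index window; moves swap set members for
  outsiders and are accepted by the Metropolis criterion
  `exp(-ΔE/T)`. This width/swap interaction is the module's largest
  interpretive choice. The best state ever visited across all widths is
  returned.
* **ACO** (50 ants, 10 cycles × 50 iterations, P 0.3, Q 0.01): the update
  rule is unpublished; ants sample variable i with probability
  `min(1, k·τ_i/Στ)` where k is an expected subset size (default 50, the
  order of the published ACO selection), pheromone evaporates at rate 0.1
  and each ant deposits `Q/RMSECV` on its subset. Variables whose final
  inclusion probability reaches P are selected, falling back to the top
  variables by pheromone (with a warning) when none does.
* **CARS** (≤ 15 components, 5 folds, 2000 Monte Carlo runs, 80%
  subsampling): each run fits PLS on a row subsample, forces the live set
  down the exponential-decay schedule `r_i = a·e^{-k·i}` with boundary
  conditions `r_1 = 1` and `r_N = 2/p`, then resamples by |coefficient|
  (adaptive reweighted sampling, on the autoscaled coefficient scale so
  channels with different units are comparable). The run whose live set
  cross-validates best is returned. Retention counts use an
  epsilon-tolerant ceiling (`cars_retention_counts()`) because the exact
  boundary value `r_N·p = 2` otherwise lands one ulp above 2. Whether the
  published "2000 Monte Carlo sampling runs" means 2000 schedule steps is
  ambiguous; it is treated as the number of runs N and is configurable.

## Numerical and degenerate-input policy

Constant features get unit scale instead of dividing by zero; constant
responses are an error for fitting but yield a constant predictor inside
CV folds; NIPALS stops early when deflation exhausts rank; correlation on
zero-variance vectors is a labelled error rather than NaN; empty subsets,
out-of-range indices, malformed CSV/JSON, and day labels outside 1–8 are
labelled errors. All stochastic entry points take seeds and restore the
session RNG state, so identical configs give bitwise-identical output.

## Grade bands

The published bands leave gaps (2–3, 4–5, 6–7). Midpoint boundaries are
used — fresh below 2.5, mild [2.5, 4.5), medium [4.5, 6.5), severe from
6.5 — so every finite score is classifiable; scores outside [1, 8] keep
the nearest band and are flagged out-of-range. Grading is monotone in the
score by construction.

## Problem sizes used by the test suite

The packaged tests run the full 72 × 3000 study conditions for
simulation, splitting and PLS recovery (20 replicates for the
Rp ≥ 0.9 recovery check), and desk-scale selector settings for the
search-heavy comparisons: GA 15 iterations, SA windows 10–12, ACO
20 ants × 5 iterations × 2 cycles, CARS 50 Monte Carlo runs (10 seeded
replicates of each, against equal-size random subsets). Toy oracles
(exhaustive best-subset search at p ≤ 12) validate SA and GA directly,
with GA at its full published settings since the toys are cheap.
These sizes are the package's chosen experiment scale; the full published
settings remain the config defaults.

## Known limitations

* The simulator's independence assumptions (no drift, white noise, shared
  day structure as the only inter-channel link) make selection easier than
  on real e-nose data.
* The published Table of calibration/prediction statistics cannot be
  reproduced without the original recordings; the packaged surrogates are
  recovery and oracle-agreement properties on synthetic data.
* Scoring simulated acquisitions with the bundled reference model
  typically lands far outside the 1–8 band (its intercept is 38.9899 and
  its coefficient scale is unknowable without the original data); the
  out-of-range flag exists for exactly this situation.
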