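---
title: "Decoding single-exposure visual memory from IT spike counts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding single-exposure visual memory from IT spike counts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itmemory)
```

## The scientific problem

After a single exposure to an image, primates can report minutes later
whether they have seen it before. A long-standing candidate neural substrate
is *repetition suppression* in inferotemporal (IT) cortex: repeated images
evoke fewer spikes than novel ones, and the decrement fades with the number
of intervening trials (n-back). `itmemory` implements the full chain of
analyses needed to test whether such signals can *quantitatively* account
for behavior: behavioral summaries, pseudopopulation construction,
cross-validated linear decoding, strength-theory reaction-time prediction,
a benchmarked prediction-quality score, and population-size extrapolation —
plus a synthetic-data generator that emulates the statistical structure of
the recordings so every stage is testable offline.

## The task and its generator

Each trial shows one image; the subject reports "novel" or "familiar".
Images appear exactly twice, with n-back separations drawn from
`1, 2, 4, 8, 16, 32, 64` intervening trials. At the default 4.5 s mean
trial interval these correspond to mean delays of 4.5 s up to 4.8 min —
forgetting over minutes within a session.

`generate_task_sequence()` builds the trial order the way an experimenter
would: the hardest (64-back) pairs are placed first into a sequence 1.2×
the minimum length, a quota of `ceiling(0.83 * n_pairs)` pairs per level is
placed in a first pass (restarting the pass when placement fails), the
remaining slots are backfilled from the n-back list, and residual slots are
filled with "off n-back" pairs that every analysis excludes. Both the 1.2×
length margin and the 83% first-pass quota are package choices: the margin
keeps 64-back placement feasible without making sessions unrealistically
long, and the quota matches the occupancy at which backfilling still
succeeds reliably. The generator restarts a bounded number of times and
raises if the per-level pair counts cannot be kept within ±10% of uniform.

## The synthetic IT population

`sim_config()`/`simulate_population()` draw, for each unit:

* a per-image gain from a log-normal with unit mean and `sdlog =
  selectivity_dispersion` (default 1). The log-normal is a package choice —
  it is positive, right-skewed like IT firing-rate distributions, and has a
  single dispersion knob; the data motivating this package do not pin down
  a selectivity distribution.
* an expected novel-presentation count `grand_mean_counts × gain`,
  normalised so the unit's grand mean over images equals
  `grand_mean_counts` (default 3 spikes in the 150–400 ms window, i.e.
  12 spikes/s — a typical IT response).
* familiar-presentation expectations `novel × (1 − d(nback))`, with the
  multiplicative decrement profile `d(n) = d1 · n^(-decay)` (defaults
  `d1 = 0.11`, `decay = 0.25`), applied to a configurable
  `memory_fraction` of units (default 0.5, motivated by evidence that
  roughly half of IT units carry the useful memory signal).
* observed counts as independent Poisson draws.

The derived simulations rebuild units from measured statistics.
`make_replication_unit()` inverts the multiplicative model from
novel/familiar pair averages: with decrement `d`,
`novel = 2·mean/(2 − d)` and `familiar = novel·(1 − d)`, so a 6-spike pair
average at `d = 0.10` predicts 6.32/5.68 spikes and a 3-spike average
3.16/2.84. `remove_visual_modulation()` applies the same inversion around
the unit's grand mean, erasing image selectivity while preserving the
per-n-back decrement and the unit's overall rate.
`simulate_timecourse()` adds a minimal temporal skeleton (baseline rate
5 spikes/s, visual onset 75 ms, memory expression from 150 ms) for PSTHs
and sliding-window analyses; it is a windowed-rate model, not a
point-process model of real spike trains.

The behavioral generator (`observer_config()`/`simulate_behavior()`) is a
strength-theory observer: per-trial Gaussian memory strength compared to a
criterion (strength below criterion reads "familiar"), and mean RT linear
in the proportion of the trial's condition-and-outcome cell (defaults:
intercept 400 ms from the go cue, slope −150 ms per unit proportion,
30 ms Gaussian trial jitter — the jitter magnitude is a package choice; the
underlying map is deterministic in the mean). This reproduces both the
declining forgetting function and the x-shaped correct/error RT pattern.

## Pseudopopulation and decoding

`build_pseudopopulation()` concatenates units recorded (or simulated) in
separate sessions into a units × pairs × {novel, familiar} tensor aligned
by n-back, with the pooled default template of 15, 15, 16, 17, 17, 15, 12
pairs at 1–64-back (107 pairs). Alignment across sessions treats
cross-session responses as uncorrelated; excess pairs are subsampled at
random, and sessions that cannot fill the template raise an error naming
the deficient session and level.

Each decoding iteration (`resample_split()`, `run_decoding()`):

1. independently permutes every unit's pairs within each n-back, removing
   artificial cross-unit correlations while preserving all per-unit
   condition marginals;
2. holds out 2 images per n-back with both presentations (4 trials per
   n-back);
3. fits the decoder on the remaining pairs, pooling all n-backs and
   ignoring behavioral outcome;
4. evaluates memory strength `s = w·x − b` on the held-out trials.

Sign conventions: class 1 is novel, class 2 familiar, so positive weights
mean repetition suppression; `s < 0` predicts "familiar" and ties predict
novel (a strict below-criterion rule). Units with zero pooled variance get
weight zero (recorded on the model) rather than an infinite d'. Ranked
variants re-estimate the criterion at every population size N — each N is
a distinct classifier. With all units selected, ranked-FLD reproduces the
regular FLD exactly, seed stream included.

## Predictions, PQ, and extrapolation

`predict_forgetting()` turns pooled strength samples into predicted
proportions; `proportions_by_outcome()` and `fit_rt_map()` convert them to
reaction times through a least-squares line (flat-line fallback when the
proportions are constant); `compute_pq()` scores predictions as

`PQ = 100 × (MSE_benchmark − MSE_neural) / MSE_benchmark`,

where the benchmark is a step at the behavior's overall proportion correct
(e.g. 84% overall correct ⇒ 84% for every familiar condition and 16% for
novel). This is the unique fractional-MSE form with the two anchor
properties PQ = 100 at a perfect prediction and PQ = 0 at the benchmark.
The overall proportion correct is trial-count-weighted when counts are
available (a pooling flag, since session-level pooling conventions vary).

For sizes beyond the recorded population (at most 1.5×),
`decoding_stats()` tracks how the per-condition means and SDs of the raw
projections `w·x`, and the criterion `b`, grow with size;
`fit_mean_trajectory()` fits lines (FLD means grow linearly, SCC means are
grand means and stay flat) and `fit_sd_trajectory()` fits the
two-parameter forms `SD(x) = (a·x)^b` (FLD) and `SD(x) = a·x^(1/b)` (SCC,
plateauing for negative `b`). The SD fits use a log–log linear
initialisation refined by multi-start Levenberg–Marquardt; near-flat
trajectories are flagged degenerate and treated as constant rather than
fitted. Fits use sizes ≥ 25 units — smaller populations make the SD
estimates unstable. `predict_extended()` then reads Gaussian tail masses
below the extrapolated criterion.

## Numerical properties worth knowing

**A closed-form oracle.** For a fully memory-carrying Poisson population
with unit-mean gains, the asymptotic FLD pipeline has a closed form
(`expected_decoded_forgetting()`): the predicted proportion at n-back k is
`pnorm((d_k − d̄/2)·√N·G / sqrt((1−d_k)²G²v + (1−d_k)G))` with grand mean
`G`, gain variance `v` and pair-weighted mean decrement `d̄`. The package
uses it as an independent check of the resampling pipeline and to
calibrate decrements to a target forgetting function
(`calibrate_decrements()`). Because the criterion sits midway between the
novel and pooled-familiar class means, the novel false-alarm rate is tied
to `d̄`: target functions inconsistent with that geometry are matched in
least squares, not exactly.

**Finite-population fluctuations.** On a *fixed* population, held-out
strengths reuse the same recorded (or simulated) spike counts across
iterations, so each condition's decoded proportion fluctuates around its
expectation with SD ≈ 0.4/√(pairs per n-back) — irreducible by more units
or more iterations. Chance-level calibration checks therefore average over
replicate generated populations, whose expectation is exactly 50%. The
same property means single-population decoded proportions at the standard
15-pair template carry ~±10-point condition-level uncertainty; this is a
property of the resampling design, not an implementation artifact.

**Problem sizes.** The test suite runs the full chain at reduced scales
chosen to keep Monte-Carlo error well inside its assertions: end-to-end
recovery uses 120 units × 150 pairs per n-back (tolerance 0.06 against the
closed form), chance calibration averages 12 replicate 60-unit populations
with 500 pairs per level, suppression recovery uses 800-unit populations at
the 15-pair template, and the size sweep spans 15–120 units with Gaussian
extrapolation to 180. These sizes are the package's own test design;
nothing prevents running the same functions at larger scales.

## What the generator does and does not emulate

It reproduces: per-unit rate heterogeneity and visual selectivity, Poisson
trial variability, multiplicative n-back-dependent suppression carried by a
subpopulation, session structure and pseudopopulation alignment, and a
behavioral observer consistent with strength theory. It does **not**
emulate: noise correlations between simultaneously recorded units (the
pseudopopulation construction assumes them away, so tests cannot speak to
their impact), non-Poisson dispersion, adaptation within a session,
eye-movement artifacts, or any trial-by-trial coupling between neural and
behavioral fluctuations — decoded predictions and behavior are linked only
through condition means. Passing tests therefore validate the analysis
machinery and its statistical calibration, not claims about real IT data.

## Known limitations

* Extrapolation is deliberately capped at 1.5× the fitted size range;
  beyond that the Gaussian trajectory assumptions are unverifiable.
* The bootstrap mean-difference p value is one-tailed by construction
  (fraction of sign flips); a two-tailed doubling is available via
  `two_tailed = TRUE`.
* `signed_rank_test()` is a plain two-sided Wilcoxon one-sample test; the
  choice of sidedness for d' distributions is a convention, not a result.
* Off-n-back residual pairs are generated (with decrements interpolated on
  the log2 n-back scale) only so that sessions are complete; every
  analysis excludes them.
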