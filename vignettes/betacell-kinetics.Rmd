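---
title: "Counting living beta cells: the model behind betakin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting living beta cells: the model behind betakin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betakin)
```

## The problem

Pancreatic beta cells in serum-free culture change in number through two
processes that a single end-point assay cannot separate: death (with later
disintegration of the corpse) and recruitment of quiescent cells into the
cell cycle. `betakin` implements the quantification machinery for following
*living* beta-cell numbers by whole-well fluorescence imaging — nuclear
(Hoechst) counting with propidium iodide (PI) dead-cell exclusion and an
insulin-positivity correction — together with the dual thymidine-analog
(EdU then BrdU) design that distinguishes *recruitment* of new cells into
the cycle from *re-entry* of previously divided cells.

Because the raw microscope data behind this assay class are not public, the
package is driven end to end by two synthetic-data generators that are
first-class, tested components: a stochastic population simulator
(`simulate_population()`) and a well-image renderer (`render_well()`). Every
stage of the measurement pipeline can therefore be scored against exact
ground truth.

## The population model

The simulator is a discrete-time Markov birth–death process over cell
states {quiescent, cycling, refractory, dead, disintegrated}:

* a quiescent cell is recruited into the cycle in a step of length
  $\Delta t$ with probability $1 - e^{-\lambda \Delta t}$, where the
  recruitment hazard $\lambda$ (per day) may follow a piecewise-constant
  schedule — the glucose and age dependence of the system lives here;
* a living cell dies with probability $1 - e^{-\delta \Delta t}$; the death
  hazard $\delta$ can differ by state (quiescent / cycling / refractory);
* a recruited cell traverses a cycle of fixed length $L$ (default 1.0 d)
  and on completion is replaced by two daughters; both inherit all labels
  (no label dilution — a labeled mother yields two labeled daughters), and
  both are quiescence-locked for a *refractory period* $\rho$ before they
  are again eligible for recruitment;
* a thymidine analog is incorporated if its labeling window overlaps the
  first $s \cdot L$ of the cycle (the S-phase; $s = 0.3$ by default). The
  standard design is EdU on days 3–6 and BrdU on days 7–10 with a 24-h
  label-free gap;
* a dead cell stays PI-detectable for `disintegration_days` (default 5 d),
  then disappears from the countable population — which is why end-point
  dead-cell percentages understate cumulative death.

Cycle length, S-phase fraction, refractory duration and the hazards are
*free parameters*: the experimental literature this assay family comes from
does not pin them down, so they are explicit configuration values, never
constants in analysis code. The refractory period is a hard minimum delay
rather than a reduced hazard; this is the simplest mechanism that produces
the characteristic signature of the assay — counted double-positive cells
falling below the independence prediction — and it makes the window-geometry
limit (no double labeling possible when $\rho + L$ exceeds the span between
the windows) exact.

Bookkeeping: at a division the existing record continues as one daughter
and a second record is appended, so every division adds exactly one living
record and the identity

$$ n_\text{living} + n_\text{dead,cum} = n_\text{initial} + n_\text{divisions,cum} $$

holds exactly at every snapshot. The test suite asserts it on every
simulated trajectory.

Stepping is discrete-time ($\Delta t = 0.05$ d by default, configurable and
validated against the closed form $1 - e^{-\lambda w}$ for the labeled
fraction of a window of length $w$) rather than exact event-driven
simulation; at the tolerances relevant here (binomial noise at
$n \le 20{,}000$) the discretization error is negligible, and the stepping
keeps the implementation a small amount of vectorized R. Within a step the
order is deaths, recruitments, divisions, refractory releases,
disintegrations; events are timestamped at the step midpoint so that
window-edge labeling is unbiased at the $\Delta t/2$ scale.

## The independence (stochastic-replication) null

If replication is purely stochastic, being labeled in the first window does
not change the probability of labeling in the second, so the expected
double-positive percentage is the product of the marginals:

$$ \hat f_{EB} = f_E \, f_B / 100 . $$

`predicted_double()` computes this, `reentry_fraction()` the complementary
readout $100 f_{EB} / f_E$ (the percent of first-window-labeled cells that
re-entered), and `stochastic_reentry_test()` compares counted and predicted
values from summary statistics. `reentry_null_experiment()` runs the whole
design in silico: with $\rho = 0$ the counted value matches the prediction
(the mean replicate difference sits within Monte-Carlo error of zero);
with $\rho = 4$ d it is significantly lower in essentially every replicate.
Within a replicate the null is tested by an exact binomial test of the
double-positive count among EdU+ cells against the overall BrdU+ marginal;
this treats the marginal as fixed, an approximation that is conservative at
the effect sizes the refractory period produces.

## The image model and the counter

`render_well()` places nuclei uniformly with a hard-core minimum distance
(sequential placement on a bucket grid; above `aggregation_above` cells the
constraint is dropped, reproducing the aggregated regime where counting
degrades). Each nucleus is a Gaussian spot with $\sigma = r/2$ truncated at
$3\sigma$ — chosen for analytic tractability, not optical realism; there is
no PSF, z-dimension or tile stitching. Insulin is a flat cytoplasmic
annulus of width 4 px outside the nuclear radius, wide enough that the 3-px
measurement ring falls inside it. Noise, when enabled, is Poisson on the
accumulated signal plus Gaussian read noise, rounded to integer detector
units. Pixel size, magnification and intensities are arbitrary defaults
(documented in `imaging_params()`), since no instrument is being emulated.
Coordinates are 0-based (row, col) with pixel centers at integers,
everywhere including the ground-truth table.

The counter mirrors the classical high-content pipeline:

1. **Background**: low-percentile block filter (64-px windows, 25th
   percentile) resized bilinearly; corrected image is
   $\max(\text{image} - \text{background}, 0)$; the noise scale is a
   sigma-clipped MAD of the residual.
2. **Segmentation**: "dynamic thresholding" is implemented as
   background-residual thresholding at $k \times$ noise scale (default
   $k = 5$), bounded below by a signal-relative floor of $e^{-2}$ of the
   peak corrected intensity — the level that cuts an isolated Gaussian spot
   exactly at its nominal radius, and the operative threshold for
   noise-free images, whose noise scale is zero. No specific published
   algorithm is being copied — both knobs are exposed, and the
   seeded-versus-counted linearity validation is the calibration gate. Touching nuclei are split by a distance-transform
   watershed (on by default); components outside the 8–400 px area range
   are discarded.
3. **Measurement**: per-cell means over nuclear pixels and over a 3-px
   annular ring assigned to its nearest nucleus, so rings partition the
   perinuclear space (ties go to the larger label, a deterministic
   tie-break); a fully crowded-out ring flags the cell instead of
   inventing a value.
4. **Classification**: PI/EdU/BrdU on nuclear means, insulin on the ring
   mean; strictly-greater-than thresholds (ties negative) for determinism.
   `"auto"` thresholds take the valley between the two dominant modes of
   the per-well histogram and are accepted only when the split is genuine
   (valley at most half the smaller peak, each side at least 2% of cells,
   between-class separation exceeding three within-class standard
   deviations); otherwise the well falls back to the noise-scale rule with
   a warning — the typical case being a well with no positives for a
   marker. Whether per-well automatic thresholding matches what any given
   laboratory does is unknowable from published methods; fixed numeric
   thresholds are supported for that reason.
5. **Counting**: living = Hoechst-positive − PI-positive; the living
   *beta*-cell number corrects for the insulin-negative fraction, computed
   among PI-negative cells (dead cells' insulin status is unreliable);
   rounding (half-to-even) happens only at report time.

## Derived statistics

Per-well counts feed the kinetics layer: `percent_of_reference()`
normalizes to day 1 (per replicate, then averaged — the mean-of-ratios
presentation used with ±SEM tables; the ratio of means is also reported for
transparency), `cumulative_recruitment()` sums interval labeled fractions
and carries an explicit overestimation caveat (an interval may count both
daughters of a previously activated cell), `hourly_fractional_release()`
converts 72-h insulin collections into percent of content per hour, and
`t_test_from_summary()` recovers SDs from SEMs to run the two-tailed
unpaired t-test (pooled by default, Welch optional).

## Scenario presets

Twelve shipped presets (`scenario_names()`) cover neonatal / young-adult /
old populations at 5/10/20 mmol/l glucose plus glucokinase-activator (GKA)
variants. They are **calibrations, not measurements**: hazards were chosen
so the qualitative pattern comes out — adult numbers fall at 5, rise
moderately at 10 and more at 20 mmol/l; neonatal populations roughly double
at 5/10 but shrink at 20 mmol/l under a high glucotoxic death hazard, with
no refractory period; old populations stay flat; GKA presets reuse the
20 mmol/l recruitment schedule at lower glucose (a lowered threshold, not an
enlarged recruitable pool). Magnitudes were tuned only coarsely against
those orderings; within-window recruitment rates were chosen to give labeled
fractions of the same order as the assay reports. Users studying anything
quantitative should treat the presets as starting points.

## Problem sizes and numerical choices

The validation runs used throughout tests and the acceptance script are
sized for a single CPU: 8 seeded densities × 3 replicate wells spanning
100–10,000 cells for the linearity gate, 20 replicates of 20,000-cell
populations for the re-entry null, 2,000-cell wells for segmentation
scoring. The simulator's per-step probabilities use `1 - exp(-h dt)`
exactly (not the `h dt` linearization). Degenerate inputs fail loudly and
typed: configuration errors (`betakin_config_error`) for invalid parameter
combinations, undefined-fraction errors for empty denominators, data errors
for malformed files; an empty image segments to an empty label map rather
than erroring.

## What passing tests do and do not show

The generators reproduce the *statistical structure* of the assay —
binomial labeling, birth–death kinetics, spot-like nuclei over smooth
background with shot noise — but not optical blur, staining variability,
focus drift, debris, or spatial clustering of related cells. A pipeline
that scores perfectly here can still need threshold recalibration on real
microscope data; conversely, the linearity, conservation and
independence-model results are exact properties of the method itself and
carry over. Real-data entry points are `read_well()` (multi-page TIFF plus
a plain-text channel map) and per-well counts in CSV.

## A worked example

```{r example, eval = FALSE}
cfg <- scenario_config("adult_20mM", n_cells_initial = 2000)
sim <- simulate_population(cfg, seed = 1)
tail(sim$snapshots, 3)

tab <- label_fractions(sim, day = 10)
tab
predicted_double(tab$f_E, tab$f_B)   # independence prediction
reentry_fraction(tab)                # % EdU+ cells relabeled with BrdU

roster <- cell_roster(sim, day = 15)
rw <- render_well(roster, imaging_params(), seed = 2)
count_well_image(rw$image)$counts
```
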