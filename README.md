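# betakin

Imaging-based counting and proliferation kinetics of cultured pancreatic
beta cells — an R package for scientists who follow *living* cell numbers
in serum-free culture and need to separate effects on survival from effects
on proliferation.

The package implements, as tested and simulator-verifiable components:

* **Whole-well counting.** Nuclear (Hoechst) segmentation by dynamic
  thresholding over a robust background estimate, distance-transform
  watershed splitting of touching nuclei, per-cell intensity averaging over
  the nucleus and a 3-px annular cytoplasm ring, and the corrected count

  `n_living_beta = (n_Hoechst+ − n_PI+) × f_insulin+`,

  i.e. living cells are Hoechst-positive minus PI-positive, corrected for
  the insulin-negative fraction. The calibration gate is the
  seeded-versus-counted linearity over 100–10,000 cells/well
  (`linearity_validation()`), summarized by the adjusted
  r² = 1 − (1 − r²)(n − 1)/(n − 2).

* **Dual pulse-chase analysis.** For sequential EdU (days 3–6) and BrdU
  (days 7–10) labeling, the marginals f_E = f_{E only} + f_{EB} and
  f_B = f_{B only} + f_{EB}, the stochastic (independence) prediction for
  double-positives f_E·f_B/100, the re-entry fraction 100·f_{EB}/f_E, and a
  summary-statistic t-test of counted versus predicted — the readout that
  reveals a post-mitotic refractory period when counted < predicted.

* **A stochastic population simulator.** Discrete-time birth–death process
  with per-day recruitment hazard (optionally a piecewise schedule), death
  hazard by state, fixed cycle length, S-phase analog incorporation, label
  inheritance by both daughters, a hard post-mitotic refractory period, and
  dead-cell disintegration (`simulate_population()`).

* **A synthetic well renderer** with exact per-cell ground truth
  (`render_well()`), so segmentation, classification and counting can be
  scored precisely (`segmentation_score()`).

* **Kinetics statistics**: percent-of-day-1 normalization, cumulative
  interval recruitment (with its overestimation caveat), per-cell hourly
  fractional insulin release, pooled/Welch t-tests from (mean, SEM, n).

See the vignette (`vignettes/betacell-kinetics.Rmd`) for the model, its
assumptions and the numerical choices.

## Worked example

```r
library(betakin)

# simulate a young-adult population at stimulating glucose
cfg <- scenario_config("adult_20mM", n_cells_initial = 2000)
sim <- simulate_population(cfg, seed = 1)
tab <- label_fractions(sim, day = 10)
tab
#> dual-label fractions (%): E+B- 11.29 | B+E- 18.75 | E+B+ 0.67  (f_E 11.97, f_B 19.43)
predicted_double(tab$f_E, tab$f_B)
#> [1] 2.325004
reentry_fraction(tab)
#> [1] 5.633803

# image the well at day 15 and count it
roster <- cell_roster(sim, day = 15)
rw <- render_well(roster, imaging_params(), seed = 2)
count_well_image(rw$image)$counts
#> well_counts: 2528 Ho+ | 59 PI+ | 2469 living | 92.4% insulin+ | 2281 living beta
#>   labels among insulin+ living: EdU 12.28% BrdU 20.34% double 0.88%
```

The counted double-positive fraction (0.67%) sits far below the
independence prediction (2.33%): the simulated 4-day refractory period
suppresses cell-cycle re-entry, which is exactly the signature the dual
labeling design detects. At day 15 the well has grown from 2,000 to ~2,500
cells and the counter recovers the living and dead numbers from the
rendered image.

Scenario presets (`scenario_names()`) are shipped as flat key-value config
files and are calibrated to reproduce qualitative orderings only; see the
vignette before using them quantitatively.

A thin command-line wrapper is installed as `exec/betakin`
(`simulate`, `render`, `count`, `validate-linearity`, `reproduce`).

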