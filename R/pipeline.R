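# Orchestration: the in-silico version of the full study
# (simulate -> render -> count -> analyze), with seeds logged in a manifest.

#' Cycloheximide-analogue dose-response through imaging and counting
#'
#' Simulates a short culture over a grid of death hazards (the in-silico
#' analogue of a dose-dependent apoptosis inducer) with dead cells kept
#' detectable for the whole run, renders each end-point well and counts it
#' with the full pipeline. The expected signature: counted dead increases
#' and counted living decreases with dose while the counted total stays
#' constant.
#'
#' @param death_hazards Increasing per-day death hazards (the dose axis).
#' @param n_cells Cells at seeding.
#' @param duration_days Exposure length, days.
#' @param iparams,sparams Imaging and segmentation parameters.
#' @param seed Integer seed.
#' @return data.frame: `death_hazard`, true `n_living_true`/`n_dead_true`,
#'   counted `n_living`, `n_dead`, `n_total`.
#' @export
chx_response <- function(death_hazards = c(0, 0.1, 0.2, 0.4, 0.8),
                         n_cells = 1000,
                         duration_days = 2,
                         iparams = imaging_params(image_size_px = c(900, 900)),
                         sparams = segmentation_params(),
                         seed = 1L) {
  rows <- lapply(seq_along(death_hazards), function(k) {
    cfg <- sim_config(n_cells_initial = n_cells, duration_days = duration_days,
                      recruitment_hazard = 0, death_hazard = death_hazards[k],
                      disintegration_days = duration_days + 1,
                      scenario_name = sprintf("chx_%g", death_hazards[k]))
    sim <- simulate_population(cfg, seed = seed + k)
    roster <- cell_roster(sim, duration_days)
    rw <- render_well(roster, iparams, seed = seed + 1000L + k)
    ct <- count_well_image(rw$image, sparams)$counts
    data.frame(death_hazard = death_hazards[k],
               n_living_true = sum(!roster$dead),
               n_dead_true = sum(roster$dead),
               n_living = ct$n_living,
               n_dead = ct$n_pi_pos,
               n_total = ct$n_total_ho)
  })
  do.call(rbind, rows)
}

#' Simulated percent-of-day-1 for a scenario preset
#'
#' Runs `replicates` independent simulations of a preset and normalizes the
#' living-cell snapshot at `day` to day 1 (mean of per-replicate ratios,
#' with SEM, plus the ratio of means).
#'
#' @param scenario Preset name (see [scenario_names()]) or a [sim_config()].
#' @param day Day of culture to normalize.
#' @param replicates Independent simulations.
#' @param seed Integer seed.
#' @param ... Overrides passed to [scenario_config()].
#' @return List as returned by [percent_of_reference_replicates()], plus
#'   `scenario` and `day`.
#' @export
scenario_percent_of_day1 <- function(scenario, day = 15, replicates = 3,
                                     seed = 1L, ...) {
  cfg <- if (inherits(scenario, "sim_config")) scenario else {
    scenario_config(scenario, ...)
  }
  counts_day <- counts_ref <- numeric(replicates)
  for (r in seq_len(replicates)) {
    sim <- simulate_population(cfg, seed = seed + r)
    snap <- sim$snapshots
    counts_ref[r] <- snap$n_living[snap$day == 1]
    counts_day[r] <- snap$n_living[snap$day == day]
  }
  out <- percent_of_reference_replicates(counts_day, counts_ref)
  out$scenario <- cfg$scenario_name
  out$day <- day
  out
}

#' Simulated dual-label table with the stochastic-model prediction
#'
#' Simulates a preset, tabulates the EdU/BrdU fractions among living cells
#' at `day`, and attaches the independence-model prediction
#' `f_E * f_B / 100` together with the re-entry fraction `100 f_EB / f_E`.
#'
#' @inheritParams scenario_percent_of_day1
#' @return data.frame, one row per replicate: the table fields, `predicted`,
#'   `reentry`, `n_living`.
#' @export
scenario_dual_label <- function(scenario, day = 10, replicates = 3,
                                seed = 1L, ...) {
  cfg <- if (inherits(scenario, "sim_config")) scenario else {
    scenario_config(scenario, ...)
  }
  rows <- lapply(seq_len(replicates), function(r) {
    sim <- simulate_population(cfg, seed = seed + r)
    tab <- label_fractions(sim, day)
    data.frame(scenario = cfg$scenario_name, replicate = r,
               f_E_only = tab$f_E_only, f_B_only = tab$f_B_only,
               f_EB = tab$f_EB, f_E = tab$f_E, f_B = tab$f_B,
               predicted = predicted_double(tab$f_E, tab$f_B),
               reentry = if (tab$f_E > 0) reentry_fraction(tab) else NA_real_,
               n_living = tab$n)
  })
  do.call(rbind, rows)
}

#' Replicated test of the stochastic (independence) re-entry model
#'
#' Simulates `replicates` independent populations under dual EdU/BrdU
#' labeling and compares, per replicate, the counted double-positive
#' fraction at the end of the second window with the independence-model
#' prediction `f_E * f_B / 100`. Within a replicate the null "a first-window
#' labeled cell is relabeled with the same probability as any cell" is
#' tested by an exact binomial test of the double-positive count among EdU+
#' cells against the overall BrdU+ marginal. With no refractory period the
#' counted and predicted values agree; a refractory period longer than the
#' inter-window gap suppresses the counted value below the prediction.
#'
#' @param refractory_days Post-mitotic refractory period of the simulated
#'   population.
#' @param n_cells Cells at seeding.
#' @param recruitment_hazard,death_hazard Per-day hazards.
#' @param replicates Independent simulations.
#' @param day Analysis day (end of the second window).
#' @param seed Integer seed.
#' @param ... Further [sim_config()] overrides.
#' @return List with `per_replicate` (data.frame: counted, predicted,
#'   difference, p of the within-replicate binomial test, direction),
#'   `mean_difference`, `se_difference`, `z` (mean difference over its SE),
#'   and `prop_significantly_lower`.
#' @export
reentry_null_experiment <- function(refractory_days = 0,
                                    n_cells = 20000,
                                    recruitment_hazard = 0.03,
                                    death_hazard = 0.005,
                                    replicates = 20,
                                    day = 10,
                                    seed = 1L,
                                    ...) {
  cfg <- sim_config(n_cells_initial = n_cells, duration_days = day,
                    recruitment_hazard = recruitment_hazard,
                    death_hazard = death_hazard,
                    refractory_days = refractory_days,
                    label_windows = default_label_windows(),
                    scenario_name = sprintf("reentry_rho%g", refractory_days),
                    ...)
  rows <- lapply(seq_len(replicates), function(r) {
    sim <- simulate_population(cfg, seed = seed + r)
    tab <- label_fractions(sim, day)
    cnt <- attr(tab, "counts")
    n_E <- cnt[["E_only"]] + cnt[["EB"]]
    pred <- predicted_double(tab$f_E, tab$f_B)
    p <- if (n_E > 0) {
      stats::binom.test(cnt[["EB"]], n_E, p = tab$f_B / 100)$p.value
    } else NA_real_
    data.frame(replicate = r, counted = tab$f_EB, predicted = pred,
               difference = tab$f_EB - pred, p = p,
               lower = !is.na(p) & p < 0.05 & tab$f_EB < pred)
  })
  per <- do.call(rbind, rows)
  md <- mean(per$difference)
  se <- sd(per$difference) / sqrt(nrow(per))
  list(per_replicate = per, mean_difference = md, se_difference = se,
       z = md / se, prop_significantly_lower = mean(per$lower))
}

#' Reproduce the full in-silico study
#'
#' Runs the four report stages -- seeded-versus-counted linearity
#' validation, day-15 percent-of-day-1 by age and glucose, dual-label tables
#' with predicted versus counted double-positives, and the
#' apoptosis-inducer dose-response -- and writes one CSV per stage plus a
#' `meta.json` manifest into `out_dir`. Deterministic for a fixed
#' `(arguments, seed)` pair: re-running reproduces byte-identical CSVs.
#'
#' @param out_dir Output directory, created if needed.
#' @param seed Integer master seed.
#' @param scenarios Preset names to simulate.
#' @param replicates Replicates per scenario and per seeded density.
#' @param linearity_counts Seeded densities for the linearity stage.
#' @param scenario_overrides Named list of [sim_config()] overrides applied
#'   to every scenario preset (e.g. a smaller `n_cells_initial`).
#' @param iparams,sparams Imaging and segmentation parameters.
#' @return Invisibly, a list with the four tables.
#' @export
reproduce <- function(out_dir, seed = 1L,
                      scenarios = c("neonatal_5mM", "neonatal_10mM",
                                    "neonatal_20mM", "adult_5mM",
                                    "adult_10mM", "adult_20mM", "old_5mM",
                                    "old_10mM", "old_20mM"),
                      replicates = 3,
                      linearity_counts = round(exp(seq(log(100), log(10000),
                                                       length.out = 8))),
                      scenario_overrides = list(),
                      iparams = imaging_params(),
                      sparams = segmentation_params()) {
  known <- scenario_names()
  unknown <- setdiff(scenarios, known)
  if (length(unknown)) {
    stop_config("unknown scenario(s): ", paste(unknown, collapse = ", "),
                "; available presets: ", paste(known, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  lin <- linearity_validation(linearity_counts, replicates = replicates,
                              iparams = iparams, sparams = sparams,
                              seed = seed)
  write.csv(lin$data, file.path(out_dir, "linearity.csv"), row.names = FALSE)
  lin_summary <- data.frame(slope = lin$slope, intercept = lin$intercept,
                            adjusted_r_squared = lin$adjusted_r_squared)
  write.csv(lin_summary, file.path(out_dir, "linearity_fit.csv"),
            row.names = FALSE)

  day15 <- do.call(rbind, lapply(seq_along(scenarios), function(i) {
    cfg <- do.call(scenario_config, c(list(scenarios[i]), scenario_overrides))
    p <- scenario_percent_of_day1(cfg, day = 15, replicates = replicates,
                                  seed = seed + 100L * i)
    data.frame(scenario = p$scenario, mean = p$mean, sem = p$sem, n = p$n,
               ratio_of_means = p$ratio_of_means)
  }))
  write.csv(day15, file.path(out_dir, "day15_percent_of_day1.csv"),
            row.names = FALSE)

  dual <- do.call(rbind, lapply(seq_along(scenarios), function(i) {
    cfg <- do.call(scenario_config, c(list(scenarios[i]), scenario_overrides))
    scenario_dual_label(cfg, day = 10, replicates = replicates,
                        seed = seed + 100L * i)
  }))
  write.csv(dual, file.path(out_dir, "dual_label.csv"), row.names = FALSE)

  chx <- chx_response(seed = seed + 5000L, sparams = sparams)
  write.csv(chx, file.path(out_dir, "chx_response.csv"), row.names = FALSE)

  write_manifest(out_dir, command = "reproduce", seed = seed,
                 extra = list(scenarios = scenarios, replicates = replicates,
                              linearity_counts = linearity_counts))
  invisible(list(linearity = lin, day15 = day15, dual_label = dual,
                 chx = chx))
}
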