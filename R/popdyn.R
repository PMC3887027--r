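# Stochastic simulator of a cultured beta-cell population.
#
# Discrete-time Markov stepping: at each step of length dt a quiescent cell
# may die or be recruited into the cell cycle with probability
# 1 - exp(-hazard * dt); a recruited cell traverses a cycle of fixed length,
# incorporating any thymidine analog whose labeling window overlaps the
# S-phase at the start of its cycle, and divides into two daughters that
# inherit all labels and are refractory for a fixed period. Dead cells stay
# PI-detectable for `disintegration_days`, then disappear from the countable
# population.

#' Create a labeling window for a thymidine analog
#'
#' @param analog_name `"EdU"` or `"BrdU"`.
#' @param start_day,end_day Window limits in days of culture; `start_day` must
#'   precede `end_day` and both must be non-negative.
#' @return A `label_window` list.
#' @export
label_window <- function(analog_name, start_day, end_day) {
  if (!analog_name %in% c("EdU", "BrdU")) {
    stop_config("analog_name must be 'EdU' or 'BrdU', got '", analog_name, "'")
  }
  check_scalar(start_day, "start_day", lower = 0)
  check_scalar(end_day, "end_day", lower = 0)
  if (start_day >= end_day) stop_config("label window start_day must be < end_day")
  structure(list(analog_name = analog_name, start_day = start_day,
                 end_day = end_day), class = "label_window")
}

#' Dual EdU/BrdU labeling windows used throughout
#'
#' The standard dual pulse-chase design: EdU from day 3 to 6, then BrdU from
#' day 7 to 10, with a 24-hour label-free period in between.
#'
#' @return List of two [label_window()] objects.
#' @export
default_label_windows <- function() {
  list(label_window("EdU", 3, 6), label_window("BrdU", 7, 10))
}

#' Configure a beta-cell population simulation
#'
#' @param n_cells_initial Number of cells present at day 0.
#' @param duration_days Length of the simulated culture, days.
#' @param time_step_days Markov step, days; must lie in (0, 0.25] and be no
#'   longer than the shortest labeling window.
#' @param recruitment_hazard Per-day hazard of recruitment of a quiescent cell
#'   into the cell cycle. Either a single non-negative rate or a
#'   piecewise-constant schedule given as a data.frame with columns
#'   `from_day` and `rate` (each rate applies from its `from_day` until the
#'   next entry).
#' @param death_hazard Per-day death hazard. A single rate applied to all
#'   living states, or a named vector with any of `quiescent`, `cycling`,
#'   `refractory` (unnamed states fall back to the `quiescent` entry, or 0).
#' @param cycle_length_days Days from S-phase entry to division.
#' @param s_phase_fraction Fraction of the cycle, at its start, during which a
#'   thymidine analog is incorporated; in (0, 1].
#' @param refractory_days Minimum post-division quiescence before a daughter
#'   is again eligible for recruitment (hard delay).
#' @param disintegration_days Days a dead cell remains PI-detectable before it
#'   is removed from the countable population.
#' @param fraction_insulin_positive Fraction of cells flagged insulin-positive,
#'   in `[0, 1]`; inherited by daughters.
#' @param label_windows List of [label_window()] objects with distinct analogs,
#'   all inside `[0, duration_days]`.
#' @param scenario_name Free-text tag carried into outputs.
#' @param rng_seed Default seed used when [simulate_population()] is called
#'   without one.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_cells_initial,
                       duration_days,
                       time_step_days = 0.05,
                       recruitment_hazard = 0,
                       death_hazard = 0,
                       cycle_length_days = 1.0,
                       s_phase_fraction = 0.3,
                       refractory_days = 0,
                       disintegration_days = 5,
                       fraction_insulin_positive = 1,
                       label_windows = list(),
                       scenario_name = "custom",
                       rng_seed = 1L) {
  check_scalar(n_cells_initial, "n_cells_initial", lower = 0)
  check_scalar(duration_days, "duration_days", lower = 0, allow_equal_lower = FALSE)
  check_scalar(time_step_days, "time_step_days", lower = 0, upper = 0.25,
               allow_equal_lower = FALSE)
  check_scalar(cycle_length_days, "cycle_length_days", lower = 0,
               allow_equal_lower = FALSE)
  check_scalar(s_phase_fraction, "s_phase_fraction", lower = 0, upper = 1,
               allow_equal_lower = FALSE)
  check_scalar(refractory_days, "refractory_days", lower = 0)
  check_scalar(disintegration_days, "disintegration_days", lower = 0)
  check_scalar(fraction_insulin_positive, "fraction_insulin_positive",
               lower = 0, upper = 1)

  recruitment_hazard <- normalize_hazard_schedule(recruitment_hazard)
  if (any(!is.finite(recruitment_hazard$rate)) || any(recruitment_hazard$rate < 0)) {
    stop_config("recruitment_hazard rates must be finite and >= 0")
  }
  death_hazard <- normalize_death_hazard(death_hazard)
  if (any(!is.finite(death_hazard)) || any(death_hazard < 0)) {
    stop_config("death_hazard rates must be finite and >= 0")
  }

  if (length(label_windows) > 0) {
    if (inherits(label_windows, "label_window")) label_windows <- list(label_windows)
    nm <- vapply(label_windows, function(w) {
      if (!inherits(w, "label_window")) stop_config("label_windows must contain label_window objects")
      w$analog_name
    }, character(1))
    if (anyDuplicated(nm)) stop_config("each analog may appear in at most one label window")
    for (w in label_windows) {
      if (w$start_day < 0 || w$end_day > duration_days) {
        stop_config("label window [", w$start_day, ", ", w$end_day,
                    "] lies outside [0, ", duration_days, "]")
      }
      if (time_step_days > (w$end_day - w$start_day)) {
        stop_config("time_step_days (", time_step_days,
                    ") exceeds the length of the ", w$analog_name, " window")
      }
    }
  }

  structure(list(
    n_cells_initial = as.integer(n_cells_initial),
    duration_days = duration_days,
    time_step_days = time_step_days,
    recruitment_hazard = recruitment_hazard,
    death_hazard = death_hazard,
    cycle_length_days = cycle_length_days,
    s_phase_fraction = s_phase_fraction,
    refractory_days = refractory_days,
    disintegration_days = disintegration_days,
    fraction_insulin_positive = fraction_insulin_positive,
    label_windows = label_windows,
    scenario_name = scenario_name,
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

# Accept scalar rate or data.frame(from_day, rate); return canonical data.frame.
normalize_hazard_schedule <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("from_day", "rate") %in% names(x)) || nrow(x) < 1) {
      stop_config("a hazard schedule needs columns from_day and rate")
    }
    x <- x[order(x$from_day), c("from_day", "rate")]
    if (x$from_day[1] > 0) {
      x <- rbind(data.frame(from_day = 0, rate = x$rate[1]), x)
    }
    return(x)
  }
  if (!is.numeric(x) || length(x) != 1L) {
    stop_config("recruitment_hazard must be a rate or a (from_day, rate) data.frame")
  }
  data.frame(from_day = 0, rate = as.numeric(x))
}

normalize_death_hazard <- function(x) {
  if (!is.numeric(x)) stop_config("death_hazard must be numeric")
  states <- c("quiescent", "cycling", "refractory")
  if (is.null(names(x))) {
    if (length(x) != 1L) stop_config("unnamed death_hazard must be a single rate")
    return(setNames(rep(as.numeric(x), 3), states))
  }
  if (!all(names(x) %in% states)) {
    stop_config("death_hazard names must be among: ", paste(states, collapse = ", "))
  }
  base <- if ("quiescent" %in% names(x)) x[["quiescent"]] else 0
  out <- setNames(rep(as.numeric(base), 3), states)
  out[names(x)] <- as.numeric(x)
  out
}

hazard_at <- function(schedule, day) {
  idx <- findInterval(day, schedule$from_day)
  idx[idx < 1L] <- 1L
  schedule$rate[idx]
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$scenario_name, "\n")
  cat("  ", x$n_cells_initial, "cells,", x$duration_days, "days, dt =",
      x$time_step_days, "\n")
  cat("  recruitment hazard:",
      paste(sprintf("%g/d from day %g", x$recruitment_hazard$rate,
                    x$recruitment_hazard$from_day), collapse = "; "), "\n")
  cat("  death hazard (q/c/r):", paste(signif(x$death_hazard, 3), collapse = "/"),
      " refractory:", x$refractory_days, "d\n")
  for (w in x$label_windows) {
    cat("  ", w$analog_name, "window: day", w$start_day, "to", w$end_day, "\n")
  }
  invisible(x)
}

# state codes used internally
.ST <- c(quiescent = 1L, cycling = 2L, refractory = 3L, dead = 4L, disintegrated = 5L)

#' Simulate a cultured beta-cell population
#'
#' Runs the discrete-time birth-death simulation described in the package
#' vignette and returns per-cell event histories plus integer-day population
#' snapshots. A division replaces the dividing cell by two daughters that
#' inherit all its labels (no label dilution): the existing record continues
#' as one daughter and one new record is appended with `parent_id` set, so
#' every division adds exactly one record and the conservation identity
#' `n_living + n_dead_cumulative = n_cells_initial + n_divisions_cumulative`
#' holds at every snapshot.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$rng_seed`.
#' @return A list of class `betakin_sim` with elements
#'   \describe{
#'     \item{cells}{data.frame, one row per cell record: `cell_id`,
#'       `parent_id` (NA for founders), `birth_day`, `edu`, `brdu`,
#'       `edu_day`/`brdu_day` (first incorporation day or NA),
#'       `insulin_positive`, `death_day`, `disintegration_day`, `n_s_entries`,
#'       `s_phase_entries` (list column of entry days), `state_events`
#'       (list column of character vectors `"day:state"`, chronological).}
#'     \item{snapshots}{data.frame, one row per integer day: `day`,
#'       `n_living`, `n_dead_detectable`, `n_dead_cumulative`,
#'       `n_divisions_cumulative`, `n_E_only`, `n_B_only`, `n_EB`, `n_none`.}
#'     \item{config}{the config used.}
#'     \item{seed}{the seed used.}
#'   }
#' @export
simulate_population <- function(config, seed = config$rng_seed) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(seed, simulate_population_impl(config, seed))
}

simulate_population_impl <- function(config, seed) {
  n0 <- config$n_cells_initial
  dt <- config$time_step_days
  n_steps <- ceiling(config$duration_days / dt - 1e-9)
  Lc <- config$cycle_length_days
  sdur <- config$s_phase_fraction * Lc
  rho <- config$refractory_days
  dis <- config$disintegration_days
  dh <- config$death_hazard

  windows <- config$label_windows
  win_edu <- win_brdu <- NULL
  for (w in windows) {
    if (w$analog_name == "EdU") win_edu <- c(w$start_day, w$end_day)
    if (w$analog_name == "BrdU") win_brdu <- c(w$start_day, w$end_day)
  }

  # per-record vectors; records are appended on division
  state <- rep(.ST[["quiescent"]], n0)
  parent <- rep(NA_integer_, n0)
  birth <- rep(0, n0)
  edu <- brdu <- rep(FALSE, n0)
  edu_day <- brdu_day <- rep(NA_real_, n0)
  cycle_end <- refract_end <- rep(NA_real_, n0)
  death_day <- disint_day <- rep(NA_real_, n0)
  insulin <- if (config$fraction_insulin_positive >= 1) rep(TRUE, n0) else {
    runif(n0) < config$fraction_insulin_positive
  }

  s_log_cell <- integer(0)   # record index of each S-phase entry
  s_log_day <- numeric(0)
  ev_cell <- integer(0)      # state-change event log (beyond birth state)
  ev_day <- numeric(0)
  ev_state <- integer(0)
  div_days <- numeric(0)     # one entry per division event

  log_event <- function(idx, day, st) {
    ev_cell <<- c(ev_cell, idx)
    ev_day <<- c(ev_day, rep_len(day, length(idx)))
    ev_state <<- c(ev_state, rep_len(st, length(idx)))
  }

  for (step in seq_len(n_steps)) {
    t0 <- (step - 1L) * dt
    t1 <- step * dt
    tm <- t0 + dt / 2   # event time assigned within the step

    # deaths among living states
    for (st_name in c("quiescent", "cycling", "refractory")) {
      st <- .ST[[st_name]]
      h <- dh[[st_name]]
      if (h <= 0) next
      at_risk <- which(state == st)
      if (!length(at_risk)) next
      dies <- at_risk[runif(length(at_risk)) < (1 - exp(-h * dt))]
      if (length(dies)) {
        state[dies] <- .ST[["dead"]]
        death_day[dies] <- tm
        disint_day[dies] <- tm + dis
        cycle_end[dies] <- refract_end[dies] <- NA_real_
        log_event(dies, tm, .ST[["dead"]])
      }
    }

    # recruitment of quiescent cells into the cycle
    lam <- hazard_at(config$recruitment_hazard, t0)
    if (lam > 0) {
      q <- which(state == .ST[["quiescent"]])
      if (length(q)) {
        rec <- q[runif(length(q)) < (1 - exp(-lam * dt))]
        if (length(rec)) {
          state[rec] <- .ST[["cycling"]]
          cycle_end[rec] <- tm + Lc
          s_log_cell <- c(s_log_cell, rec)
          s_log_day <- c(s_log_day, rep(tm, length(rec)))
          log_event(rec, tm, .ST[["cycling"]])
          # analog incorporation: S-phase [tm, tm + sdur] vs window overlap
          if (!is.null(win_edu) && tm < win_edu[2] && tm + sdur > win_edu[1]) {
            newly <- rec[!edu[rec]]
            edu[rec] <- TRUE
            edu_day[newly] <- tm
          }
          if (!is.null(win_brdu) && tm < win_brdu[2] && tm + sdur > win_brdu[1]) {
            newly <- rec[!brdu[rec]]
            brdu[rec] <- TRUE
            brdu_day[newly] <- tm
          }
        }
      }
    }

    # divisions: cycling cells whose cycle ends within this step
    divd <- which(state == .ST[["cycling"]] & cycle_end <= t1 + 1e-12)
    if (length(divd)) {
      dday <- cycle_end[divd]
      div_days <- c(div_days, dday)
      post <- if (rho > 0) .ST[["refractory"]] else .ST[["quiescent"]]
      # continuing daughter (reuses the record)
      state[divd] <- post
      refract_end[divd] <- if (rho > 0) dday + rho else NA_real_
      cycle_end[divd] <- NA_real_
      log_event(divd, dday, post)
      # new daughter record
      k <- length(divd)
      new_ids <- length(state) + seq_len(k)
      state <- c(state, rep(post, k))
      parent <- c(parent, divd)
      birth <- c(birth, dday)
      edu <- c(edu, edu[divd])
      brdu <- c(brdu, brdu[divd])
      edu_day <- c(edu_day, ifelse(edu[divd], dday, NA_real_))
      brdu_day <- c(brdu_day, ifelse(brdu[divd], dday, NA_real_))
      cycle_end <- c(cycle_end, rep(NA_real_, k))
      refract_end <- c(refract_end, if (rho > 0) dday + rho else rep(NA_real_, k))
      death_day <- c(death_day, rep(NA_real_, k))
      disint_day <- c(disint_day, rep(NA_real_, k))
      insulin <- c(insulin, insulin[divd])
    }

    # refractory cells whose delay has elapsed become quiescent (eligible)
    wake <- which(state == .ST[["refractory"]] & refract_end <= t1 + 1e-12)
    if (length(wake)) {
      state[wake] <- .ST[["quiescent"]]
      log_event(wake, refract_end[wake], .ST[["quiescent"]])
      refract_end[wake] <- NA_real_
    }

    # disintegration of detectable dead cells
    gone <- which(state == .ST[["dead"]] & disint_day <= t1 + 1e-12)
    if (length(gone)) {
      state[gone] <- .ST[["disintegrated"]]
      log_event(gone, disint_day[gone], .ST[["disintegrated"]])
    }
  }

  n_rec <- length(state)
  s_entries <- vector("list", n_rec)
  if (length(s_log_cell)) {
    sp <- split(s_log_day, s_log_cell)
    idx <- as.integer(names(sp))
    s_entries[idx] <- lapply(sp, unname)
  }
  s_entries[vapply(s_entries, is.null, logical(1))] <- list(numeric(0))

  # state histories as "day:state" strings, one character vector per record
  # (vectorized build; first entry is the birth state)
  state_names <- names(.ST)
  init_state <- rep(.ST[["quiescent"]], n_rec)
  if (rho > 0) init_state[!is.na(parent)] <- .ST[["refractory"]]
  all_cell <- c(seq_len(n_rec), ev_cell)
  all_day <- c(birth, ev_day)
  all_state <- c(init_state, ev_state)
  ord <- order(all_cell, all_day)
  ev_str <- sprintf("%g:%s", all_day[ord], state_names[all_state[ord]])
  events <- unname(split(ev_str, all_cell[ord]))

  cells <- data.frame(
    cell_id = seq_len(n_rec),
    parent_id = parent,
    birth_day = birth,
    edu = edu, brdu = brdu,
    edu_day = edu_day, brdu_day = brdu_day,
    insulin_positive = insulin,
    death_day = death_day,
    disintegration_day = disint_day,
    n_s_entries = vapply(s_entries, length, integer(1))
  )
  cells$s_phase_entries <- s_entries
  cells$state_events <- events

  snapshots <- do.call(rbind, lapply(0:floor(config$duration_days), function(d) {
    population_snapshot(cells, div_days, d, n0)
  }))

  structure(list(cells = cells, snapshots = snapshots, config = config,
                 seed = as.integer(seed), division_days = div_days),
            class = "betakin_sim")
}

# who is alive / detectable-dead at day d (record-level, post-hoc)
alive_at <- function(cells, day) {
  cells$birth_day <= day + 1e-9 &
    (is.na(cells$death_day) | cells$death_day > day + 1e-9)
}

dead_detectable_at <- function(cells, day) {
  !is.na(cells$death_day) & cells$death_day <= day + 1e-9 &
    cells$disintegration_day > day + 1e-9
}

population_snapshot <- function(cells, div_days, day, n0) {
  liv <- alive_at(cells, day)
  e <- !is.na(cells$edu_day) & cells$edu_day <= day + 1e-9
  b <- !is.na(cells$brdu_day) & cells$brdu_day <= day + 1e-9
  data.frame(
    day = day,
    n_living = sum(liv),
    n_dead_detectable = sum(dead_detectable_at(cells, day)),
    n_dead_cumulative = sum(!is.na(cells$death_day) & cells$death_day <= day + 1e-9),
    n_divisions_cumulative = sum(div_days <= day + 1e-9),
    n_E_only = sum(liv & e & !b),
    n_B_only = sum(liv & !e & b),
    n_EB = sum(liv & e & b),
    n_none = sum(liv & !e & !b)
  )
}

#' @export
print.betakin_sim <- function(x, ...) {
  cat("betakin_sim:", x$config$scenario_name, "(seed", x$seed, ")\n")
  cat("  ", nrow(x$cells), "cell records,",
      x$snapshots$n_divisions_cumulative[nrow(x$snapshots)], "divisions\n")
  print(utils::tail(x$snapshots, 3), row.names = FALSE)
  invisible(x)
}

#' Dual-label fractions among living cells at a given day
#'
#' Tabulates EdU/BrdU single- and double-positive fractions (percent scale)
#' among the cells living at `day`, together with the marginals
#' `f_E = f_E_only + f_EB` and `f_B = f_B_only + f_EB`.
#'
#' @param sim A `betakin_sim` result, or its `cells` data.frame.
#' @param day Day of culture to evaluate; must lie within the simulation.
#' @param denominator `"all"` (all living cells) or `"insulin_positive"`
#'   (living insulin-positive cells only). Both are meaningful readouts; the
#'   insulin-positive denominator matches immunostained counts.
#' @return A [dual_label_table()] with counts attached as attributes.
#' @export
label_fractions <- function(sim, day,
                            denominator = c("all", "insulin_positive")) {
  denominator <- match.arg(denominator)
  cells <- if (inherits(sim, "betakin_sim")) sim$cells else sim
  liv <- alive_at(cells, day)
  if (denominator == "insulin_positive") liv <- liv & cells$insulin_positive
  n <- sum(liv)
  if (n == 0) stop_undefined_fraction("no living cells at day ", day,
                                      " (denominator '", denominator, "')")
  e <- liv & !is.na(cells$edu_day) & cells$edu_day <= day + 1e-9
  b <- liv & !is.na(cells$brdu_day) & cells$brdu_day <= day + 1e-9
  tab <- dual_label_table(
    f_E_only = 100 * sum(e & !b) / n,
    f_B_only = 100 * sum(b & !e) / n,
    f_EB = 100 * sum(e & b) / n,
    n = n
  )
  attr(tab, "counts") <- c(E_only = sum(e & !b), B_only = sum(b & !e),
                           EB = sum(e & b), none = sum(liv & !e & !b))
  attr(tab, "day") <- day
  attr(tab, "denominator") <- denominator
  tab
}

#' Percent dead (PI-positive) among detectable cells
#'
#' The propidium iodide readout: dead cells are counted only while still
#' detectable (not yet disintegrated); the denominator is living plus
#' detectable dead cells, as in a stained well.
#'
#' @inheritParams label_fractions
#' @return Percent, scalar.
#' @export
percent_dead <- function(sim, day) {
  cells <- if (inherits(sim, "betakin_sim")) sim$cells else sim
  n_liv <- sum(alive_at(cells, day))
  n_dead <- sum(dead_detectable_at(cells, day))
  if (n_liv + n_dead == 0) {
    stop_undefined_fraction("no detectable cells at day ", day)
  }
  100 * n_dead / (n_liv + n_dead)
}

#' Phenotype roster of living cells at a given day
#'
#' Extracts the per-cell flags needed by the image renderer: one row per
#' detectable cell (living or PI-positive dead), with `dead`,
#' `insulin_positive`, `edu_positive`, `brdu_positive`.
#'
#' @inheritParams label_fractions
#' @return data.frame with one row per detectable cell.
#' @export
cell_roster <- function(sim, day) {
  cells <- if (inherits(sim, "betakin_sim")) sim$cells else sim
  liv <- alive_at(cells, day)
  dead <- dead_detectable_at(cells, day)
  keep <- liv | dead
  data.frame(
    cell_id = cells$cell_id[keep],
    dead = dead[keep],
    insulin_positive = cells$insulin_positive[keep],
    edu_positive = !is.na(cells$edu_day[keep]) & cells$edu_day[keep] <= day + 1e-9,
    brdu_positive = !is.na(cells$brdu_day[keep]) & cells$brdu_day[keep] <= day + 1e-9
  )
}

#' Serialize simulated cells and snapshots to CSV
#'
#' Writes `cells.csv` (events serialized as `day:state` pairs separated by
#' `;`), `snapshots.csv` and a `meta.json` run manifest into `dir`.
#'
#' @param sim A `betakin_sim`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "betakin_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cells <- sim$cells
  flat <- cells[setdiff(names(cells), c("s_phase_entries", "state_events"))]
  flat$s_phase_entries <- vapply(cells$s_phase_entries, function(x) {
    paste(signif(x, 10), collapse = ";")
  }, character(1))
  flat$state_events <- vapply(cells$state_events, paste, character(1),
                              collapse = ";")
  write.csv(flat, file.path(dir, "cells.csv"), row.names = FALSE)
  write.csv(sim$snapshots, file.path(dir, "snapshots.csv"), row.names = FALSE)
  write_manifest(dir, command = "simulate",
                 config = unclass_config_for_meta(sim$config),
                 seed = sim$seed)
  invisible(dir)
}

unclass_config_for_meta <- function(config) {
  cfg <- unclass(config)
  cfg$label_windows <- lapply(cfg$label_windows, unclass)
  cfg$recruitment_hazard <- as.list(cfg$recruitment_hazard)
  cfg$death_hazard <- as.list(cfg$death_hazard)
  cfg
}
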