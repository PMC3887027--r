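# Population simulator: event-free limits, closed-form labeling oracle,
# window geometry, bookkeeping invariants and error contracts.

test_that("with zero hazards the population is constant and unlabeled", {
  cfg <- sim_config(150, 10, recruitment_hazard = 0, death_hazard = 0,
                    label_windows = default_label_windows())
  sim <- simulate_population(cfg, seed = 1)
  snap <- sim$snapshots
  expect_equal(snap$n_living, rep(150L, 11))
  expect_equal(snap$n_dead_cumulative, rep(0L, 11))
  expect_equal(snap$n_divisions_cumulative, rep(0L, 11))
  expect_equal(snap$n_none, snap$n_living)
  tab <- label_fractions(sim, 10)
  expect_equal(c(tab$f_E_only, tab$f_B_only, tab$f_EB), c(0, 0, 0))
})

test_that("labeled fraction matches the exponential waiting-time closed form", {
  # window covers the start of culture and no cell completes a cycle inside
  # it, so P(labeled) = 1 - exp(-lambda * w)
  lam <- 0.05; w <- 3
  cfg <- sim_config(20000, w, recruitment_hazard = lam,
                    cycle_length_days = 10,
                    label_windows = list(label_window("EdU", 0, w)))
  sim <- simulate_population(cfg, seed = 101)
  f <- mean(sim$cells$edu)
  p <- 1 - exp(-lam * w)
  se <- sqrt(p * (1 - p) / 20000)
  expect_lt(abs(f - p), 3 * se)
})

test_that("recruitment rate is recoverable from the labeled fraction", {
  lam <- 0.05; w <- 3
  cfg <- sim_config(20000, w, recruitment_hazard = lam,
                    cycle_length_days = 10,
                    label_windows = list(label_window("EdU", 0, w)))
  sim <- simulate_population(cfg, seed = 202)
  lam_hat <- -log(1 - mean(sim$cells$edu)) / w
  expect_lt(abs(lam_hat - lam) / lam, 0.10)
})

test_that("a long refractory period forbids double labeling by window geometry", {
  # refractory 7 d + cycle 1 d exceed the day-3-to-day-10 span
  cfg <- sim_config(2000, 10, recruitment_hazard = 0.2,
                    refractory_days = 7, cycle_length_days = 1,
                    label_windows = default_label_windows())
  sim <- simulate_population(cfg, seed = 7)
  tab <- label_fractions(sim, 10)
  expect_equal(tab$f_EB, 0)
  expect_gt(tab$f_E, 0)
  expect_gt(tab$f_B, 0)
})

test_that("snapshot bookkeeping invariants hold on stochastic trajectories", {
  cfgs <- list(
    sim_config(500, 11, recruitment_hazard = 0.1, death_hazard = 0.05,
               refractory_days = 2, disintegration_days = 3,
               label_windows = default_label_windows()),
    sim_config(300, 6, recruitment_hazard = 0.3, death_hazard = 0.02,
               refractory_days = 0, disintegration_days = 1),
    sim_config(400, 12,
               recruitment_hazard = data.frame(from_day = c(0, 4),
                                               rate = c(0, 0.2)),
               death_hazard = c(quiescent = 0.03, cycling = 0.08,
                                refractory = 0.01),
               label_windows = default_label_windows())
  )
  for (k in seq_along(cfgs)) {
    sim <- simulate_population(cfgs[[k]], seed = 30 + k)
    snap <- sim$snapshots
    expect_equal(snap$n_living + snap$n_dead_cumulative,
                 cfgs[[k]]$n_cells_initial + snap$n_divisions_cumulative)
    expect_true(all(snap$n_dead_detectable <= snap$n_dead_cumulative))
    expect_equal(snap$n_E_only + snap$n_B_only + snap$n_EB + snap$n_none,
                 snap$n_living)
  }
})

test_that("cell records are chronological and respect the re-entry gap", {
  rho <- 2; L <- 1
  cfg <- sim_config(800, 12, recruitment_hazard = 0.25, refractory_days = rho,
                    cycle_length_days = L,
                    label_windows = default_label_windows())
  sim <- simulate_population(cfg, seed = 5)
  ev_days <- lapply(sim$cells$state_events, function(ev) {
    as.numeric(vapply(strsplit(ev, ":"), `[[`, character(1), 1))
  })
  expect_true(all(vapply(ev_days, function(d) !is.unsorted(d), logical(1))))
  gaps <- unlist(lapply(sim$cells$s_phase_entries, function(s) {
    if (length(s) >= 2) diff(s) else numeric(0)
  }))
  expect_gt(length(gaps), 0)            # re-entry does happen at rho = 2
  expect_true(all(gaps >= rho + L - 1e-9))
  # a disintegration time implies a prior death time
  dis <- !is.na(sim$cells$disintegration_day)
  expect_true(all(!is.na(sim$cells$death_day[dis])))
  expect_true(all(sim$cells$death_day[dis] < sim$cells$disintegration_day[dis]))
})

test_that("daughters inherit all labels of the dividing cell", {
  cfg <- sim_config(2000, 10, recruitment_hazard = 0.15, refractory_days = 0,
                    label_windows = default_label_windows())
  sim <- simulate_population(cfg, seed = 11)
  cells <- sim$cells
  kids <- cells[!is.na(cells$parent_id), ]
  expect_gt(nrow(kids), 0)
  parents <- cells[match(kids$parent_id, cells$cell_id), ]
  # a parent labeled before the division passes the label on
  labeled_before <- !is.na(parents$edu_day) & parents$edu_day <= kids$birth_day
  expect_true(all(kids$edu[labeled_before]))
})

test_that("hand-built 10-cell roster gives (20, 30, 10) percent", {
  cells <- hand_cells(10)
  cells$edu_day <- c(4, 4, NA, NA, NA, 5, NA, NA, NA, NA)
  cells$brdu_day <- c(NA, NA, 8, 8, 8, 9, NA, NA, NA, NA)
  tab <- label_fractions(cells, 10)
  expect_equal(tab$f_E_only, 20)
  expect_equal(tab$f_B_only, 30)
  expect_equal(tab$f_EB, 10)
  expect_equal(tab$f_E, 30)
  expect_equal(tab$f_B, 40)
})

test_that("percent dead uses detectable cells and disintegration empties the well", {
  cfg <- sim_config(600, 10, death_hazard = 0)
  expect_equal(percent_dead(simulate_population(cfg, seed = 2), 10), 0)

  # 90 living + 10 detectable dead -> 10%
  cells <- hand_cells(100)
  cells$death_day[1:10] <- 5
  cells$disintegration_day[1:10] <- 20
  expect_equal(percent_dead(cells, 9), 10)

  # heavy death with fast disintegration: most corpses vanish, so percent
  # dead stays moderate while the living count collapses
  cfg2 <- sim_config(2000, 10, death_hazard = 0.25, disintegration_days = 1)
  sim2 <- simulate_population(cfg2, seed = 3)
  snap <- sim2$snapshots[sim2$snapshots$day == 10, ]
  expect_lt(snap$n_living, 2000 * 0.3)
  expect_lt(percent_dead(sim2, 10), 40)
  n_disintegrated <- sum(!is.na(sim2$cells$disintegration_day) &
                           sim2$cells$disintegration_day <= 10)
  expect_equal(snap$n_dead_cumulative - snap$n_dead_detectable,
               n_disintegrated)
})

test_that("simulation is reproducible for a fixed (config, seed) pair", {
  cfg <- sim_config(300, 10, recruitment_hazard = 0.1, death_hazard = 0.03,
                    label_windows = default_label_windows())
  s1 <- simulate_population(cfg, seed = 99)
  s2 <- simulate_population(cfg, seed = 99)
  expect_identical(s1$cells, s2$cells)
  expect_identical(s1$snapshots, s2$snapshots)
})

test_that("invalid configurations are rejected as configuration errors", {
  expect_config_error(sim_config(100, 10, recruitment_hazard = -0.1))
  expect_config_error(sim_config(100, 10, recruitment_hazard = Inf))
  expect_config_error(sim_config(100, 10, time_step_days = 0.3))
  expect_config_error(sim_config(100, 10, time_step_days = 0.2,
                                 label_windows = list(label_window("EdU", 3, 3.1))))
  expect_config_error(sim_config(100, 10, s_phase_fraction = 0))
  expect_config_error(
    sim_config(100, 10, label_windows = list(label_window("EdU", 3, 6),
                                             label_window("EdU", 7, 9))))
  expect_config_error(sim_config(100, 10,
                                 label_windows = list(label_window("BrdU", 7, 12))))
})

test_that("empty denominators raise undefined-fraction errors", {
  cells <- hand_cells(5, death_day = 1, disintegration_day = 2)
  expect_error(label_fractions(cells, 5), class = "betakin_undefined_fraction")
  expect_error(percent_dead(cells, 5), class = "betakin_undefined_fraction")
})

test_that("simulation output serializes to CSV with a manifest", {
  cfg <- sim_config(50, 4, recruitment_hazard = 0.1,
                    label_windows = list(label_window("EdU", 1, 3)))
  sim <- simulate_population(cfg, seed = 4)
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("cells.csv", "snapshots.csv",
                                               "meta.json")))))
  cells <- read.csv(file.path(dir, "cells.csv"))
  expect_equal(nrow(cells), nrow(sim$cells))
  expect_match(cells$state_events[1], "^0:quiescent")
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  expect_equal(meta$seed, 4)
  expect_equal(meta$command, "simulate")
})
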