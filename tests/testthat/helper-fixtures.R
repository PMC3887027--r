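# Small parameter sets and hand-built cell tables shared across tests.

small_imaging_params <- function(...) {
  imaging_params(image_size_px = c(256, 256), min_center_distance_px = 12,
                 ...)
}

noise_free_params <- function(...) {
  imaging_params(image_size_px = c(256, 256), min_center_distance_px = 12,
                 noise = FALSE, background_gradient = 0, ...)
}

# A cells table in the layout of simulate_population()$cells, built by hand.
# edu/brdu acquisition days and death/disintegration days are given directly.
hand_cells <- function(n, edu_day = NA, brdu_day = NA, death_day = NA,
                       disintegration_day = NA, insulin = TRUE) {
  data.frame(
    cell_id = seq_len(n),
    parent_id = NA_integer_,
    birth_day = 0,
    edu = !is.na(rep_len(edu_day, n)),
    brdu = !is.na(rep_len(brdu_day, n)),
    edu_day = rep_len(edu_day, n),
    brdu_day = rep_len(brdu_day, n),
    insulin_positive = rep_len(insulin, n),
    death_day = rep_len(death_day, n),
    disintegration_day = rep_len(disintegration_day, n),
    n_s_entries = 0L
  )
}

expect_config_error <- function(expr) {
  expect_error(expr, class = "betakin_config_error")
}
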