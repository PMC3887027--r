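# Counting pipeline: background subtraction, segmentation against rendered
# ground truth, annular-ring measurement geometry, classification rules and
# the corrected living-beta-cell arithmetic.

test_that("flat background with no cells subtracts to zero with zero noise scale", {
  img <- matrix(120, 200, 200)
  sb <- subtract_background(img)
  expect_equal(max(abs(sb$corrected)), 0)
  expect_equal(sb$noise_scale, 0)
})

test_that("background window larger than the image is a configuration error", {
  expect_config_error(subtract_background(matrix(1, 40, 40),
                                          segmentation_params(background_window_px = 64)))
})

test_that("a spot on a gradient background keeps its peak after subtraction", {
  p <- imaging_params(image_size_px = c(256, 256), noise = FALSE,
                      background_gradient = 40)
  rw <- render_well(1, p, seed = 13)
  ho <- rw$image$channels$hoechst
  # true signal: rendered image minus the known synthetic background
  ramp <- matrix(rep(seq(0, 1, length.out = 256), each = 256), 256, 256)
  true_sig <- ho - (p$background_level + p$background_gradient * ramp)
  sb <- subtract_background(ho)
  expect_lt(abs(max(sb$corrected) - max(true_sig)) / max(true_sig), 0.05)
})

test_that("well-separated rendered nuclei are segmented exactly", {
  p <- imaging_params(image_size_px = c(800, 800), noise = FALSE,
                      background_gradient = 0, min_center_distance_px = 14)
  rw <- render_well(200, p, seed = 31)
  sb <- subtract_background(rw$image$channels$hoechst)
  lab <- segment_nuclei(sb$corrected, sb$noise_scale)
  expect_equal(max(lab), 200)
  meas <- measure_cells(lab, rw$image)
  sc <- segmentation_score(rw$ground_truth, meas)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)
})

test_that("an empty image yields an empty label map", {
  lab <- segment_nuclei(matrix(0, 64, 64), 0)
  expect_equal(max(lab), 0)
  meas <- measure_cells(lab, well_image(setNames(
    rep(list(matrix(0, 64, 64)), 5),
    c("hoechst", "pi", "insulin", "edu", "brdu"))))
  expect_equal(nrow(meas), 0)
})

test_that("touching nuclei split under the watershed and merge without it", {
  # two spots 1.5 nuclear radii apart: their thresholded footprints join
  # through a thin bridge, one connected component with two distance maxima
  h <- w <- 80; r <- 6; sigma <- r / 2
  img <- numeric(h * w)
  for (c0 in c(36, 36 + 1.5 * r)) {
    p <- betakin:::spot_patch(40, c0, sigma, 1000, h, w)
    img[p$idx] <- img[p$idx] + p$val
  }
  img <- matrix(img, h, w)
  ns <- 65  # threshold 5 * ns cuts near the nominal nuclear boundary
  lab_split <- segment_nuclei(img, ns, segmentation_params(split_touching = TRUE))
  lab_merge <- segment_nuclei(img, ns, segmentation_params(split_touching = FALSE))
  expect_equal(max(lab_split), 2)
  expect_equal(max(lab_merge), 1)
})

test_that("uniform intensity gives equal nuclear and annulus means", {
  lab <- matrix(0L, 64, 64)
  lab[30:36, 30:36] <- 1L
  chans <- setNames(rep(list(matrix(7.5, 64, 64)), 5),
                    c("hoechst", "pi", "insulin", "edu", "brdu"))
  meas <- measure_cells(lab, well_image(chans), annulus_width_px = 3)
  expect_equal(meas$nuc_hoechst, 7.5)
  expect_equal(meas$cyt_insulin, 7.5)
  expect_equal(meas$nuclear_area, 49)
})

test_that("the insulin halo lands in the annulus, not the nucleus", {
  p <- noise_free_params()
  rw <- render_well(1, p, seed = 41)
  res <- count_well_image(rw$image)
  m <- res$measurements
  expect_equal(nrow(m), 1)
  expect_true(m$annulus_ok)
  expect_gt(m$cyt_insulin, m$nuc_insulin)
})

test_that("annuli of adjacent cells are disjoint from all nuclei and each other", {
  p <- imaging_params(image_size_px = c(256, 256), noise = FALSE,
                      background_gradient = 0, min_center_distance_px = 9)
  rw <- render_well(60, p, seed = 51)
  sb <- subtract_background(rw$image$channels$hoechst)
  lab <- segment_nuclei(sb$corrected, sb$noise_scale)
  ring <- betakin:::annulus_labels(lab, 3)
  expect_true(all(ring[lab > 0] == 0))         # rings never cover nuclei
  # every ring pixel belongs to exactly one cell and rings stay near it
  ids <- sort(unique(ring[ring > 0]))
  expect_true(all(ids %in% seq_len(max(lab))))
  meas <- measure_cells(lab, rw$image)
  expect_true(all(meas$annulus_area >= 1))
})

test_that("classification uses strict thresholds and nuclear/cytoplasmic channels", {
  meas <- data.frame(label_id = 1:3,
                     nuc_pi = c(0, 10, 20), cyt_insulin = c(5, 5, 5),
                     nuc_edu = c(0, 0, 0), nuc_brdu = c(0, 0, 0))
  flags <- classify_cells(meas, segmentation_params(
    thresholds = list(pi = 10, insulin = 5, edu = 1, brdu = 1)))
  # value exactly at the threshold is negative (strict >)
  expect_equal(flags$pi, c(FALSE, FALSE, TRUE))
  expect_equal(flags$insulin, c(FALSE, FALSE, FALSE))
  expect_equal(flags$edu, rep(FALSE, 3))
})

test_that("all-dark wells classify all-negative through the noise fallback", {
  meas <- data.frame(label_id = 1:20, nuc_pi = 0, cyt_insulin = 0,
                     nuc_edu = 0, nuc_brdu = 0)
  w <- capture_warnings(
    flags <- classify_cells(meas, segmentation_params(),
                            noise_scales = c(pi = 0, insulin = 0, edu = 0,
                                             brdu = 0, hoechst = 0)))
  expect_length(w, 4)                      # one fallback per marker channel
  expect_true(all(grepl("unimodal", w)))
  expect_false(any(flags$pi | flags$insulin | flags$edu | flags$brdu))
})

test_that("rendered wells classify within tolerance of ground truth", {
  set.seed(61)
  n <- 400
  cells <- data.frame(dead = runif(n) < 0.10,
                      insulin_positive = runif(n) < 0.9,
                      edu_positive = runif(n) < 0.15,
                      brdu_positive = runif(n) < 0.10)
  p <- imaging_params(image_size_px = c(900, 900))
  rw <- render_well(cells, p, seed = 62)
  res <- count_well_image(rw$image)
  ct <- res$counts
  expect_equal(ct$n_total_ho, n)
  # PI+ fraction within 2 percentage points of truth
  expect_lt(abs(100 * ct$n_pi_pos / n - 100 * mean(cells$dead)), 2)
  expect_lt(abs(ct$f_insulin_pos - mean(cells$insulin_positive)), 0.03)
  truth_beta <- sum(!cells$dead & cells$insulin_positive)
  expect_lt(abs(ct$n_living_beta - truth_beta) / truth_beta, 0.03)
})

test_that("the corrected living-beta-cell count follows its defining formula", {
  flags <- data.frame(label_id = 1:1000,
                      pi = rep(c(TRUE, FALSE), c(100, 900)),
                      insulin = rep(c(FALSE, TRUE, FALSE), c(100, 810, 90)),
                      edu = FALSE, brdu = FALSE)
  ct <- count_well(flags)
  expect_equal(ct$n_total_ho, 1000)
  expect_equal(ct$n_living, 900)
  expect_equal(ct$f_insulin_pos, 0.9)
  expect_equal(ct$n_living_beta, 810)

  # no dead cells, all insulin-positive: living beta equals the total
  flags2 <- data.frame(label_id = 1:50, pi = FALSE, insulin = TRUE,
                       edu = FALSE, brdu = FALSE)
  expect_equal(count_well(flags2)$n_living_beta, 50)

  # label-count consistency: E + B - EB never exceeds the living count
  flags3 <- data.frame(label_id = 1:30, pi = rep(c(TRUE, FALSE), c(5, 25)),
                       insulin = TRUE,
                       edu = rep(c(TRUE, FALSE), 15),
                       brdu = rep(c(TRUE, FALSE), c(10, 20)))
  ct3 <- count_well(flags3)
  expect_lte(ct3$n_edu_pos + ct3$n_brdu_pos - ct3$n_double_pos, ct3$n_living)

  empty <- count_well(flags3[0, ])
  expect_true(empty$undefined)
  expect_equal(empty$n_total_ho, 0)
  expect_true(is.na(empty$f_insulin_pos))
})

test_that("the linearity fit reproduces the long-hand adjusted r-squared", {
  # identity data: perfect fit
  perfect <- linearity_fit(c(100, 500, 1000, 2000), c(100, 500, 1000, 2000))
  expect_equal(perfect$slope, 1)
  expect_equal(perfect$intercept, 0)
  expect_equal(perfect$adjusted_r_squared, 1)

  # 5-point hand dataset, long-hand computation
  x <- c(100, 250, 500, 750, 1000)
  y <- c(110, 240, 520, 730, 990)
  fit <- linearity_fit(x, y)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  r2 <- 1 - sum((y - a - b * x)^2) / sum((y - mean(y))^2)
  expect_equal(fit$slope, b)
  expect_equal(fit$r_squared, r2)
  expect_equal(fit$adjusted_r_squared, 1 - (1 - r2) * 4 / 3)

  expect_error(linearity_fit(c(1, 2), c(1, 2)), class = "betakin_data_error")
  expect_error(linearity_validation(c(100, 100, 100)),
               class = "betakin_data_error")
})
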