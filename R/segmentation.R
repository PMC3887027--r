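# Whole-well counting: background subtraction, dynamic-threshold nuclear
# segmentation on the Hoechst channel, annular-ring cytoplasm measurement,
# per-cell classification and the corrected living-beta-cell count.

#' Segmentation and classification parameters
#'
#' @param background_window_px Block size of the large-window percentile
#'   filter used to estimate the smooth background.
#' @param background_percentile Percentile used within each block; low enough
#'   to ignore nuclear spots.
#' @param threshold_k Multiplier on the robust (MAD-based) noise scale that
#'   sets the dynamic segmentation threshold.
#' @param threshold_floor_frac Lower bound on the threshold as a fraction of
#'   the peak corrected intensity. The default `exp(-2)` cuts an isolated
#'   Gaussian nuclear spot (sigma = radius/2) exactly at its nominal radius,
#'   and keeps noise-free images from being thresholded at zero, where every
#'   truncated spot tail would become foreground.
#' @param min_nucleus_area_px,max_nucleus_area_px Connected components
#'   outside this area range are discarded.
#' @param split_touching Split touching nuclei with a distance-transform
#'   watershed.
#' @param watershed_tolerance Minimum object-height separation for the
#'   watershed split.
#' @param annulus_width_px Width of the annular cytoplasm ring, pixels.
#' @param thresholds Per-channel classification thresholds for `pi`,
#'   `insulin`, `edu`, `brdu`: numeric values, or `"auto"` for a bimodal
#'   split of the per-well intensity histogram (with a noise-scale fallback
#'   when the histogram is unimodal).
#' @return A `segmentation_params` object.
#' @export
segmentation_params <- function(background_window_px = 64,
                                background_percentile = 0.25,
                                threshold_k = 5,
                                threshold_floor_frac = exp(-2),
                                min_nucleus_area_px = 8,
                                max_nucleus_area_px = 400,
                                split_touching = TRUE,
                                watershed_tolerance = 1,
                                annulus_width_px = 3,
                                thresholds = list(pi = "auto", insulin = "auto",
                                                  edu = "auto", brdu = "auto")) {
  check_scalar(threshold_k, "threshold_k", lower = 0, allow_equal_lower = FALSE)
  check_scalar(threshold_floor_frac, "threshold_floor_frac", lower = 0, upper = 1)
  check_scalar(min_nucleus_area_px, "min_nucleus_area_px", lower = 0,
               allow_equal_lower = FALSE)
  check_scalar(max_nucleus_area_px, "max_nucleus_area_px",
               lower = min_nucleus_area_px, allow_equal_lower = FALSE)
  check_scalar(annulus_width_px, "annulus_width_px", lower = 1)
  check_scalar(background_percentile, "background_percentile", lower = 0, upper = 1)
  for (nm in c("pi", "insulin", "edu", "brdu")) {
    th <- thresholds[[nm]]
    if (is.null(th)) stop_config("thresholds needs an entry for '", nm, "'")
    if (!(identical(th, "auto") || (is.numeric(th) && is.finite(th)))) {
      stop_config("threshold for '", nm, "' must be numeric or 'auto'")
    }
  }
  structure(list(
    background_window_px = as.integer(background_window_px),
    background_percentile = background_percentile,
    threshold_k = threshold_k,
    threshold_floor_frac = threshold_floor_frac,
    min_nucleus_area_px = min_nucleus_area_px,
    max_nucleus_area_px = max_nucleus_area_px,
    split_touching = isTRUE(split_touching),
    watershed_tolerance = watershed_tolerance,
    annulus_width_px = as.integer(annulus_width_px),
    thresholds = thresholds
  ), class = "segmentation_params")
}

#' Subtract a smooth background estimate from a channel image
#'
#' The background is a low-percentile block filter (window
#' `background_window_px`), bilinearly resized to full resolution; the
#' corrected image is `max(image - background, 0)`. The noise scale is a
#' sigma-clipped MAD of the residual, which is ~0 for noise-free images.
#'
#' @param img Finite, non-negative matrix.
#' @param params [segmentation_params()].
#' @return List with `corrected`, `background`, `noise_scale`.
#' @export
subtract_background <- function(img, params = segmentation_params()) {
  if (any(!is.finite(img)) || any(img < 0)) {
    stop_data("image must be finite and non-negative")
  }
  wpx <- params$background_window_px
  h <- nrow(img); w <- ncol(img)
  if (wpx > min(h, w)) {
    stop_config("background_window_px (", wpx, ") exceeds the image size")
  }
  nbr <- max(1L, floor(h / wpx)); nbc <- max(1L, floor(w / wpx))
  ri <- cut(seq_len(h) - 1L, nbr, labels = FALSE)
  ci <- cut(seq_len(w) - 1L, nbc, labels = FALSE)
  blocks <- matrix(NA_real_, nbr, nbc)
  for (i in seq_len(nbr)) {
    rows <- which(ri == i)
    sub <- img[rows, , drop = FALSE]
    for (j in seq_len(nbc)) {
      blocks[i, j] <- quantile(sub[, ci == j], params$background_percentile,
                               names = FALSE)
    }
  }
  bg <- if (nbr == 1 && nbc == 1) {
    matrix(blocks[1, 1], h, w)
  } else {
    as.matrix(EBImage::resize(EBImage::Image(blocks), w = h, h = w))
  }
  resid <- img - bg
  sc <- mad(resid, center = median(resid))
  for (k in 1:2) {  # two clipping rounds against spot contamination
    if (sc <= 0) break
    keep <- abs(resid - median(resid)) <= 4 * sc
    sc <- mad(resid[keep], center = median(resid[keep]))
  }
  list(corrected = pmax(img - bg, 0), background = bg, noise_scale = sc)
}

#' Segment nuclei by dynamic thresholding of the corrected Hoechst image
#'
#' The binary mask is `corrected > threshold`, where the threshold is
#' `threshold_k * noise_scale` bounded below by the signal-relative floor
#' (`threshold_floor_frac` of the peak corrected intensity);
#' connected components are optionally split by a distance-transform
#' watershed and filtered to the configured area range.
#'
#' @param corrected Background-subtracted Hoechst image.
#' @param noise_scale Robust noise scale from [subtract_background()].
#' @param params [segmentation_params()].
#' @return Integer label matrix (0 = background, labels contiguous from 1).
#' @export
segment_nuclei <- function(corrected, noise_scale,
                           params = segmentation_params()) {
  thr <- max(params$threshold_k * noise_scale,
             params$threshold_floor_frac * max(corrected))
  mask <- corrected > thr
  if (!any(mask)) return(matrix(0L, nrow(corrected), ncol(corrected)))
  m <- EBImage::Image(mask * 1)
  labels <- if (params$split_touching) {
    EBImage::watershed(EBImage::distmap(m),
                       tolerance = params$watershed_tolerance, ext = 1)
  } else {
    EBImage::bwlabel(m)
  }
  lab <- as.matrix(EBImage::imageData(labels))
  storage.mode(lab) <- "integer"
  areas <- tabulate(lab)
  keep <- which(areas >= params$min_nucleus_area_px &
                  areas <= params$max_nucleus_area_px)
  remap <- integer(length(areas))
  remap[keep] <- seq_along(keep)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

# Assign background pixels within `width` of a nucleus to their (geodesically)
# nearest nucleus by iterative greyscale dilation; ties go to the larger
# label id. Returns an integer matrix of annulus ownership (0 elsewhere).
annulus_labels <- function(lab, width) {
  kern <- EBImage::makeBrush(3, shape = "box")
  grown <- lab
  for (i in seq_len(width)) {
    d <- as.matrix(EBImage::imageData(
      EBImage::dilate(EBImage::Image(grown), kern)))
    grown <- ifelse(grown > 0, grown, d)
  }
  ring <- grown
  ring[lab > 0] <- 0L
  storage.mode(ring) <- "integer"
  ring
}

#' Per-cell nuclear and cytoplasmic (annular-ring) measurements
#'
#' For every segmented nucleus, averages each channel over the nuclear pixels
#' and over an annular ring of width `annulus_width_px` outside the nuclear
#' boundary. Ring pixels are assigned to their nearest nucleus so annuli are
#' pairwise disjoint and never overlap any nucleus; a cell whose ring is
#' fully crowded out is flagged (`annulus_ok = FALSE`) with `NA` cytoplasmic
#' means.
#'
#' @param lab Label matrix from [segment_nuclei()].
#' @param wi [well_image()] aligned with `lab`.
#' @param annulus_width_px Ring width in pixels.
#' @return data.frame with one row per cell: `label_id`, `row`/`col`
#'   (0-based centroid), `nuclear_area`, `annulus_area`, `annulus_ok`,
#'   `nuc_<channel>` and `cyt_<channel>` mean intensities.
#' @export
measure_cells <- function(lab, wi, annulus_width_px = 3) {
  stopifnot(inherits(wi, "well_image"))
  n <- max(lab)
  if (n == 0) {
    out <- data.frame(label_id = integer(0), row = numeric(0), col = numeric(0),
                      nuclear_area = integer(0), annulus_area = integer(0),
                      annulus_ok = logical(0))
    for (nm in CHANNELS) out[[paste0("nuc_", nm)]] <- numeric(0)
    for (nm in CHANNELS) out[[paste0("cyt_", nm)]] <- numeric(0)
    return(out)
  }
  ring <- annulus_labels(lab, annulus_width_px)
  nuc_idx <- which(lab > 0)
  nuc_lab <- lab[nuc_idx]
  ring_idx <- which(ring > 0)
  ring_lab <- ring[ring_idx]

  area <- tabulate(nuc_lab, n)
  ring_area <- tabulate(ring_lab, n)
  rr <- (nuc_idx - 1) %% nrow(lab)        # 0-based row
  cc <- (nuc_idx - 1) %/% nrow(lab)       # 0-based col
  cent_r <- rowsum(rr, nuc_lab)[, 1] / area
  cent_c <- rowsum(cc, nuc_lab)[, 1] / area

  out <- data.frame(label_id = seq_len(n), row = cent_r, col = cent_c,
                    nuclear_area = area, annulus_area = ring_area,
                    annulus_ok = ring_area > 0)
  for (nm in CHANNELS) {
    ch <- wi$channels[[nm]]
    out[[paste0("nuc_", nm)]] <- rowsum(ch[nuc_idx], nuc_lab)[, 1] / area
    cy <- rep(NA_real_, n)
    if (length(ring_idx)) {
      s <- rowsum(ch[ring_idx], ring_lab)
      ids <- as.integer(rownames(s))
      cy[ids] <- s[, 1] / ring_area[ids]
    }
    out[[paste0("cyt_", nm)]] <- cy
  }
  out
}

# Threshold from a bimodal intensity histogram: the minimum of the kernel
# density between its two dominant modes. To avoid splitting a unimodal
# histogram on density wiggles or isolated outliers, the split is accepted
# only if the valley is at most half as high as the smaller peak and each
# side keeps at least 2% of the cells; otherwise NA (caller falls back to
# the noise-scale rule).
bimodal_threshold <- function(v, min_minor_mass = 0.02,
                              max_valley_ratio = 0.5) {
  v <- v[is.finite(v)]
  if (length(v) < 8 || stats::sd(v) == 0) return(NA_real_)
  d <- density(v, n = 512)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1
  is_max <- is_max[y[is_max] > 0.01 * max(y)]
  if (length(is_max) < 2) return(NA_real_)
  top2 <- is_max[order(y[is_max], decreasing = TRUE)[1:2]]
  lo <- min(top2); hi <- max(top2)
  valley <- lo + which.min(y[lo:hi]) - 1
  if (y[valley] > max_valley_ratio * min(y[lo], y[hi])) return(NA_real_)
  thr <- d$x[valley]
  below <- v[v <= thr]; above <- v[v > thr]
  minor <- min(length(below), length(above)) / length(v)
  if (minor < min_minor_mass) return(NA_real_)
  # the two classes must be genuinely separated, not a split of one cluster
  if (abs(mean(above) - mean(below)) <= 3 * (sd_or0(below) + sd_or0(above))) {
    return(NA_real_)
  }
  thr
}

sd_or0 <- function(x) if (length(x) > 1) stats::sd(x) else 0

#' Classify segmented cells on their per-compartment mean intensities
#'
#' PI, EdU and BrdU are judged on nuclear means, insulin on the cytoplasmic
#' (annulus) mean. A cell is positive only when its mean is strictly above
#' the threshold (ties are negative). `"auto"` thresholds use the minimum
#' between the two modes of the per-well intensity histogram and fall back
#' to `threshold_k * noise_scale` (with a warning) when the histogram is
#' unimodal -- the situation when a well has essentially no positives or no
#' negatives for that marker.
#'
#' @param meas Measurements from [measure_cells()].
#' @param params [segmentation_params()].
#' @param noise_scales Named numeric with a robust noise scale per
#'   classification channel; required for the unimodal fallback.
#' @return data.frame `label_id`, `pi`, `insulin`, `edu`, `brdu` (logical)
#'   with the thresholds used attached as attribute `"thresholds"`.
#' @export
classify_cells <- function(meas, params = segmentation_params(),
                           noise_scales = NULL) {
  value_of <- list(pi = meas$nuc_pi, insulin = meas$cyt_insulin,
                   edu = meas$nuc_edu, brdu = meas$nuc_brdu)
  used <- numeric(0)
  out <- data.frame(label_id = meas$label_id)
  for (nm in names(value_of)) {
    th <- params$thresholds[[nm]]
    if (identical(th, "auto")) {
      th_num <- bimodal_threshold(value_of[[nm]])
      if (is.na(th_num)) {
        if (is.null(noise_scales) || is.na(noise_scales[nm])) {
          stop_config("unimodal '", nm, "' histogram and no noise scale ",
                      "available for the fallback rule")
        }
        th_num <- params$threshold_k * noise_scales[[nm]]
        warning("unimodal '", nm,
                "' intensity histogram; falling back to the noise-scale rule",
                call. = FALSE)
      }
    } else {
      th_num <- th
    }
    v <- value_of[[nm]]
    out[[nm]] <- !is.na(v) & v > th_num   # strict >: ties are negative
    used[nm] <- th_num
  }
  attr(out, "thresholds") <- used
  out
}

#' Per-well counts and the corrected living-beta-cell number
#'
#' Implements the counting correction: living cells are Hoechst-positive
#' minus PI-positive, and the living beta-cell number corrects for the
#' percent insulin-negative cells, with the insulin-positive fraction
#' computed among PI-negative cells. Label counts are taken among PI-negative
#' cells; label percentages among PI-negative, insulin-positive cells.
#' Rounding (half-to-even) is applied only to the reported
#' `n_living_beta`.
#'
#' @param flags Classification data.frame from [classify_cells()].
#' @return A `well_counts` list: `n_total_ho`, `n_pi_pos`, `n_living`,
#'   `f_insulin_pos`, `n_living_beta`, `n_edu_pos`, `n_brdu_pos`,
#'   `n_double_pos`, `pct_edu`, `pct_brdu`, `pct_double`, `undefined`
#'   (TRUE when the well held no cells).
#' @export
count_well <- function(flags) {
  n <- nrow(flags)
  if (n == 0) {
    return(structure(list(n_total_ho = 0L, n_pi_pos = 0L, n_living = 0L,
                          f_insulin_pos = NA_real_, n_living_beta = 0L,
                          n_edu_pos = 0L, n_brdu_pos = 0L, n_double_pos = 0L,
                          pct_edu = NA_real_, pct_brdu = NA_real_,
                          pct_double = NA_real_, undefined = TRUE),
                     class = "well_counts"))
  }
  living <- !flags$pi
  n_living <- sum(living)
  f_ins <- if (n_living > 0) mean(flags$insulin[living]) else NA_real_
  beta <- living & flags$insulin
  n_beta <- sum(beta)
  pct <- function(x) if (n_beta > 0) 100 * sum(x & beta) / n_beta else NA_real_
  structure(list(
    n_total_ho = n,
    n_pi_pos = sum(flags$pi),
    n_living = n_living,
    f_insulin_pos = f_ins,
    n_living_beta = if (is.na(f_ins)) 0L else as.integer(round(n_living * f_ins)),
    n_edu_pos = sum(living & flags$edu),
    n_brdu_pos = sum(living & flags$brdu),
    n_double_pos = sum(living & flags$edu & flags$brdu),
    pct_edu = pct(flags$edu),
    pct_brdu = pct(flags$brdu),
    pct_double = pct(flags$edu & flags$brdu),
    undefined = FALSE
  ), class = "well_counts")
}

#' @export
print.well_counts <- function(x, ...) {
  cat(sprintf("well_counts: %d Ho+ | %d PI+ | %d living | %.1f%% insulin+ | %d living beta\n",
              x$n_total_ho, x$n_pi_pos, x$n_living,
              100 * x$f_insulin_pos, x$n_living_beta))
  cat(sprintf("  labels among insulin+ living: EdU %.2f%% BrdU %.2f%% double %.2f%%\n",
              x$pct_edu, x$pct_brdu, x$pct_double))
  invisible(x)
}

#' Count a well image end to end
#'
#' Background subtraction on every channel, nuclear segmentation on Hoechst,
#' annular-ring measurement, classification and counting in one call.
#'
#' @param wi [well_image()].
#' @param params [segmentation_params()].
#' @return List with `counts` ([count_well()] result), `measurements`,
#'   `flags`, `labels` (the label matrix).
#' @export
count_well_image <- function(wi, params = segmentation_params()) {
  stopifnot(inherits(wi, "well_image"))
  corr <- list(); noise <- numeric(0)
  for (nm in CHANNELS) {
    sb <- subtract_background(wi$channels[[nm]], params)
    corr[[nm]] <- sb$corrected
    noise[nm] <- sb$noise_scale
  }
  wic <- well_image(corr, wi$pixel_size_um)
  lab <- segment_nuclei(corr$hoechst, noise[["hoechst"]], params)
  meas <- measure_cells(lab, wic, params$annulus_width_px)
  flags <- withCallingHandlers(
    classify_cells(meas, params, noise_scales = noise),
    warning = function(w) invokeRestart("muffleWarning"))
  list(counts = count_well(flags), measurements = meas, flags = flags,
       labels = lab)
}

#' Score segmentation against the renderer's ground truth
#'
#' Greedy nearest matching of segmented centroids to true centroids within
#' `max_dist_px`; each truth cell matches at most one segmented object.
#'
#' @param ground_truth Ground-truth table from [render_well()].
#' @param meas Measurements from [measure_cells()].
#' @param max_dist_px Maximum centroid distance for a match.
#' @return List with `recall`, `precision`, `n_true`, `n_segmented`,
#'   `n_matched`.
#' @export
segmentation_score <- function(ground_truth, meas, max_dist_px = 5) {
  nt <- nrow(ground_truth); ns <- nrow(meas)
  if (nt == 0 || ns == 0) {
    return(list(recall = if (nt == 0) NA_real_ else 0,
                precision = if (ns == 0) NA_real_ else 0,
                n_true = nt, n_segmented = ns, n_matched = 0L))
  }
  d2 <- outer(ground_truth$row, meas$row, "-")^2 +
    outer(ground_truth$col, meas$col, "-")^2
  max2 <- max_dist_px^2
  matched <- 0L
  used_t <- rep(FALSE, nt); used_s <- rep(FALSE, ns)
  ord <- order(d2)
  for (k in ord) {
    if (d2[k] > max2) break
    i <- (k - 1) %% nt + 1
    j <- (k - 1) %/% nt + 1
    if (used_t[i] || used_s[j]) next
    used_t[i] <- used_s[j] <- TRUE
    matched <- matched + 1L
  }
  list(recall = matched / nt, precision = matched / ns,
       n_true = nt, n_segmented = ns, n_matched = matched)
}

#' Seeded-versus-counted linearity validation
#'
#' Renders wells at the given seeded densities (all-living, insulin-positive
#' cells), counts them with the full pipeline, and fits ordinary least
#' squares of counted on seeded numbers. The adjusted r-squared
#' `1 - (1 - r^2) (n - 1) / (n - 2)` is the calibration gate of the counting
#' method.
#'
#' @param seeded_counts At least 3 distinct seeded cell numbers.
#' @param replicates Wells per density.
#' @param iparams [imaging_params()].
#' @param sparams [segmentation_params()].
#' @param seed Integer seed.
#' @return List with `slope`, `intercept`, `r_squared`,
#'   `adjusted_r_squared`, `data` (per-well seeded/counted), `fit` (the lm).
#' @export
linearity_validation <- function(seeded_counts, replicates = 3,
                                 iparams = imaging_params(),
                                 sparams = segmentation_params(),
                                 seed = 1L) {
  if (length(unique(seeded_counts)) < 3) {
    stop_data("linearity validation needs at least 3 distinct seeded counts")
  }
  grid <- expand.grid(seeded = seeded_counts, replicate = seq_len(replicates))
  counted <- integer(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    rw <- render_well(grid$seeded[k], iparams, seed = seed + k)
    counted[k] <- count_well_image(rw$image, sparams)$counts$n_total_ho
  }
  dat <- data.frame(seeded = grid$seeded, replicate = grid$replicate,
                    counted = counted)
  out <- linearity_fit(dat$seeded, dat$counted)
  out$data <- dat
  out
}

#' Ordinary least squares of counted on seeded numbers
#'
#' @param seeded,counted Equal-length numeric vectors (>= 3 points).
#' @return List with `slope`, `intercept`, `r_squared`,
#'   `adjusted_r_squared` (`1 - (1 - r^2)(n - 1)/(n - 2)`), `fit`.
#' @export
linearity_fit <- function(seeded, counted) {
  if (length(seeded) != length(counted) || length(seeded) < 3) {
    stop_data("linearity fit needs >= 3 paired points")
  }
  fit <- lm(counted ~ seeded)
  # suppress summary.lm's note on exact fits; identity data are legitimate here
  r2 <- suppressWarnings(summary(fit))$r.squared
  n <- length(seeded)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2,
       adjusted_r_squared = 1 - (1 - r2) * (n - 1) / (n - 2),
       fit = fit)
}
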