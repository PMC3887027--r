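# Synthetic whole-well fluorescence renderer.
#
# Each cell contributes a truncated-Gaussian nuclear spot (sigma = radius/2,
# cut at 3 sigma) to the Hoechst channel; PI colocalizes with dead nuclei,
# EdU/BrdU are nuclear in flagged cells, and insulin is a flat cytoplasmic
# halo (annulus outside the nucleus). Noise, when enabled, is Poisson on the
# accumulated photon signal plus additive Gaussian read noise, rounded to
# integer detector units. Coordinates are 0-based (row, col) with pixel
# centers at integers, everywhere including the ground-truth table.

CHANNELS <- c("hoechst", "pi", "insulin", "edu", "brdu")

#' Parameters of the synthetic well renderer
#'
#' Optics are not modeled; sizes and intensities are in pixels and arbitrary
#' detector units and the defaults are deliberately generic (no particular
#' instrument is emulated).
#'
#' @param image_size_px `(height, width)` in pixels.
#' @param pixel_size_um Physical pixel size, microns.
#' @param nucleus_radius_px Mean nuclear radius, pixels.
#' @param nucleus_radius_sd_px Spread of nuclear radii.
#' @param peak_intensity Named vector of per-channel peak intensities
#'   (detector units) for `hoechst`, `pi`, `insulin`, `edu`, `brdu`.
#' @param background_level Flat background, detector units.
#' @param background_gradient Amplitude of a left-to-right linear background
#'   ramp added on top of `background_level`.
#' @param noise Logical; `FALSE` gives the exact noise-free signal used by
#'   oracle tests.
#' @param read_noise_sd Gaussian read noise sigma, detector units.
#' @param min_center_distance_px Hard-core minimum distance between nuclear
#'   centers during placement.
#' @param aggregation_above Cell count beyond which the hard-core constraint
#'   is dropped and centers are placed uniformly, emulating the aggregated
#'   regime in which segmentation of individual cells degrades.
#' @param insulin_halo_width_px Width of the cytoplasmic insulin annulus.
#' @param rng_seed Default seed for [render_well()].
#' @return An `imaging_params` object.
#' @export
imaging_params <- function(image_size_px = c(1500, 1500),
                           pixel_size_um = 1.0,
                           nucleus_radius_px = 4,
                           nucleus_radius_sd_px = 0.3,
                           peak_intensity = c(hoechst = 800, pi = 600,
                                              insulin = 500, edu = 600,
                                              brdu = 600),
                           background_level = 100,
                           background_gradient = 20,
                           noise = TRUE,
                           read_noise_sd = 5,
                           min_center_distance_px = 9,
                           aggregation_above = 12000,
                           insulin_halo_width_px = 4,
                           rng_seed = 1L) {
  stopifnot(length(image_size_px) == 2, all(image_size_px >= 16))
  check_scalar(nucleus_radius_px, "nucleus_radius_px", lower = 0,
               allow_equal_lower = FALSE)
  check_scalar(nucleus_radius_sd_px, "nucleus_radius_sd_px", lower = 0)
  if (!all(CHANNELS %in% names(peak_intensity))) {
    stop_config("peak_intensity needs entries for: ",
                paste(CHANNELS, collapse = ", "))
  }
  if (any(peak_intensity < 0)) stop_config("peak intensities must be >= 0")
  check_scalar(background_level, "background_level", lower = 0)
  check_scalar(read_noise_sd, "read_noise_sd", lower = 0)
  check_scalar(min_center_distance_px, "min_center_distance_px", lower = 0)
  check_scalar(insulin_halo_width_px, "insulin_halo_width_px", lower = 1)
  structure(list(
    image_size_px = as.integer(image_size_px),
    pixel_size_um = pixel_size_um,
    nucleus_radius_px = nucleus_radius_px,
    nucleus_radius_sd_px = nucleus_radius_sd_px,
    peak_intensity = peak_intensity[CHANNELS],
    background_level = background_level,
    background_gradient = background_gradient,
    noise = noise,
    read_noise_sd = read_noise_sd,
    min_center_distance_px = min_center_distance_px,
    aggregation_above = aggregation_above,
    insulin_halo_width_px = insulin_halo_width_px,
    rng_seed = as.integer(rng_seed)
  ), class = "imaging_params")
}

#' Multichannel well image container
#'
#' @param channels Named list of equal-dimension, finite, non-negative
#'   matrices for `hoechst`, `pi`, `insulin`, `edu`, `brdu`.
#' @param pixel_size_um Pixel size, microns.
#' @return A `well_image` object.
#' @export
well_image <- function(channels, pixel_size_um = 1.0) {
  if (!all(CHANNELS %in% names(channels))) {
    stop_data("well_image needs channels: ", paste(CHANNELS, collapse = ", "))
  }
  channels <- channels[CHANNELS]
  d <- dim(channels[[1]])
  for (nm in CHANNELS) {
    ch <- channels[[nm]]
    if (!is.matrix(ch) || !identical(dim(ch), d)) {
      stop_data("channel '", nm, "' has mismatched dimensions")
    }
    if (any(!is.finite(ch)) || any(ch < 0)) {
      stop_data("channel '", nm, "' has non-finite or negative intensities")
    }
  }
  structure(list(channels = channels, pixel_size_um = pixel_size_um),
            class = "well_image")
}

#' @export
print.well_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("well_image:", d[1], "x", d[2], "px,", x$pixel_size_um, "um/px,",
      length(x$channels), "channels\n")
  invisible(x)
}

# Sequential hard-core placement on a bucket grid (<=1 point per bucket).
place_centers <- function(n, height, width, min_dist, margin, seed_attempts = 200L) {
  lo_r <- margin; hi_r <- height - 1 - margin
  lo_c <- margin; hi_c <- width - 1 - margin
  if (hi_r <= lo_r || hi_c <= lo_c) {
    stop_config("image_size_px too small for the rendered spot size")
  }
  if (n == 0) return(cbind(row = numeric(0), col = numeric(0)))
  if (min_dist <= 0) {
    return(cbind(row = runif(n, lo_r, hi_r), col = runif(n, lo_c, hi_c)))
  }
  cell <- min_dist / sqrt(2)
  gr <- ceiling(height / cell); gc <- ceiling(width / cell)
  occ <- matrix(0L, gr, gc)
  rows <- cols <- numeric(n)
  md2 <- min_dist^2
  for (i in seq_len(n)) {
    ok <- FALSE
    for (a in seq_len(seed_attempts)) {
      r <- runif(1, lo_r, hi_r); c <- runif(1, lo_c, hi_c)
      gi <- floor(r / cell) + 1; gj <- floor(c / cell) + 1
      i0 <- max(1, gi - 2); i1 <- min(gr, gi + 2)
      j0 <- max(1, gj - 2); j1 <- min(gc, gj + 2)
      nb <- occ[i0:i1, j0:j1]
      nb <- nb[nb > 0L]
      if (!length(nb) ||
          all((rows[nb] - r)^2 + (cols[nb] - c)^2 >= md2)) {
        rows[i] <- r; cols[i] <- c; occ[gi, gj] <- i
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop_config("could not place ", n, " cells at min_center_distance_px = ",
                  min_dist, " in a ", height, "x", width,
                  " image; min_center_distance_px is the limiting parameter")
    }
  }
  cbind(row = rows, col = cols)
}

# Patch of a truncated Gaussian spot: linear (column-major) pixel indices
# and intensity values, clipped to the image.
spot_patch <- function(r0, c0, sigma, peak, h, w) {
  ext <- ceiling(3 * sigma)
  rr <- max(0, floor(r0 - ext)):min(h - 1, ceiling(r0 + ext))
  cc <- max(0, floor(c0 - ext)):min(w - 1, ceiling(c0 + ext))
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  k <- peak * exp(-d2 / (2 * sigma^2))
  k[d2 > (3 * sigma)^2] <- 0
  keep <- k > 0
  idx <- outer(rr + 1, (cc) * h, "+")   # 1-based linear index
  list(idx = idx[keep], val = k[keep])
}

halo_patch <- function(r0, c0, r_in, width, peak, h, w) {
  ext <- ceiling(r_in + width)
  rr <- max(0, floor(r0 - ext)):min(h - 1, ceiling(r0 + ext))
  cc <- max(0, floor(c0 - ext)):min(w - 1, ceiling(c0 + ext))
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  keep <- d2 > r_in^2 & d2 <= (r_in + width)^2
  idx <- outer(rr + 1, (cc) * h, "+")
  list(idx = idx[keep], val = rep(peak, sum(keep)))
}

#' Render a synthetic multichannel well image
#'
#' @param cells data.frame of per-cell phenotype flags with logical columns
#'   `dead`, `insulin_positive`, `edu_positive`, `brdu_positive` (as produced
#'   by [cell_roster()]), or a single count for an all-living, all
#'   insulin-positive well.
#' @param params [imaging_params()].
#' @param seed Integer seed; defaults to `params$rng_seed`.
#' @return List with `image` (a [well_image()]) and `ground_truth`
#'   (data.frame: `cell_id`, `row`, `col` 0-based centroid,
#'   `nucleus_radius_px`, `dead`, `insulin_positive`, `edu_positive`,
#'   `brdu_positive`; rows match the input order).
#' @export
render_well <- function(cells, params = imaging_params(),
                        seed = params$rng_seed) {
  stopifnot(inherits(params, "imaging_params"))
  if (is.numeric(cells) && length(cells) == 1L) {
    n <- as.integer(cells)
    cells <- data.frame(dead = logical(n),
                        insulin_positive = rep(TRUE, n),
                        edu_positive = logical(n), brdu_positive = logical(n))
  }
  need <- c("dead", "insulin_positive", "edu_positive", "brdu_positive")
  if (!all(need %in% names(cells))) {
    stop_config("cells needs logical columns: ", paste(need, collapse = ", "))
  }
  n <- nrow(cells)
  with_local_seed(seed, {
    h <- params$image_size_px[1]; w <- params$image_size_px[2]
    radii <- pmax(1, rnorm(n, params$nucleus_radius_px,
                           params$nucleus_radius_sd_px))
    margin <- if (n > 0) {
      ceiling(max(1.5 * radii, radii + params$insulin_halo_width_px))
    } else 0
    min_dist <- if (n > params$aggregation_above) 0 else params$min_center_distance_px
    xy <- place_centers(n, h, w, min_dist, margin)

    pk <- params$peak_intensity
    # accumulate spots into flat vectors (in-place subassignment, no copies)
    acc_ho <- acc_pi <- acc_ins <- acc_edu <- acc_brdu <- numeric(h * w)
    for (i in seq_len(n)) {
      r0 <- xy[i, "row"]; c0 <- xy[i, "col"]
      sg <- radii[i] / 2
      p <- spot_patch(r0, c0, sg, pk[["hoechst"]], h, w)
      acc_ho[p$idx] <- acc_ho[p$idx] + p$val
      if (cells$dead[i]) {
        p <- spot_patch(r0, c0, sg, pk[["pi"]], h, w)
        acc_pi[p$idx] <- acc_pi[p$idx] + p$val
      }
      if (cells$edu_positive[i]) {
        p <- spot_patch(r0, c0, sg, pk[["edu"]], h, w)
        acc_edu[p$idx] <- acc_edu[p$idx] + p$val
      }
      if (cells$brdu_positive[i]) {
        p <- spot_patch(r0, c0, sg, pk[["brdu"]], h, w)
        acc_brdu[p$idx] <- acc_brdu[p$idx] + p$val
      }
      if (cells$insulin_positive[i]) {
        p <- halo_patch(r0, c0, radii[i], params$insulin_halo_width_px,
                        pk[["insulin"]], h, w)
        acc_ins[p$idx] <- acc_ins[p$idx] + p$val
      }
    }

    ramp <- matrix(rep(seq(0, 1, length.out = w), each = h), h, w)
    base_bg <- params$background_level + params$background_gradient * ramp
    ch <- list(hoechst = matrix(acc_ho, h, w) + base_bg,
               pi = matrix(acc_pi, h, w) + base_bg,
               insulin = matrix(acc_ins, h, w) + base_bg,
               edu = matrix(acc_edu, h, w) + base_bg,
               brdu = matrix(acc_brdu, h, w) + base_bg)

    if (params$noise) {
      for (nm in CHANNELS) {
        v <- rpois(length(ch[[nm]]), ch[[nm]]) +
          rnorm(length(ch[[nm]]), 0, params$read_noise_sd)
        ch[[nm]] <- matrix(pmax(0, round(v)), h, w)
      }
    }

    gt <- data.frame(
      cell_id = if (n > 0 && "cell_id" %in% names(cells)) cells$cell_id else seq_len(n),
      row = xy[, "row"], col = xy[, "col"],
      nucleus_radius_px = radii,
      dead = cells$dead,
      insulin_positive = cells$insulin_positive,
      edu_positive = cells$edu_positive,
      brdu_positive = cells$brdu_positive
    )
    list(image = well_image(ch, params$pixel_size_um), ground_truth = gt)
  })
}

#' Write a well image as multi-page TIFF plus channel-map sidecar
#'
#' Channels are stored as one 16-bit page each, in a fixed order recorded in
#' a plain-text YAML sidecar together with the pixel size. Intensities are
#' rounded to integers and values above 65535 are clamped; any clamping is
#' flagged per channel in the sidecar. For integer-valued images within
#' range the round trip through [read_well()] is exact.
#'
#' @param wi A [well_image()].
#' @param path Path of the TIFF to write; the sidecar is written next to it
#'   as `<path>.channels.yaml`.
#' @return Invisibly, the sidecar metadata list.
#' @export
write_well <- function(wi, path) {
  stopifnot(inherits(wi, "well_image"))
  clipped <- vapply(wi$channels, function(ch) any(ch > 65535), logical(1))
  pages <- lapply(wi$channels, function(ch) {
    pmin(pmax(round(ch), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  meta <- list(channels = as.list(names(wi$channels)),
               pixel_size_um = wi$pixel_size_um,
               clipped = as.list(clipped))
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(meta)
}

sidecar_path <- function(path) paste0(path, ".channels.yaml")

#' Read a well image written by [write_well()]
#'
#' @param path Path of the multi-page TIFF; the sidecar
#'   `<path>.channels.yaml` must exist and name all required channels.
#' @return A [well_image()].
#' @export
read_well <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop_data("channel-map sidecar not found: ", sp)
  meta <- yaml::read_yaml(sp)
  chn <- unlist(meta$channels)
  missing <- setdiff(CHANNELS, chn)
  if (length(missing)) {
    stop_data("channel map omits required channel(s): ",
              paste(missing, collapse = ", "))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < length(chn)) {
    stop_data("TIFF has ", length(pages), " pages but the channel map names ",
              length(chn))
  }
  ch <- lapply(pages[seq_along(chn)], function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    round(p * 65535)
  })
  names(ch) <- chn
  well_image(ch[CHANNELS], pixel_size_um = meta$pixel_size_um)
}
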