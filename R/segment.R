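## Background removal: Lab/HSI channel thresholds, 9x9 median filter,
## morphological repair, component filtering, and yellow-leaf removal.

#' Segmentation configuration
#'
#' Threshold intervals are calibration constants, not biological quantities:
#' the defaults are the channel midpoints between the renderer's default
#' tissue palette (green a* ~ -36 / b* ~ 34, yellowing a* ~ +1 / b* ~ 59)
#' and its background (a* ~ -1 / b* ~ -3) and pot (a* ~ +16 / b* ~ +17), so
#' the binarization boundary falls at ~50% pixel coverage. Re-calibrate for
#' any other camera or palette.
#'
#' @param a_range,b_range Closed intervals on the Lab a*/b* channels.
#' @param h_range Interval on HSI hue in degrees; may wrap past 360.
#' @param median_window Odd side length of the square median filter
#'   (default 9, i.e. a 9 x 9 mask).
#' @param morph_radius Disc radius for morphological closing.
#' @param opening_radius Disc radius for the subsequent opening.
#' @param min_component_px Connected components smaller than this are dropped.
#' @param yellow_b_threshold Components whose mean b* exceeds this (and whose
#'   mean a* is >= 0, i.e. not green-dominant) count as yellowing.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(a_range = c(-80, 8),
                                b_range = c(15.5, 120),
                                h_range = c(35, 170),
                                median_window = 9,
                                morph_radius = 2,
                                opening_radius = 1,
                                min_component_px = 150,
                                yellow_b_threshold = 45) {
  cfg <- list(a_range = as.numeric(a_range), b_range = as.numeric(b_range),
              h_range = as.numeric(h_range),
              median_window = as.integer(median_window),
              morph_radius = as.integer(morph_radius),
              opening_radius = as.integer(opening_radius),
              min_component_px = as.integer(min_component_px),
              yellow_b_threshold = as.numeric(yellow_b_threshold))
  if (cfg$median_window < 1 || cfg$median_window %% 2 == 0) {
    stop("median_window must be an odd integer >= 1", call. = FALSE)
  }
  if (cfg$a_range[1] > cfg$a_range[2] || cfg$b_range[1] > cfg$b_range[2]) {
    stop("a_range and b_range must be non-decreasing intervals", call. = FALSE)
  }
  class(cfg) <- "segmentation_config"
  cfg
}

#' Majority (median) filter on a binary raster
#'
#' The median of 0/1 values over an odd-sized square window is their
#' majority; computed exactly with an integral image. Borders are padded by
#' replication so constant rasters are preserved.
#'
#' @param mask Logical matrix.
#' @param window Odd window side length.
#' @return Filtered logical matrix of the same dimensions.
#' @export
binary_median_filter <- function(mask, window = 9) {
  assert_mask(mask, nonempty = FALSE)
  stopifnot(window >= 1, window %% 2 == 1)
  if (window == 1) return(mask)
  p <- (window - 1L) / 2L
  h <- nrow(mask); w <- ncol(mask)
  ri <- pmin(pmax(seq(1 - p, h + p), 1L), h)
  ci <- pmin(pmax(seq(1 - p, w + p), 1L), w)
  padded <- mask[ri, ci, drop = FALSE] * 1L
  ## integral image with leading zero row/col
  S <- matrix(0L, nrow(padded) + 1L, ncol(padded) + 1L)
  S[-1, -1] <- apply(apply(padded, 2, cumsum), 1, cumsum) |> t()
  r0 <- seq_len(h); c0 <- seq_len(w)
  sums <- S[r0 + window, c0 + window, drop = FALSE] -
    S[r0, c0 + window, drop = FALSE] -
    S[r0 + window, c0, drop = FALSE] + S[r0, c0, drop = FALSE]
  sums >= (window * window + 1) / 2
}

## EBImage uses (x, y) = (col, row) order; the package stores masks as
## (row, col) matrices, hence the transposes at this boundary.
mask_to_ebi <- function(mask) EBImage::Image(t(mask) * 1)
ebi_to_mask <- function(img) t(EBImage::imageData(img)) > 0.5

#' Segment the plant from the background
#'
#' A pixel is tentatively plant iff its a*, b* (Lab) and H (HSI) values fall
#' in the configured intervals. The binary raster is then cleaned with the
#' square median filter, repaired by morphological closing-then-opening with
#' disc elements plus hole filling, and components smaller than
#' `min_component_px` are dropped. An all-background result is returned as
#' an empty mask with attribute `empty_warning = TRUE` rather than an error.
#'
#' @param image Height x width x 3 RGB array (0-255).
#' @param config A [segmentation_config()].
#' @param lab,hsi Optional precomputed [rgb_to_lab()] / [rgb_to_hsi()]
#'   rasters of `image` (avoids recomputation along the measurement chain).
#' @return Logical mask with attributes `empty_warning` (flag) and
#'   `n_components`.
#' @export
segment_plant <- function(image, config = segmentation_config(),
                          lab = NULL, hsi = NULL) {
  assert_rgb_image(image)
  stopifnot(inherits(config, "segmentation_config"))
  if (is.null(lab)) lab <- rgb_to_lab(image)
  if (is.null(hsi)) hsi <- rgb_to_hsi(image)
  mask <- lab[, , 2] >= config$a_range[1] & lab[, , 2] <= config$a_range[2] &
    lab[, , 3] >= config$b_range[1] & lab[, , 3] <= config$b_range[2] &
    hue_in_range(hsi[, , 1], config$h_range)

  mask <- binary_median_filter(mask, config$median_window)

  if (any(mask)) {
    ## morphology only needs the plant bounding box (plus a structuring-
    ## element margin); cropping keeps large frames cheap
    pad <- 2L * (config$morph_radius + config$opening_radius) + 2L
    rr <- range(which(rowSums(mask) > 0))
    cr <- range(which(colSums(mask) > 0))
    rows <- max(1, rr[1] - pad):min(nrow(mask), rr[2] + pad)
    cols <- max(1, cr[1] - pad):min(ncol(mask), cr[2] + pad)
    img <- mask_to_ebi(mask[rows, cols, drop = FALSE])
    if (config$morph_radius >= 1) {
      img <- EBImage::closing(img, EBImage::makeBrush(2L * config$morph_radius + 1L, "disc"))
    }
    if (config$opening_radius >= 1) {
      img <- EBImage::opening(img, EBImage::makeBrush(2L * config$opening_radius + 1L, "disc"))
    }
    img <- EBImage::fillHull(img)
    comp <- EBImage::imageData(EBImage::bwlabel(img))
    sizes <- tabulate(comp[comp > 0])
    keep <- which(sizes >= config$min_component_px)
    sub <- t(matrix(comp %in% keep, nrow = nrow(comp)))
    mask[] <- FALSE
    mask[rows, cols] <- sub
    n_comp <- length(keep)
  } else {
    n_comp <- 0L
  }

  empty <- !any(mask)
  if (empty) warning("segmentation produced an empty mask", call. = FALSE)
  structure(mask, empty_warning = empty, n_components = n_comp)
}

#' Remove yellowing leaves from a segmented mask
#'
#' Works per connected component (leaves are removed as units, avoiding
#' speckled masks): a component is dropped when its mean b* exceeds
#' `yellow_b_threshold` and its mean a* is `>= 0` (not green-dominant).
#' The result is always a subset of the input mask.
#'
#' @param image The RGB image the mask was segmented from.
#' @param mask Logical mask from [segment_plant()].
#' @param config A [segmentation_config()].
#' @param lab Optional precomputed [rgb_to_lab()] raster of `image`.
#' @return Logical mask with attribute `removed_components` (count).
#' @export
remove_yellow_leaves <- function(image, mask, config = segmentation_config(),
                                 lab = NULL) {
  assert_rgb_image(image)
  assert_mask(mask, nonempty = FALSE)
  if (!any(mask)) return(structure(mask, removed_components = 0L))
  comp <- t(EBImage::imageData(EBImage::bwlabel(mask_to_ebi(mask))))
  if (is.null(lab)) lab <- rgb_to_lab(image)
  ids <- comp[mask]
  mean_a <- tapply(lab[, , 2][mask], ids, mean)
  mean_b <- tapply(lab[, , 3][mask], ids, mean)
  drop_ids <- as.integer(names(mean_b))[mean_b > config$yellow_b_threshold & mean_a >= 0]
  out <- mask & !(comp %in% drop_ids)
  dim(out) <- dim(mask)
  structure(out, removed_components = length(drop_ids))
}
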