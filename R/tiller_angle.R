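## Automatic tiller-angle measurement from a segmented mask: crop the basal
## region, assign the four outer vertices (a, b upper; c, d lower), and sum
## the two atan angles at the base. The tiller angle is the maximum angle
## between the outermost tillers, in degrees.

#' Tiller-angle measurement configuration
#'
#' @param height_fraction Fraction of the plant bounding-box height, counted
#'   up from the lowest plant row, kept for the basal crop (default 1/3: tall
#'   enough to contain the tiller divergence, short enough to exclude
#'   drooping leaf tips).
#' @param min_crop_px Minimum number of plant pixels the crop must retain.
#' @param view_aggregate How to combine per-view angles into one value per
#'   plant/stage: `"mean"` (default) or `"max"`.
#' @return An `angle_config` list.
#' @export
angle_config <- function(height_fraction = 1 / 3, min_crop_px = 30,
                         view_aggregate = c("mean", "max")) {
  stop_if_not_scalar_number(height_fraction, "height_fraction",
                            lower = 1e-6, upper = 1)
  cfg <- list(height_fraction = height_fraction,
              min_crop_px = as.integer(min_crop_px),
              view_aggregate = match.arg(view_aggregate))
  class(cfg) <- "angle_config"
  cfg
}

#' Crop the basal region of a plant mask
#'
#' Retains plant pixels whose row lies within
#' `height_fraction * bounding-box height` of the lowest plant row.
#'
#' @param mask Logical plant mask.
#' @param config An [angle_config()].
#' @return Logical mask of the same dimensions containing only the basal
#'   region, with attribute `crop_height_px`.
#' @export
crop_basal_region <- function(mask, config = angle_config()) {
  assert_mask(mask)
  rows <- range(which(rowSums(mask) > 0))
  bbox_h <- rows[2] - rows[1] + 1
  keep_h <- ceiling(config$height_fraction * bbox_h)
  top_row <- rows[2] - keep_h + 1
  out <- mask
  if (top_row > 1) out[seq_len(top_row - 1), ] <- FALSE
  if (sum(out) < config$min_crop_px) {
    stop("plant too small: basal crop retains fewer pixels than min_crop_px",
         call. = FALSE)
  }
  structure(out, crop_height_px = keep_h)
}

#' Assign the four outer vertices of the basal crop
#'
#' `a`/`b` are the leftmost/rightmost plant pixels on the top occupied row of
#' the crop; `c`/`d` are the leftmost/rightmost pixels on the bottom occupied
#' row. The base point is the midpoint of `c` and `d`. Coordinates are
#' `(col, row)`, origin top-left.
#'
#' @param cropped Basal mask from [crop_basal_region()].
#' @return List with `a`, `b`, `c`, `d` (each `c(col, row)`) and
#'   `base_point`.
#' @export
find_vertices <- function(cropped) {
  assert_mask(cropped)
  occ <- which(rowSums(cropped) > 0)
  top <- occ[1]; bottom <- occ[length(occ)]
  if (top == bottom) stop("degenerate crop: single occupied row", call. = FALSE)
  top_cols <- which(cropped[top, ])
  bottom_cols <- which(cropped[bottom, ])
  list(a = c(min(top_cols), top),
       b = c(max(top_cols), top),
       c = c(min(bottom_cols), bottom),
       d = c(max(bottom_cols), bottom),
       base_point = c((min(bottom_cols) + max(bottom_cols)) / 2, bottom))
}

#' Internal tiller angle at the base
#'
#' `angle = atan(|a_col - base_col| / (base_row - a_row)) +
#'          atan(|b_col - base_col| / (base_row - b_row))`, in degrees:
#' the internal angle at the base point subtended by the two outermost
#' upper vertices.
#'
#' @param vertices Vertex list from [find_vertices()] (fields `a`, `b`).
#' @param base_point `c(col, row)` base; defaults to `vertices$base_point`.
#' @return Angle in degrees, `>= 0`.
#' @export
compute_angle <- function(vertices, base_point = vertices$base_point) {
  a <- vertices$a; b <- vertices$b
  drop_a <- base_point[2] - a[2]
  drop_b <- base_point[2] - b[2]
  if (drop_a <= 0 || drop_b <= 0) {
    stop("zero vertical drop: upper vertices must lie above the base point",
         call. = FALSE)
  }
  (atan(abs(a[1] - base_point[1]) / drop_a) +
     atan(abs(b[1] - base_point[1]) / drop_b)) * 180 / pi
}

#' Measure the tiller angle from an RGB image
#'
#' Full measurement chain: segment the plant, remove yellowing leaves, crop
#' the basal region, assign vertices, and compute the internal angle. Errors
#' raised by a stage are re-signalled with the stage name prefixed.
#'
#' @param image Height x width x 3 RGB array (0-255).
#' @param seg_config A [segmentation_config()].
#' @param config An [angle_config()].
#' @return A `tiller_angle_result` list: `angle_deg`, `vertices` (a-d),
#'   `base_point`, `crop_height_px`, `mask` (yellow-removed full mask).
#' @export
measure_tiller_angle <- function(image,
                                 seg_config = segmentation_config(),
                                 config = angle_config()) {
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
    })
  }
  lab <- rgb_to_lab(image)
  mask <- run_stage("segment_plant", segment_plant(image, seg_config, lab = lab))
  mask <- run_stage("remove_yellow_leaves",
                    remove_yellow_leaves(image, mask, seg_config, lab = lab))
  cropped <- run_stage("crop_basal_region", crop_basal_region(mask, config))
  vertices <- run_stage("find_vertices", find_vertices(cropped))
  angle <- run_stage("compute_angle", compute_angle(vertices))
  structure(list(angle_deg = angle,
                 vertices = vertices[c("a", "b", "c", "d")],
                 base_point = vertices$base_point,
                 crop_height_px = attr(cropped, "crop_height_px"),
                 mask = mask),
            class = "tiller_angle_result")
}
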