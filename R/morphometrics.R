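## Six silhouette shape descriptors of a binary plant mask: projected area,
## convex hull area, compactness, eccentricity, and bounding-box extents.
## Pixels are treated as unit squares on a grid with origin top-left;
## (col, row) coordinates are used throughout.

#' Projected area of a mask
#'
#' @param mask Logical matrix (TRUE = plant).
#' @return Number of plant pixels (px^2).
#' @export
projected_area <- function(mask) {
  assert_mask(mask)
  sum(mask)
}

#' Convex hull area of a mask
#'
#' Area of the convex hull of the plant pixels, each treated as a unit
#' square (the hull polygon spans pixel corners, and its area is computed
#' by the shoelace formula). With this convention the hull area of any
#' convex filled shape equals its projected area exactly, a single pixel
#' has hull area 1, and degenerate collinear masks get the area of the
#' covering 1-px-wide rectangle.
#'
#' @param mask Logical matrix.
#' @return Hull area in px^2.
#' @export
convex_hull_area <- function(mask) {
  assert_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  cols <- idx[, 2]; rows <- idx[, 1]
  ## the four corners of each pixel square (pixel (c, r) spans
  ## [c - 0.5, c + 0.5] x [r - 0.5, r + 0.5])
  x <- c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5)
  y <- c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5)
  hull <- grDevices::chull(x, y)
  hx <- x[hull]; hy <- y[hull]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' Compactness of a mask
#'
#' Projected area divided by convex hull area, in `(0, 1]`; 1 for any
#' convex filled shape. The common phenomics convention, consistent with
#' compactness falling as the plant spreads out.
#'
#' @param mask Logical matrix.
#' @return Compactness in `(0, 1]`.
#' @export
compactness <- function(mask) {
  projected_area(mask) / convex_hull_area(mask)
}

#' Eccentricity of the moment-matched ellipse
#'
#' Conic-section eccentricity of the ellipse with the same second central
#' moments as the pixel-center cloud: `e = sqrt(1 - lambda_min/lambda_max)`
#' with `lambda` the eigenvalues of the 2 x 2 central moment matrix
#' (equivalently `sqrt(1 - (b/a)^2)` for the matched semi-axes `a >= b`).
#' 0 means circular, values near 1 mean linear. A single-pixel mask returns
#' 0 by convention.
#'
#' @param mask Logical matrix.
#' @return Eccentricity in `[0, 1]`.
#' @export
eccentricity <- function(mask) {
  assert_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 2) return(0)
  x <- idx[, 2]; y <- idx[, 1]
  mu <- cbind(x - mean(x), y - mean(y))
  M <- crossprod(mu) / nrow(mu)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0) return(0)
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

#' Bounding-box extents of a mask
#'
#' @param mask Logical matrix.
#' @return Named numeric vector `c(extent_x, extent_y)`: bounding-box width
#'   (`max_col - min_col + 1`) and height (`max_row - min_row + 1`) in px.
#' @export
object_extent <- function(mask) {
  assert_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  c(extent_x = diff(range(idx[, 2])) + 1,
    extent_y = diff(range(idx[, 1])) + 1)
}

#' All six shape descriptors of a mask
#'
#' @param mask Logical matrix.
#' @return A one-row `data.frame` with columns `projected_area`,
#'   `convex_hull_area`, `compactness`, `eccentricity`, `object_extent_x`,
#'   `object_extent_y`.
#' @export
morphometrics <- function(mask) {
  area <- projected_area(mask)
  hull <- convex_hull_area(mask)
  ext <- object_extent(mask)
  data.frame(projected_area = area,
             convex_hull_area = hull,
             compactness = area / hull,
             eccentricity = eccentricity(mask),
             object_extent_x = unname(ext["extent_x"]),
             object_extent_y = unname(ext["extent_y"]))
}
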