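#' Convert an RGB raster to CIE L*a*b*
#'
#' Channels are interpreted as 8-bit sRGB and converted under the D65
#' reference white. `L*` lies in `[0, 100]`; `a*` is the green (-) to red
#' (+) axis and `b*` the blue (-) to yellow (+) axis, the two channels used
#' to separate green tissue from soil and background. The conversion is the
#' standard sRGB gamma expansion, the sRGB-to-XYZ matrix, and the CIE cube
#' root, vectorized over the raster. It agrees with
#' `grDevices::convertColor(from = "sRGB", to = "Lab")` to within 0.4 Lab
#' units (exactly on neutrals; the residual comes from primary-chromaticity
#' rounding), which a unit test asserts.
#'
#' @param image Height x width x 3 array with values in 0-255.
#' @return Height x width x 3 array of `(L*, a*, b*)`.
#' @export
rgb_to_lab <- function(image) {
  assert_rgb_image(image)
  d <- dim(image)
  v <- c(image) / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  rgb <- matrix(lin, ncol = 3)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- tcrossprod(rgb, M)
  white <- rowSums(M)  # D65 (exactly the image of RGB white, so L*(white) = 100)
  tt <- sweep(xyz, 2, white, "/")
  delta <- 6 / 29
  f <- ifelse(tt > delta^3, tt^(1 / 3), tt / (3 * delta^2) + 4 / 29)
  lab <- cbind(116 * f[, 2] - 16,
               500 * (f[, 1] - f[, 2]),
               200 * (f[, 2] - f[, 3]))
  array(lab, dim = d)
}

#' Convert an RGB raster to HSI (hue, saturation, intensity)
#'
#' Classical HSI: intensity `I = (R + G + B) / 3` (0-255 scale), saturation
#' `S = 1 - min(R, G, B) / I` (0 when `I = 0`), and hue from the arccos
#' formulation, in degrees `[0, 360)`. Achromatic pixels (`S = 0` or an
#' undefined chromatic denominator) take `H = 0` by convention.
#'
#' @param image Height x width x 3 array with values in 0-255.
#' @return Height x width x 3 array of `(H degrees, S, I)`.
#' @export
rgb_to_hsi <- function(image) {
  assert_rgb_image(image)
  d <- dim(image)
  R <- as.vector(image[, , 1]); G <- as.vector(image[, , 2]); B <- as.vector(image[, , 3])
  I <- (R + G + B) / 3
  mn <- pmin(R, G, B)
  S <- ifelse(I > 0, 1 - mn / I, 0)
  num <- 0.5 * ((R - G) + (R - B))
  den <- sqrt((R - G)^2 + (R - B) * (G - B))
  H <- rep(0, length(R))
  ok <- den > .Machine$double.eps & S > 0
  theta <- acos(pmin(1, pmax(-1, num[ok] / den[ok]))) * 180 / pi
  H[ok] <- ifelse(B[ok] <= G[ok], theta, 360 - theta)
  array(c(H, S, I), dim = d)
}

#' @keywords internal
hue_in_range <- function(h, range) {
  lo <- range[1]; hi <- range[2]
  if (lo <= hi) h >= lo & h <= hi else h >= lo | h <= hi  # interval may wrap 360
}
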