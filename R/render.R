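## Synthetic side-view plant renderer.
##
## A plant is a fan of straight tillers radiating from a basal point above a
## pot band on a uniform background. Straight strokes make the ground-truth
## tiller angle exact: truth_angle = max(angle_i) - min(angle_i). Default
## geometry emulates a greenhouse imaging cabinet: a 768 x 768 px frame in
## which the plant spans ~450 px (roughly 1.3 mm/px for a 1 m scene), with
## 6 px wide tillers (culm plus leaf sheath).

#' Parametric description of a synthetic plant
#'
#' Angles are signed degrees from vertical (negative = leaning left) and must
#' lie in (-90, 90). `base_point` is `(col, row)` with origin at the top-left
#' pixel; it must sit inside the image above the pot band. Yellowing tillers
#' (senescing leaves) are drawn with their basal quarter omitted, so they
#' form connected components detached from the green canopy, the way dying
#' leaves separate from the plant in a segmented mask.
#'
#' @param n_tillers Number of tillers (>= 1).
#' @param tiller_angles_deg Signed angles from vertical, length `n_tillers`.
#' @param tiller_lengths_px Stroke lengths in px, length `n_tillers`.
#' @param tiller_width_px Stroke width in px.
#' @param base_point `(col, row)` of the basal point.
#' @param green_color_mean RGB triplet (0-255) of healthy tissue.
#' @param green_color_sd Per-pixel Gaussian RGB noise s.d.
#' @param yellow_fraction Proportion of tillers recolored yellow, in `[0, 1]`.
#' @param yellow_color RGB triplet of senescing tissue.
#' @param sheath_fraction Tillers are wrapped in a common leaf-sheath bundle
#'   near the base; the renderer fills the wedge between the outermost
#'   tillers up to this fraction of the mean tiller length (0 disables it).
#' @param pot_height_px Height of the pot band at the bottom of the frame.
#' @param pot_color,background_color RGB triplets.
#' @param image_size `(width, height)` in px.
#' @return A validated `plant_spec` list.
#' @export
plant_spec <- function(n_tillers,
                       tiller_angles_deg,
                       tiller_lengths_px,
                       tiller_width_px = 8,
                       base_point = c(512, 853),
                       green_color_mean = c(70, 135, 60),
                       green_color_sd = 6,
                       yellow_fraction = 0,
                       yellow_color = c(205, 170, 60),
                       sheath_fraction = 0.18,
                       pot_height_px = 147,
                       pot_color = c(120, 78, 62),
                       background_color = c(172, 176, 180),
                       image_size = c(1024, 1024)) {
  spec <- list(n_tillers = as.integer(n_tillers),
               tiller_angles_deg = as.numeric(tiller_angles_deg),
               tiller_lengths_px = as.numeric(tiller_lengths_px),
               tiller_width_px = as.integer(tiller_width_px),
               base_point = as.numeric(base_point),
               green_color_mean = as.numeric(green_color_mean),
               green_color_sd = as.numeric(green_color_sd),
               yellow_fraction = as.numeric(yellow_fraction),
               yellow_color = as.numeric(yellow_color),
               sheath_fraction = as.numeric(sheath_fraction),
               pot_height_px = as.integer(pot_height_px),
               pot_color = as.numeric(pot_color),
               background_color = as.numeric(background_color),
               image_size = as.integer(image_size))
  validate_plant_spec(spec)
}

#' @keywords internal
validate_plant_spec <- function(spec) {
  if (spec$n_tillers < 1) stop("need at least one tiller", call. = FALSE)
  if (length(spec$tiller_angles_deg) != spec$n_tillers ||
      length(spec$tiller_lengths_px) != spec$n_tillers) {
    stop("angle and length lists must have length n_tillers", call. = FALSE)
  }
  if (any(abs(spec$tiller_angles_deg) >= 90)) {
    stop("tiller angles must lie in (-90, 90) degrees", call. = FALSE)
  }
  if (spec$yellow_fraction < 0 || spec$yellow_fraction > 1) {
    stop("yellow_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (spec$sheath_fraction < 0 || spec$sheath_fraction > 0.9) {
    stop("sheath_fraction must lie in [0, 0.9]", call. = FALSE)
  }
  w <- spec$image_size[1]; h <- spec$image_size[2]
  bc <- spec$base_point[1]; br <- spec$base_point[2]
  if (bc < 1 || bc > w || br < 1 || br > h - spec$pot_height_px) {
    stop("base_point must lie inside the image above the pot band", call. = FALSE)
  }
  th <- spec$tiller_angles_deg * pi / 180
  tip_col <- bc + spec$tiller_lengths_px * sin(th)
  tip_row <- br - spec$tiller_lengths_px * cos(th)
  pad <- spec$tiller_width_px
  if (any(tip_row < 1 + pad) || any(tip_col < 1 + pad) || any(tip_col > w - pad)) {
    stop("impossible geometry: tiller extends beyond the image", call. = FALSE)
  }
  class(spec) <- "plant_spec"
  spec
}

#' Random plant specification with a prescribed tiller-angle spread
#'
#' The two outermost tillers sit at exactly `+/- spread_deg / 2`, so the
#' ground-truth angle equals `spread_deg`; interior tillers follow jittered
#' equal spacing (culms occupy space and repel, so independent uniform
#' angles — which can place two tillers in the same plane — are not
#' physical). Used by validation sweeps where the truth angle is the
#' quantity under study.
#'
#' @param spread_deg Target maximum angle between outermost tillers (>= 0).
#' @param n_tillers Number of tillers; default drawn uniformly from 6..11.
#' @param seed Integer seed.
#' @param ... Passed on to [plant_spec()] (e.g. `yellow_fraction`).
#' @return A `plant_spec`.
#' @export
random_plant_spec <- function(spread_deg, n_tillers = NULL, seed = 1, ...) {
  stop_if_not_scalar_number(spread_deg, "spread_deg", lower = 0, upper = 170)
  with_seed(seed, {
    if (is.null(n_tillers)) n_tillers <- sample(6:11, 1)
    half <- spread_deg / 2
    angles <- if (n_tillers == 1) 0 else if (n_tillers == 2) c(-half, half) else {
      gap <- spread_deg / (n_tillers - 1)
      jit <- stats::runif(n_tillers, -0.25 * gap, 0.25 * gap)
      jit[c(1, n_tillers)] <- 0  # outermost pinned so truth angle is exact
      seq(-half, half, length.out = n_tillers) + jit
    }
    lengths <- stats::runif(n_tillers, 570, 630)
    plant_spec(n_tillers = n_tillers, tiller_angles_deg = angles,
               tiller_lengths_px = lengths, ...)
  })
}

#' Render a plant specification to an RGB image with ground truth
#'
#' Tillers are anti-aliased straight strokes with round caps; per-pixel
#' coverage is derived from the distance to the stroke centerline. The truth
#' mask contains pixels with majority plant coverage (alpha > 0.5). Rendering
#' is bit-deterministic for a given spec and seed.
#'
#' @param spec A [plant_spec()].
#' @param seed Integer seed driving color noise and yellow-tiller selection.
#' @return A `rendered_plant` list: `image` (height x width x 3, 0-255
#'   integers), `truth_mask` (logical), `tiller_labels` (integer raster, 0 =
#'   background), `yellow_tillers` (indices), `truth_angle_deg`,
#'   `truth_morphometrics`, `spec`, `seed`.
#' @export
render_plant <- function(spec, seed = 1) {
  spec <- validate_plant_spec(spec)
  w <- spec$image_size[1]; h <- spec$image_size[2]
  with_seed(seed, {
    ## background + pot band
    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) img[, , ch] <- spec$background_color[ch]
    pot_rows <- (h - spec$pot_height_px + 1):h
    for (ch in 1:3) img[pot_rows, , ch] <- spec$pot_color[ch]

    n_yellow <- round(spec$yellow_fraction * spec$n_tillers)
    yellow <- if (n_yellow > 0) sort(sample.int(spec$n_tillers, n_yellow)) else integer(0)

    alpha <- matrix(0, h, w)
    labels <- matrix(0L, h, w)
    color_r <- matrix(0, h, w); color_g <- matrix(0, h, w); color_b <- matrix(0, h, w)
    half <- spec$tiller_width_px / 2
    bc <- spec$base_point[1]; br <- spec$base_point[2]

    ## basal leaf-sheath bundle: filled wedge between the outermost green
    ## tillers up to sheath_fraction of the mean tiller length
    green_idx <- setdiff(seq_len(spec$n_tillers), yellow)
    if (!length(green_idx)) green_idx <- seq_len(spec$n_tillers)
    if (spec$sheath_fraction > 0 && length(green_idx) >= 2) {
      ts <- spec$sheath_fraction * mean(spec$tiller_lengths_px)
      th_lo <- min(spec$tiller_angles_deg[green_idx]) * pi / 180
      th_hi <- max(spec$tiller_angles_deg[green_idx]) * pi / 180
      V <- rbind(c(bc, br),
                 c(bc + ts * sin(th_lo), br - ts * cos(th_lo)),
                 c(bc + ts * sin(th_hi), br - ts * cos(th_hi)))
      area2 <- (V[2, 1] - V[1, 1]) * (V[3, 2] - V[1, 2]) -
        (V[3, 1] - V[1, 1]) * (V[2, 2] - V[1, 2])
      if (abs(area2) > 1) {
        rows <- max(1, floor(min(V[, 2]) - 1)):min(h, ceiling(max(V[, 2]) + 1))
        cols <- max(1, floor(min(V[, 1]) - 1)):min(w, ceiling(max(V[, 1]) + 1))
        px <- rep(cols, each = length(rows)); py <- rep(rows, times = length(cols))
        sdist <- rep(Inf, length(px))
        for (e in 1:3) {
          A <- V[e, ]; B <- V[e %% 3 + 1, ]
          elen <- sqrt(sum((B - A)^2))
          d_e <- ((B[1] - A[1]) * (py - A[2]) - (B[2] - A[2]) * (px - A[1])) / elen
          if (area2 < 0) d_e <- -d_e  # orient so inside is positive
          sdist <- pmin(sdist, d_e)
        }
        a <- pmin(1, pmax(0, sdist + 0.5))
        keep <- a > 0
        if (any(keep)) {
          idx <- cbind(py[keep], px[keep]); a <- a[keep]
          noise <- matrix(stats::rnorm(3 * length(a), 0, spec$green_color_sd), ncol = 3)
          take <- a > alpha[idx]
          if (any(take)) {
            sel <- idx[take, , drop = FALSE]
            alpha[sel] <- a[take]
            labels[sel] <- spec$n_tillers + 1L  # sheath bundle
            color_r[sel] <- spec$green_color_mean[1] + noise[take, 1]
            color_g[sel] <- spec$green_color_mean[2] + noise[take, 2]
            color_b[sel] <- spec$green_color_mean[3] + noise[take, 3]
          }
        }
      }
    }

    for (i in seq_len(spec$n_tillers)) {
      th <- spec$tiller_angles_deg[i] * pi / 180
      L <- spec$tiller_lengths_px[i]
      t0 <- if (i %in% yellow) 0.25 * L else 0  # senesced tillers detach from base
      x0 <- bc + t0 * sin(th); y0 <- br - t0 * cos(th)
      x1 <- bc + L * sin(th);  y1 <- br - L * cos(th)
      rows <- max(1, floor(min(y0, y1) - half - 1)):min(h, ceiling(max(y0, y1) + half + 1))
      cols <- max(1, floor(min(x0, x1) - half - 1)):min(w, ceiling(max(x0, x1) + half + 1))
      px <- rep(cols, each = length(rows)); py <- rep(rows, times = length(cols))
      dx <- x1 - x0; dy <- y1 - y0; len2 <- dx * dx + dy * dy
      t_proj <- pmin(1, pmax(0, ((px - x0) * dx + (py - y0) * dy) / len2))
      d <- sqrt((px - (x0 + t_proj * dx))^2 + (py - (y0 + t_proj * dy))^2)
      a <- pmin(1, pmax(0, half + 0.5 - d))
      keep <- a > 0
      if (!any(keep)) next
      idx <- cbind(py[keep], px[keep])
      a <- a[keep]
      base_col <- if (i %in% yellow) spec$yellow_color else spec$green_color_mean
      noise <- matrix(stats::rnorm(3 * length(a), 0, spec$green_color_sd), ncol = 3)
      take <- a > alpha[idx]
      if (any(take)) {
        sel <- idx[take, , drop = FALSE]
        alpha[sel] <- a[take]
        labels[sel] <- i
        color_r[sel] <- base_col[1] + noise[take, 1]
        color_g[sel] <- base_col[2] + noise[take, 2]
        color_b[sel] <- base_col[3] + noise[take, 3]
      }
    }

    plantish <- alpha > 0
    for (ch in 1:3) {
      plane <- img[, , ch]
      col_plane <- switch(ch, color_r, color_g, color_b)
      plane[plantish] <- alpha[plantish] * col_plane[plantish] +
        (1 - alpha[plantish]) * plane[plantish]
      img[, , ch] <- plane
    }
    img <- round(pmin(pmax(img, 0), 255))

    truth_mask <- alpha > 0.5
    labels[!truth_mask] <- 0L
    structure(list(
      image = img,
      truth_mask = truth_mask,
      tiller_labels = labels,
      yellow_tillers = yellow,
      truth_angle_deg = max(spec$tiller_angles_deg) - min(spec$tiller_angles_deg),
      truth_morphometrics = morphometrics(truth_mask),
      spec = spec,
      seed = seed
    ), class = "rendered_plant")
  })
}

#' Write a rendered plant as a PNG plus a JSON ground-truth sidecar
#'
#' @param rendered A `rendered_plant`.
#' @param path Output PNG path; the sidecar goes to `<path>.json` and the
#'   truth mask to `<path stem>_mask.png` when `write_mask = TRUE`.
#' @param write_mask Also write the truth mask as a 0/255 grayscale PNG.
#' @return `path`, invisibly.
#' @export
write_plant_png <- function(rendered, path, write_mask = FALSE) {
  stopifnot(inherits(rendered, "rendered_plant"))
  png::writePNG(rendered$image / 255, target = path)
  sidecar <- list(truth_angle_deg = rendered$truth_angle_deg,
                  seed = rendered$seed,
                  spec = unclass(rendered$spec))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  if (write_mask) {
    png::writePNG(rendered$truth_mask * 1,
                  target = sub("\\.png$", "_mask.png", path))
  }
  invisible(path)
}

#' Read an RGB image from PNG into the package's raster convention
#'
#' @param path PNG path.
#' @return Height x width x 3 numeric array with values in 0-255.
#' @export
read_rgb_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  round(arr * 255)
}

#' Write a binary mask as a 0/255 grayscale PNG
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  assert_mask(mask, nonempty = FALSE)
  png::writePNG(mask * 1, target = path)
  invisible(path)
}
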