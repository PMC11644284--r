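# Basal crop, vertex assignment, and the atan-based internal angle.

test_that("basal crop keeps the requested fraction of the plant height", {
  m <- matrix(FALSE, 400, 50)
  m[51:350, 25] <- TRUE  # plant spanning 300 rows
  crop <- crop_basal_region(m, angle_config(height_fraction = 1 / 3,
                                            min_crop_px = 10))
  rows <- which(rowSums(crop) > 0)
  expect_equal(length(rows), 100)
  expect_equal(max(rows), 350)
  ## fraction 1 is the identity
  full <- crop_basal_region(m, angle_config(height_fraction = 1, min_crop_px = 10))
  expect_identical(unclass(full)[, ], m)
  ## 1-px bar of height 100, fraction 0.5 -> 50 pixels
  bar <- matrix(FALSE, 120, 9); bar[11:110, 5] <- TRUE
  half <- crop_basal_region(bar, angle_config(height_fraction = 0.5,
                                              min_crop_px = 10))
  expect_equal(sum(half), 50)
  expect_error(crop_basal_region(bar, angle_config(height_fraction = 0.01,
                                                   min_crop_px = 30)),
               "plant too small")
})

test_that("vertices land on the outermost pixels of the crop", {
  ## rendered V of two tillers at +/-25 degrees
  sp <- small_plant_spec(c(-25, 25))
  rp <- render_plant(sp, seed = 6)
  crop <- crop_basal_region(rp$truth_mask, angle_config())
  v <- find_vertices(crop)
  rows <- which(rowSums(crop) > 0)
  top <- rows[1]
  h <- 420 - top  # stroke drop from the base at that row
  half_w <- sp$tiller_width_px / 2
  expect_lt(abs(v$a[1] - (256 - tan(25 * pi / 180) * h - half_w)), 2.5)
  expect_lt(abs(v$b[1] - (256 + tan(25 * pi / 180) * h + half_w)), 2.5)
  expect_equal(v$a[2], top)
  ## vertical bar: a and b share a column
  bar <- matrix(FALSE, 120, 9); bar[11:110, 5] <- TRUE
  vb <- find_vertices(crop_basal_region(bar, angle_config(min_crop_px = 5)))
  expect_equal(vb$a, vb$b)
  ## single-row crop is degenerate
  flat <- matrix(FALSE, 10, 10); flat[7, 3:8] <- TRUE
  expect_error(find_vertices(flat), "degenerate crop")
})

test_that("the internal angle follows the two-sided atan closed form", {
  v <- list(a = c(80, 150), b = c(120, 150), base_point = c(100, 200))
  expect_equal(compute_angle(v), 2 * atan(20 / 50) * 180 / pi, tolerance = 1e-12)
  expect_equal(round(compute_angle(v), 2), 43.60)
  ## both vertices directly above the base
  v0 <- list(a = c(100, 150), b = c(100, 150), base_point = c(100, 200))
  expect_equal(compute_angle(v0), 0)
  ## offsets equal to drops on both sides: 45 + 45
  v90 <- list(a = c(50, 150), b = c(150, 150), base_point = c(100, 200))
  expect_equal(compute_angle(v90), 90)
  ## degenerate drop
  vz <- list(a = c(80, 200), b = c(120, 200), base_point = c(100, 200))
  expect_error(compute_angle(vz), "zero vertical drop")
})

test_that("a single vertical tiller measures close to zero degrees", {
  ## a lone young culm: full scale, single 6 px stroke
  sp <- plant_spec(n_tillers = 1, tiller_angles_deg = 0,
                   tiller_lengths_px = 620, tiller_width_px = 6)
  res <- measure_tiller_angle(render_plant(sp, seed = 2)$image)
  expect_lt(res$angle_deg, 2)
})

test_that("the measured angle is invariant under horizontal mirroring", {
  rp <- render_plant(random_plant_spec(33, seed = 31), seed = 31)
  res <- measure_tiller_angle(rp$image)
  mirrored <- rp$image[, dim(rp$image)[2]:1, , drop = FALSE]
  res_m <- measure_tiller_angle(mirrored)
  expect_equal(res$angle_deg, res_m$angle_deg, tolerance = 0.6)
})

test_that("the measured angle is scale-invariant for straight tillers", {
  angles <- c(-14, -5, 2, 9, 14)
  small <- small_plant_spec(angles)
  big <- plant_spec(n_tillers = 5, tiller_angles_deg = angles,
                    tiller_lengths_px = rep(560, 5), tiller_width_px = 8,
                    base_point = c(512, 840), pot_height_px = 160,
                    image_size = c(1024, 1024))
  a1 <- measure_tiller_angle(render_plant(small, seed = 3)$image)$angle_deg
  a2 <- measure_tiller_angle(render_plant(big, seed = 3)$image)$angle_deg
  expect_lt(abs(a1 - a2), 1.5)
})

test_that("widening the truth angle monotonically widens the measurement", {
  measured <- vapply(c(10, 22, 34, 46, 58), function(spread) {
    rp <- render_plant(random_plant_spec(spread, n_tillers = 7, seed = 40),
                       seed = 40)
    measure_tiller_angle(rp$image)$angle_deg
  }, numeric(1))
  expect_true(all(diff(measured) > 0))
})

test_that("stage errors are tagged with the failing stage", {
  bg <- array(0, dim = c(64, 64, 3))
  for (ch in 1:3) bg[, , ch] <- c(172, 176, 180)[ch]
  expect_error(suppressWarnings(measure_tiller_angle(bg)), "\\[crop_basal_region\\]")
})
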