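# Shared fixtures. Heavy objects (rendered populations, segmented masks)
# are built once per test run and cached, since several suites measure
# different properties of the same synthetic population.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small plant on a 512 px canvas: cheap enough for structural unit tests
# (subset/idempotence/yellow-removal); fidelity targets use full-scale
# plants from rendered_population().
small_plant_spec <- function(angles = c(-15, -7, 0, 8, 15), ...) {
  plant_spec(n_tillers = length(angles), tiller_angles_deg = angles,
             tiller_lengths_px = rep(280, length(angles)), tiller_width_px = 6,
             base_point = c(256, 420), pot_height_px = 80,
             image_size = c(512, 512), ...)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Full-scale validation population: plants with truth spreads across
# 5-70 degrees, segmented with default configuration, plus the downstream
# angle measurement and shape descriptors of the measured masks.
rendered_population <- function() {
  cached("population", function() {
    n <- 200
    spreads <- seq(5, 70, length.out = n)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      rp <- render_plant(random_plant_spec(spreads[i], seed = 5000 + i),
                         seed = 5000 + i)
      lab <- rgb_to_lab(rp$image)
      mask <- segment_plant(rp$image, lab = lab)
      mask <- remove_yellow_leaves(rp$image, mask, lab = lab)
      angle <- tryCatch({
        cropped <- crop_basal_region(mask)
        compute_angle(find_vertices(cropped))
      }, error = function(e) NA_real_)
      out[[i]] <- list(spread = spreads[i],
                       truth_angle = rp$truth_angle_deg,
                       truth_mask = rp$truth_mask,
                       mask = mask,
                       angle = angle,
                       morpho = morphometrics(mask))
    }
    out
  })
}

# MGRIL-scale map shared by the QTL suites.
mgril_map <- function() cached("map", function() make_genetic_map())
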