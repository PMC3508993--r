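make_montage_like <- function(pixels, scale = 10, mask = NULL) {
  calibrated_image(pixels, scale, c(0, 0),
                   mask %||% matrix(TRUE, nrow(pixels), ncol(pixels)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a constant montage maps to a constant (zero after background removal) map", {
  mon <- make_montage_like(matrix(5, 120, 120))
  map <- build_brightness_map(mon)
  v <- map$pixels[map$outline_mask]
  expect_true(all(abs(v - v[1]) < 1e-9))
})

test_that("the brightness map is linear in montage intensity", {
  p <- make_density_profile("rd10_st", retina_radius = 0.8,
                            scotoma_radius = 0.2)
  m <- sample_mosaic(p, seed = 3)
  mon <- render_montage(m)
  map1 <- build_brightness_map(mon)
  mon2 <- mon
  mon2$pixels <- mon$pixels * 2
  map2 <- build_brightness_map(mon2)
  expect_equal(map2$pixels[map2$outline_mask],
               2 * map1$pixels[map1$outline_mask], tolerance = 1e-9)
})

test_that("the scotoma is darker than the periphery on the map", {
  p <- make_density_profile("rd10_st", retina_radius = 1.2,
                            scotoma_radius = 0.29)
  m <- sample_mosaic(p, seed = 12)
  map <- build_brightness_map(render_montage(m))
  ax <- conetop:::image_axis(map, 1)
  rr <- outer(ax, ax, function(x, y) sqrt(x^2 + y^2))
  expect_lt(mean(map$pixels[rr < 0.15]),
            mean(map$pixels[rr > 0.9 & rr < 1.1], na.rm = TRUE))
})

test_that("a too-fine smoothing scale is rejected", {
  mon <- make_montage_like(matrix(1, 50, 50), scale = 100)
  expect_error(build_brightness_map(mon, smooth_scale = 150), "2 pixels")
})

test_that("Otsu thresholding isolates the bright component of a step map", {
  px <- matrix(1, 100, 100)
  px[, 51:100] <- 3
  map <- make_montage_like(px)
  fg <- threshold_clusters(map)
  expect_true(all(fg[, 51:100]))
  expect_false(any(fg[, 1:50]))
})

test_that("a degenerate map thresholds to all-foreground with a warning", {
  map <- make_montage_like(matrix(2, 60, 60))
  expect_warning(fg <- threshold_clusters(map), "constant")
  expect_true(all(fg))
})

test_that("thresholding excludes the scotoma on a degenerating mosaic", {
  p <- make_density_profile("rd10_st", retina_radius = 1.2,
                            scotoma_radius = 0.35)
  m <- sample_mosaic(p, seed = 13)
  map <- build_brightness_map(render_montage(m))
  fg <- threshold_clusters(map)
  ax <- conetop:::image_axis(map, 1)
  rr <- outer(ax, ax, function(x, y) sqrt(x^2 + y^2))
  core <- rr < 0.25
  expect_gt(mean(!fg[core]), 0.95)
})

test_that("a single-level partition is the whole outline", {
  g <- gradient_map()
  part <- trace_isodensity(g, n_levels = 1)
  expect_equal(part$n_levels, 1)
  expect_equal(part$labels[g$outline_mask], rep(1L, sum(g$outline_mask)))
  expect_equal(sum(part$areas_mm2), outline_area(part))
})

test_that("a two-level step map partitions into disc and annulus with geometric areas", {
  radius <- 1.5
  npix <- 300
  ax <- ((seq_len(npix) - 0.5) * 10) / 1000 - radius
  rr <- outer(ax, ax, function(x, y) sqrt(x^2 + y^2))
  mask <- rr <= radius
  px <- ifelse(rr <= 1, 1, 2)  # tied intensities split exactly at the step
  px[!mask] <- NA
  map <- calibrated_image(px, 10, c(-radius, -radius), mask)
  part <- trace_isodensity(map, n_levels = 2)
  # pixel-counted areas must match pi*1^2 and pi*(1.5^2-1^2) within a
  # one-pixel-wide ring around each circle
  ring <- 2 * pi * 1 * (10 / 1000) * 2
  expect_lt(abs(part$areas_mm2[1] - pi), ring)
  expect_lt(abs(part$areas_mm2[2] - pi * (radius^2 - 1)), ring + 0.1)
  expect_equal(sum(part$areas_mm2), outline_area(part))
})

test_that("a radial gradient yields radially ordered annular regions", {
  g <- gradient_map()
  part <- trace_isodensity(g, n_levels = 5)
  ax <- conetop:::image_axis(g, 1)
  rr <- outer(ax, ax, function(x, y) sqrt(x^2 + y^2))
  centroids <- vapply(1:5, function(k) mean(rr[part$labels == k]),
                      numeric(1))
  expect_true(all(diff(centroids) > 0))
  # quantile bins: equal pixel mass
  counts <- tabulate(part$labels[g$outline_mask], 5)
  expect_lt(diff(range(counts)) / mean(counts), 0.02)
})

test_that("partition invariants: disjoint cover, exact area conservation, idempotence", {
  p <- make_density_profile("rd10_ee", retina_radius = 1.2,
                            scotoma_radius = 0.088)
  m <- sample_mosaic(p, seed = 17)
  map <- build_brightness_map(render_montage(m))
  part <- trace_isodensity(map, 5)
  expect_equal(sum(part$labels[part$outline_mask] >= 1),
               sum(part$outline_mask))
  expect_true(all(part$labels[!part$outline_mask] == 0))
  expect_identical(sum(tabulate(part$labels[part$outline_mask], 5)),
                   sum(part$outline_mask))
  expect_equal(sum(part$areas_mm2), outline_area(part))
  part2 <- trace_isodensity(map, 5)
  expect_identical(part, part2)
  # label-density concordance: true mean density strictly increases with level
  lab_at <- region_at(part, m$positions[, 1], m$positions[, 2])
  dens <- vapply(1:5, function(k) sum(lab_at == k) / part$areas_mm2[k],
                 numeric(1))
  expect_true(all(diff(dens) > 0))
})

test_that("degenerate partitions are refused", {
  g <- gradient_map()
  expect_error(trace_isodensity(g, n_levels = 1e6), "distinct")
  lab <- matrix(0L, 10, 10)
  mask <- matrix(TRUE, 10, 10)
  lab[mask] <- 1L
  expect_error(conetop:::new_partition(lab, cbind(c(0, 1), c(1, 2)),
                                       10, c(0, 0), mask),
               "empty region")
})

test_that("region areas are invariant to re-rasterization at a finer scale", {
  for (sc in c(10, 5)) {
    npix <- 2 * 1000 / sc
    ax <- ((seq_len(npix) - 0.5) * sc) / 1000 - 1
    rr <- outer(ax, ax, function(x, y) sqrt(x^2 + y^2))
    mask <- rr <= 1
    px <- rr
    px[!mask] <- NA
    map <- calibrated_image(px, sc, c(-1, -1), mask)
    part <- trace_isodensity(map, 4)
    if (sc == 10) a10 <- part$areas_mm2 else a5 <- part$areas_mm2
  }
  expect_equal(a5, a10, tolerance = 0.02)
})

test_that("isodensity curves export as polylines in mm and to GeoJSON", {
  g <- gradient_map()
  part <- trace_isodensity(g, 3)
  curves <- isodensity_curves(g, part)
  expect_gt(length(curves), 0)
  r_first <- sqrt(curves[[1]]$x^2 + curves[[1]]$y^2)
  expect_lt(sd(r_first), 0.05)  # level curve of a radial map is a circle
  tf <- withr::local_tempfile(fileext = ".geojson")
  curves_to_geojson(curves, tf)
  gj <- jsonlite::read_json(tf)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), length(curves))
})
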