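test_that("an empty field renders as pure background", {
  p <- make_density_profile("uniform", d_max = 0, retina_radius = 0.3)
  m <- sample_mosaic(p, seed = 1)
  img <- render_field(m, c(0, 0), snr = Inf, background = 0.2)
  expect_true(all(img$pixels == 0.2))
  img2 <- render_field(m, c(0, 0), snr = 10, background = 0.2)
  expect_lt(abs(mean(img2$pixels) - 0.2), 0.01)
})

test_that("noiseless renders peak at the ground-truth positions", {
  m <- grid_mosaic()  # 25 cones, 25 um spacing
  img <- render_field(m, c(0, 0), snr = Inf, background = 0)
  mx <- conetop:::cpp_local_maxima(img$pixels, 0.5, 4L)
  expect_equal(length(mx$x), 25)
  found_um <- cbind(mx$x, mx$y) * img$scale
  truth_um <- cbind(m$positions[, 1] * 1000 + 62.5,
                    m$positions[, 2] * 1000 + 62.5)
  for (i in seq_len(25)) {
    expect_lt(min(sqrt((found_um[, 1] - truth_um[i, 1])^2 +
                       (found_um[, 2] - truth_um[i, 2])^2)),
              1 * img$scale + 1)  # within one pixel
  }
})

test_that("field content matches the area arithmetic at 50,000/mm^2", {
  # 50,000 x 0.015625 mm^2 = 781.25 cones expected in a 125 um field
  m <- uniform_field_mosaic(50000, seed = 21)
  n <- cones_in_field(m, c(0, 0), 125)
  expect_lt(abs(n - 781.25), 4 * sqrt(781.25))
})

test_that("fields must lie inside the retinal outline", {
  m <- uniform_field_mosaic(1000, seed = 1, radius = 0.2)
  expect_error(render_field(m, c(0.19, 0)), "outline")
})

test_that("an empty mosaic yields a background-level montage", {
  p <- make_density_profile("uniform", d_max = 0, retina_radius = 0.5)
  m <- sample_mosaic(p, seed = 1)
  mon <- render_montage(m, snr = Inf)
  v <- mon$pixels[mon$outline_mask]
  expect_true(all(abs(v - v[1]) < 1e-12))
})

test_that("uniform mosaics give a low-variability montage", {
  p <- make_density_profile("uniform", d_max = 10000, retina_radius = 0.8)
  m <- sample_mosaic(p, seed = 4)
  mon <- render_montage(m)
  # interior pixels only, away from the outline edge
  ax <- conetop:::image_axis(mon, 1)
  rr <- outer(ax, ax, function(x, y) sqrt(x^2 + y^2))
  v <- mon$pixels[rr <= 0.7]
  expect_lt(sd(v) / mean(v), 0.30)
})

test_that("montage brightness is monotone in local density", {
  p <- make_density_profile("rd10_st", retina_radius = 1.2,
                            scotoma_radius = 0.29)
  m <- sample_mosaic(p, seed = 8)
  mon <- render_montage(m)
  # scotoma darker than periphery
  ax <- conetop:::image_axis(mon, 1)
  rr <- outer(ax, ax, function(x, y) sqrt(x^2 + y^2))
  expect_lt(mean(mon$pixels[rr < 0.2]),
            mean(mon$pixels[rr > 0.9 & rr < 1.1]))
  # Spearman correlation between windowed brightness and true density
  win <- sqrt(0.05)  # 0.05 mm^2 windows
  centers <- expand.grid(x = seq(-1, 1, win), y = seq(-1, 1, win))
  centers <- centers[sqrt(centers$x^2 + centers$y^2) + win < 1.2, ]
  h <- win / 2
  bright <- dens <- numeric(nrow(centers))
  for (i in seq_len(nrow(centers))) {
    sel_x <- ax >= centers$x[i] - h & ax < centers$x[i] + h
    sel_y <- ax >= centers$y[i] - h & ax < centers$y[i] + h
    bright[i] <- mean(mon$pixels[sel_x, sel_y])
    dens[i] <- sum(m$positions[, 1] >= centers$x[i] - h &
                   m$positions[, 1] < centers$x[i] + h &
                   m$positions[, 2] >= centers$y[i] - h &
                   m$positions[, 2] < centers$y[i] + h)
  }
  expect_gt(cor(bright, dens, method = "spearman"), 0.95)
})

test_that("renders are deterministic for a fixed mosaic and center", {
  m <- uniform_field_mosaic(5000, seed = 2)
  f1 <- render_field(m, c(0.01, -0.02))
  f2 <- render_field(m, c(0.01, -0.02))
  expect_identical(f1, f2)
  mon1 <- render_montage(m)
  mon2 <- render_montage(m)
  expect_identical(mon1, mon2)
})
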