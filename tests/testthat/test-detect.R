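test_that("noiseless well-separated spots are recovered with full recall and precision", {
  m <- grid_mosaic()  # 25 um spacing >> 4 sigma
  img <- render_field(m, c(0, 0), snr = Inf, background = 0)
  det <- detect_cones(img, detect_params(unit_amp = 1))
  expect_equal(nrow(det), 25)
  truth_um <- cbind(m$positions[, 1] * 1000 + 62.5,
                    m$positions[, 2] * 1000 + 62.5)
  for (i in seq_len(25)) {
    expect_lt(min(sqrt((det[, 1] - truth_um[i, 1])^2 +
                       (det[, 2] - truth_um[i, 2])^2)), 1)
  }
})

test_that("self-calibration matches the rendered spot amplitude on sparse and mid-density fields", {
  for (d in c(3000, 20000, 50000)) {
    m <- uniform_field_mosaic(d, seed = 31)
    det <- detect_cones(render_field(m, c(0, 0)))
    expect_lt(abs(attr(det, "unit_amp") - 1), 0.06)
  }
})

test_that("count error stays within 5% (median) across the published density range", {
  # Session-style calibration: the single-spot amplitude is pooled from a
  # sparse field acquired with the same settings, as in the pipeline's
  # two-pass scheme; per-field self-calibration is impossible at the
  # crowded end because nearly every spot overlaps a neighbour.
  cal_field <- render_field(uniform_field_mosaic(3000, seed = 100), c(0, 0))
  session <- field_unit_amp(cal_field)
  expect_true(is.finite(session$amp))
  params <- detect_params(unit_amp = session$amp)
  for (d in c(3000, 50000, 85000)) {
    errs <- vapply(1:20, function(s) {
      m <- uniform_field_mosaic(d, seed = 200 + s)
      img <- render_field(m, c(0, 0))
      truth <- cones_in_field(m, c(0, 0))
      100 * (nrow(detect_cones(img, params)) / truth - 1)
    }, numeric(1))
    expect_lt(abs(median(errs)), 5)
  }
})

test_that("detections are invariant to uniform intensity rescaling", {
  m <- uniform_field_mosaic(8000, seed = 41)
  img <- render_field(m, c(0, 0))
  det1 <- detect_cones(img)
  img$pixels <- img$pixels * 7.3
  det2 <- detect_cones(img)
  expect_equal(nrow(det1), nrow(det2))
  expect_equal(as.numeric(det1), as.numeric(det2), tolerance = 1e-8)
  # while the calibrated amplitude scales with the image
  expect_equal(attr(det2, "unit_amp") / attr(det1, "unit_amp"), 7.3,
               tolerance = 0.01)
})

test_that("degenerate fields are flagged, not fatal", {
  blank <- calibrated_image(matrix(0.2, 500, 500), 0.25)
  det <- detect_cones(blank)
  expect_equal(nrow(det), 0)
  expect_true("empty" %in% attr(det, "flags"))

  sat <- calibrated_image(matrix(1, 500, 500), 0.25)
  sat$pixels[1:100, 1:300] <- 0.4
  expect_warning(det2 <- detect_cones(sat), "saturated")
  expect_true("saturated" %in% attr(det2, "flags"))

  odd <- calibrated_image(matrix(0.2, 200, 200), 0.25)  # 50 um field
  expect_warning(detect_cones(odd), "deviates")
})

test_that("field_density applies exact area arithmetic", {
  expect_equal(field_density(0, 125), 0)
  expect_equal(field_density(781, 125), 49984)
  expect_equal(field_density(47, 125), 3008)
  expect_error(field_density(10, 0), "positive")
})

test_that("two fields at a location combine by the mean, with flag fallback", {
  fs <- function(density, flags = character(0)) {
    structure(list(location = c(0.1, 0.2), field_side = 125,
                   detections = NULL, count = density * 0.015625,
                   density = density, flags = flags),
              class = "field_sample")
  }
  expect_equal(combine_location(list(fs(10000), fs(12000)))$density, 11000)
  expect_equal(combine_location(list(fs(10000), fs(10000)))$density, 10000)
  one_bad <- combine_location(list(fs(10000), fs(44000, "saturated")))
  expect_equal(one_bad$density, 10000)
  expect_true("saturated" %in% one_bad$flags)
  both_bad <- combine_location(list(fs(1, "low_snr"), fs(2, "saturated")))
  expect_true(is.na(both_bad$density))
  bad_loc <- fs(5000)
  bad_loc$location <- c(9, 9)
  expect_error(combine_location(list(fs(5000), bad_loc)), "location")
})
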