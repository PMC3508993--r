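# Shared fixtures, all generated in code.

# A mosaic with cones on a regular grid (known positions, no randomness).
grid_mosaic <- function(spacing_mm = 0.025, n_side = 5, radius = 0.3) {
  half <- (n_side - 1) / 2 * spacing_mm
  pts <- as.matrix(expand.grid(x = seq(-half, half, spacing_mm),
                               y = seq(-half, half, spacing_mm)))
  structure(list(positions = pts, true_total = nrow(pts),
                 profile = make_density_profile("uniform", d_max = 1,
                                                retina_radius = radius),
                 seed = 1L, exclusion_radius = 0),
            class = "cone_mosaic")
}

# A uniform-density mosaic on a small disc, for detector benchmarks.
uniform_field_mosaic <- function(density, seed, radius = 0.25) {
  sample_mosaic(make_density_profile("uniform", d_max = density,
                                     retina_radius = radius),
                seed = seed)
}

# Disc outline mask as a single-region partition (13.2 mm^2 by default).
disc_partition <- function(radius_mm = 2.05, scale_um = 10) {
  npix <- ceiling(2 * radius_mm * 1000 / scale_um)
  ax <- ((seq_len(npix) - 0.5) * scale_um) / 1000 - radius_mm
  mask <- outer(ax, ax, function(x, y) sqrt(x^2 + y^2) <= radius_mm)
  labels <- matrix(0L, npix, npix)
  labels[mask] <- 1L
  conetop:::new_partition(labels, cbind(level_lo = 0, level_hi = 1),
                          scale_um, c(-radius_mm, -radius_mm), mask)
}

# Radial-gradient brightness map on a disc (deterministic).
gradient_map <- function(radius_mm = 1, scale_um = 10) {
  npix <- ceiling(2 * radius_mm * 1000 / scale_um)
  ax <- ((seq_len(npix) - 0.5) * scale_um) / 1000 - radius_mm
  r <- outer(ax, ax, function(x, y) sqrt(x^2 + y^2))
  mask <- r <= radius_mm
  px <- r / radius_mm
  px[!mask] <- NA_real_
  calibrated_image(px, scale_um, c(-radius_mm, -radius_mm), mask)
}

# Scaled-down rd10 profiles used by the seeded recovery suites: same density
# range and relative geometry as the full-size presets on a 1 mm radius disc.
scaled_overrides <- function(kind) {
  list(retina_radius = 1.0,
       scotoma_radius = if (kind == "rd10_st") 0.244 else 0.073)
}

quiet_pipeline <- function(...) {
  suppressWarnings(suppressMessages(run_pipeline(...)))
}
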