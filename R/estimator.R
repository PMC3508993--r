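#' Default wildtype reference cone count
#'
#' Whole-retina cone total of a normal mouse retina used to express
#' degenerating-retina totals as percent-of-wildtype. Exposed so users can
#' substitute their own reference.
#' @export
WILDTYPE_REFERENCE_TOTAL <- 180000

#' Place the meridian sampling scheme
#'
#' Places `2 * n_per_half` sampling locations on each of the two principal
#' meridians (dorso-ventral and naso-temporal): on every half-meridian,
#' `n_per_half` locations evenly spaced between the scotoma/center margin
#' and the retinal margin (with a buffer keeping each 125 um field fully
#' inside the outline). If an isodensity region ends up holding no
#' location, locations are shifted perpendicular to their meridian in
#' 25 um steps (up to `max_shift`) until every region is sampled; a
#' region that remains unreachable raises an error naming it.
#'
#' The inner margin (edge of the central cone-depleted zone) is
#' auto-detected as the first radius at which brightness exceeds a small
#' fraction of the dynamic range. The scan prefers a lightly smoothed
#' montage (25 um) over the brightness map, whose coarse smoothing blurs
#' the scotoma boundary outward; it can also be given explicitly via
#' `inner_margin`.
#'
#' @param partition an [trace_isodensity()] result.
#' @param map optional brightness map, for inner-margin auto-detection.
#' @param montage optional raw montage; when supplied the inner-margin
#'   scan uses it at fine smoothing for a sharper scotoma edge.
#' @param n_per_half locations per half-meridian (default 4, i.e. 16
#'   locations).
#' @param field_side field side, um.
#' @param inner_margin explicit inner radius, mm (overrides detection).
#' @param edge_buffer distance kept from the retinal margin, mm; by
#'   default the smallest buffer (plus 15 um safety) that keeps an
#'   axis-aligned field square fully inside a circular margin.
#' @param max_shift maximum perpendicular adjustment, mm.
#' @return an object of class `sampling_scheme`: `locations` data frame
#'   (`x`, `y`, `meridian`, `radius`, `region`), `field_side`,
#'   `fields_per_location`, `center`.
#' @export
make_sampling_scheme <- function(partition, map = NULL, montage = NULL,
                                 n_per_half = 4,
                                 field_side = 125, inner_margin = NULL,
                                 edge_buffer = NULL, max_shift = 0.2) {
  stopifnot(inherits(partition, "isodensity_partition"))
  mask <- partition$outline_mask
  px_mm <- partition$scale / 1000
  xs <- partition$origin[1] + (seq_len(nrow(mask)) - 0.5) * px_mm
  ys <- partition$origin[2] + (seq_len(ncol(mask)) - 0.5) * px_mm
  idx <- which(mask, arr.ind = TRUE)
  center <- c(mean(xs[idx[, 1]]), mean(ys[idx[, 2]]))
  dirs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  meridian <- c("naso-temporal", "naso-temporal",
                "dorso-ventral", "dorso-ventral")
  half_diag <- field_side * sqrt(2) / 2000 + 0.005
  step <- px_mm / 2

  ray_extent <- function(dir) {
    r <- 0
    while (region_at(partition, center[1] + (r + step) * dir[1],
                     center[2] + (r + step) * dir[2]) > 0) {
      r <- r + step
    }
    r
  }
  edge_img <- if (!is.null(montage)) {
    fine <- montage
    fine$pixels <- gauss_blur(montage$pixels,
                              max(1, 25 / montage$scale))
    fine
  } else {
    map
  }
  inner_edge <- function(dir) {
    if (!is.null(inner_margin)) return(inner_margin)
    if (is.null(edge_img)) return(0)
    v <- edge_img$pixels[edge_img$outline_mask]
    # dark reference: brightness at the retinal center, where the
    # cone-depleted zone of degenerating retinas sits; a healthy mosaic
    # is bright there, so no inner margin is detected
    cx <- floor((center[1] - edge_img$origin[1]) * 1000 / edge_img$scale) + 1
    cy <- floor((center[2] - edge_img$origin[2]) * 1000 / edge_img$scale) + 1
    rpx <- max(1, round(25 / edge_img$scale))
    lo <- mean(edge_img$pixels[(cx - rpx):(cx + rpx),
                               (cy - rpx):(cy + rpx)], na.rm = TRUE)
    hi <- quantile(v, 0.98, na.rm = TRUE)
    thr <- lo + 0.03 * (hi - lo)
    r <- 0
    r_first <- NA_real_
    run <- 0L
    repeat {
      p <- center + r * dir
      ix <- floor((p[1] - edge_img$origin[1]) * 1000 / edge_img$scale) + 1
      iy <- floor((p[2] - edge_img$origin[2]) * 1000 / edge_img$scale) + 1
      val <- edge_img$pixels[ix, iy]
      if (!is.na(val) && val >= thr) {
        if (run == 0L) r_first <- r
        run <- run + 1L
        # the crossing must persist over 25 um so a single noisy pixel
        # cannot fake a scotoma edge; the 25 um outward offset then keeps
        # the innermost field clear of the cone-free zone (the raw
        # crossing sits inside the smoothing smear)
        if (run * step >= 0.025) {
          return(if (r_first > 0) r_first + 0.025 else 0)
        }
      } else {
        run <- 0L
      }
      r <- r + step
      if (r > ray_extent(dir)) return(0)
    }
  }

  locs <- list()
  n_rays <- length(dirs)
  for (d in seq_along(dirs)) {
    dir <- dirs[[d]]
    r_ray <- ray_extent(dir)
    h <- field_side / 2000
    buf <- edge_buffer %||%
      (r_ray - (sqrt(max(r_ray^2 - h^2, 0)) - h) + 0.015)
    r_out <- r_ray - buf
    r_in <- inner_edge(dir) + half_diag
    if (r_out <= r_in) {
      stopf("half-meridian %d too short to place %d fields", d, n_per_half)
    }
    # stagger the radii across the four half-meridians so the 16 locations
    # stratify the whole radial span (shared radii could never cover more
    # annular regions than there are radii per ray); the first ray keeps a
    # location at the inner margin and the last one at the outer margin
    fracs <- (seq_len(n_per_half) - 1 + (d - 1) / n_rays) /
      (n_per_half - 1 + (n_rays - 1) / n_rays)
    radii <- r_in + fracs * (r_out - r_in)
    for (r in radii) {
      locs[[length(locs) + 1]] <- data.frame(
        x = center[1] + r * dir[1], y = center[2] + r * dir[2],
        meridian = meridian[d], radius = r,
        dir_x = dir[1], dir_y = dir[2])
    }
  }
  locs <- do.call(rbind, locs)
  locs$region <- region_at(partition, locs$x, locs$y)

  field_inside <- function(x, y) {
    h <- field_side / 2000
    cx <- c(x - h, x - h, x + h, x + h)
    cy <- c(y - h, y + h, y - h, y + h)
    all(region_at(partition, cx, cy) > 0)
  }
  missing_regions <- setdiff(seq_len(partition$n_levels), locs$region)
  for (reg in missing_regions) {
    moved <- FALSE
    for (off in seq(0.025, max_shift, by = 0.025)) {
      for (i in order(-locs$radius)) {
        # shifts perpendicular to the meridian are tried first (least
        # disturbance to the radial spacing), then diagonal and radial
        perp <- c(-locs$dir_y[i], locs$dir_x[i])
        rad <- c(locs$dir_x[i], locs$dir_y[i])
        dirs8 <- list(perp, -perp,
                      (perp + rad) / sqrt(2), (perp - rad) / sqrt(2),
                      (-perp + rad) / sqrt(2), (-perp - rad) / sqrt(2),
                      -rad, rad)
        for (dd in dirs8) {
          nx <- locs$x[i] + off * dd[1]
          ny <- locs$y[i] + off * dd[2]
          if (region_at(partition, nx, ny) == reg &&
              sum(locs$region == locs$region[i]) > 1 &&
              field_inside(nx, ny)) {
            locs$x[i] <- nx; locs$y[i] <- ny; locs$region[i] <- reg
            moved <- TRUE
            break
          }
        }
        if (moved) break
      }
      if (moved) break
    }
    if (!moved) {
      stopf("isodensity region %d is unreachable from the meridians (max shift %.0f um)",
            reg, max_shift * 1000)
    }
  }
  locs$dir_x <- NULL
  locs$dir_y <- NULL
  structure(list(locations = locs, field_side = field_side,
                 fields_per_location = 2, center = center),
            class = "sampling_scheme")
}

#' Per-region densities from sampled location densities
#'
#' Each region's density is the arithmetic mean of the densities measured
#' at the sampling locations falling inside it.
#'
#' @param scheme a [make_sampling_scheme()] result.
#' @param location_densities numeric vector, cones/mm^2, one per scheme
#'   location (NA allowed for flagged locations, which are dropped with a
#'   warning).
#' @param partition the matching `isodensity_partition`.
#' @return numeric vector of length `partition$n_levels`.
#' @export
region_density <- function(scheme, location_densities, partition) {
  locs <- scheme$locations
  stopifnot(length(location_densities) == nrow(locs))
  if (anyNA(location_densities)) {
    warnf("%d flagged location(s) dropped from region densities",
          sum(is.na(location_densities)))
  }
  out <- numeric(partition$n_levels)
  for (reg in seq_len(partition$n_levels)) {
    d <- location_densities[locs$region == reg]
    d <- d[!is.na(d)]
    if (!length(d)) stopf("isodensity region %d has no sampled density", reg)
    out[reg] <- mean(d)
  }
  out
}

#' Area-weighted total cone estimate
#'
#' The whole-mount total is the sum over isodensity regions of region
#' density times region area, i.e. a stratified estimator with the
#' regions as strata.
#'
#' @param partition an `isodensity_partition`.
#' @param region_densities cones/mm^2, one per region (dark to bright).
#' @param scheme optional `sampling_scheme`, used to report the sampled
#'   area and sampling fraction.
#' @param reference_total optional wildtype reference count; when given,
#'   the estimate also carries percent-of-wildtype.
#' @return an object of class `total_estimate` with `per_region` (data
#'   frame: region, density, area, contribution), `total`,
#'   `sampled_area_mm2`, `sampling_fraction_pct`, `percent_of_wildtype`.
#' @export
estimate_total <- function(partition, region_densities, scheme = NULL,
                           reference_total = NULL) {
  stopifnot(inherits(partition, "isodensity_partition"))
  if (length(region_densities) != partition$n_levels ||
      anyNA(region_densities)) {
    stopf("need one non-missing density per isodensity region")
  }
  if (any(region_densities < 0)) stopf("region densities must be >= 0")
  areas <- partition$areas_mm2
  contrib <- region_densities * areas
  per_region <- data.frame(region = seq_len(partition$n_levels),
                           density_mm2 = region_densities,
                           area_mm2 = areas, contribution = contrib)
  total <- sum(contrib)
  sampled_area <- sampling_fraction_pct <- NA_real_
  if (!is.null(scheme)) {
    n_fields <- nrow(scheme$locations) * scheme$fields_per_location
    sampled_area <- n_fields * (scheme$field_side / 1000)^2
    sampling_fraction_pct <- sampling_fraction(scheme, outline_area(partition))
  }
  pw <- if (!is.null(reference_total)) {
    percent_of_wildtype(total, reference_total)
  }
  structure(list(per_region = per_region, total = total,
                 sampled_area_mm2 = sampled_area,
                 sampling_fraction_pct = sampling_fraction_pct,
                 percent_of_wildtype = pw),
            class = "total_estimate")
}

#' Sampled fraction of the retinal surface
#'
#' @param scheme a `sampling_scheme`.
#' @param outline_area_mm2 whole-mount area, mm^2.
#' @return percent of the outline covered by the sampling fields:
#'   `100 * n_fields * (field_side/1000)^2 / outline_area_mm2`.
#' @examples
#' # 32 fields of 125x125 um on a 13.2 mm^2 whole mount ~ 3.8%
#' @export
sampling_fraction <- function(scheme, outline_area_mm2) {
  stopifnot(outline_area_mm2 > 0)
  n_fields <- nrow(scheme$locations) * scheme$fields_per_location
  100 * n_fields * (scheme$field_side / 1000)^2 / outline_area_mm2
}

#' Express a cone total as percent of the wildtype reference
#'
#' @param total estimated cone count.
#' @param reference_total wildtype whole-retina cone count (> 0).
#' @return list with `ratio_pct` (raw percentage), `percent` (nearest
#'   integer) and `label` (e.g. `"56%"`).
#' @examples
#' percent_of_wildtype(100000, 180000)$label  # "56%"
#' percent_of_wildtype(80000, 180000)$label   # "44%"
#' @export
percent_of_wildtype <- function(total, reference_total = WILDTYPE_REFERENCE_TOTAL) {
  if (!is.numeric(reference_total) || reference_total <= 0) {
    stopf("reference_total must be positive")
  }
  ratio <- 100 * total / reference_total
  list(ratio_pct = ratio, percent = as.integer(round(ratio)),
       label = sprintf("%d%%", as.integer(round(ratio))))
}

#' @export
print.sampling_scheme <- function(x, ...) {
  cat(sprintf(
    "<sampling_scheme>  %d locations x %d fields of %.0f um, center (%.2f, %.2f) mm\n",
    nrow(x$locations), x$fields_per_location, x$field_side,
    x$center[1], x$center[2]))
  invisible(x)
}

#' @export
print.total_estimate <- function(x, ...) {
  cat("<total_estimate>\n")
  print(x$per_region, row.names = FALSE)
  cat(sprintf("  total: %s cones\n", format(round(x$total), big.mark = ",")))
  if (!is.na(x$sampling_fraction_pct)) {
    cat(sprintf("  sampled area: %.3g mm^2 (%.2f%% of the whole mount)\n",
                x$sampled_area_mm2, x$sampling_fraction_pct))
  }
  if (!is.null(x$percent_of_wildtype)) {
    cat(sprintf("  percent of wildtype: %s (raw %.1f%%)\n",
                x$percent_of_wildtype$label, x$percent_of_wildtype$ratio_pct))
  }
  invisible(x)
}
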