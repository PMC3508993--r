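#' Build a smoothed brightness map from a whole-mount montage
#'
#' Brightness on a cone-opsin-stained whole mount is a monotone proxy for
#' local cone density. The montage is background-corrected with a
#' rolling-ball-style grey opening (square structuring element at
#' `bg_scale`), then smoothed at a stated physical scale with a
#' mask-normalized Gaussian (so tissue near the outline is not dimmed by
#' the empty surround). Pixels outside the outline are `NA`.
#'
#' The map is linear in the input: scaling all montage intensities by a
#' constant scales the map by the same constant.
#'
#' @param montage a [calibrated_image()] with an outline mask.
#' @param smooth_scale Gaussian smoothing s.d., um (must be at least 2
#'   pixels at the montage scale).
#' @param bg_scale background structuring-element half-width, um; `0`
#'   disables background correction.
#' @return a [calibrated_image()] holding the map.
#' @export
build_brightness_map <- function(montage, smooth_scale = 100,
                                 bg_scale = 500) {
  stopifnot(inherits(montage, "calibrated_image"))
  mask <- montage$outline_mask
  if (!any(mask)) stopf("montage outline mask is empty")
  sigma_px <- smooth_scale / montage$scale
  if (sigma_px < 2) {
    stopf("smoothing scale %.0f um is below 2 pixels at %.3g um/px",
          smooth_scale, montage$scale)
  }
  img <- montage$pixels
  if (bg_scale > 0) {
    r_px <- max(1L, as.integer(round(bg_scale / montage$scale / 2)))
    img <- img - cpp_box_open(img, r_px)
  }
  m <- mask * 1
  num <- gauss_blur(img * m, sigma_px)
  den <- gauss_blur(m, sigma_px)
  sm <- num / pmax(den, 1e-12)
  sm[!mask] <- NA_real_
  calibrated_image(sm, montage$scale, montage$origin, mask)
}

#' Threshold cone-rich clusters on a brightness map
#'
#' Applies Otsu's between-class-variance threshold to the masked map
#' values; foreground pixels are the cone-rich clusters. A degenerate
#' (constant) map returns the whole outline as foreground with a warning
#' rather than failing.
#'
#' @param map a [build_brightness_map()] result.
#' @param n_bins histogram resolution for the threshold search.
#' @return logical matrix, `TRUE` on cone-rich pixels inside the outline;
#'   the threshold is attached as attribute `threshold`.
#' @export
threshold_clusters <- function(map, n_bins = 256) {
  stopifnot(inherits(map, "calibrated_image"))
  mask <- map$outline_mask
  v <- map$pixels[mask]
  if (diff(range(v)) == 0) {
    warnf("brightness map is constant; returning the whole outline as foreground")
    fg <- mask
    attr(fg, "threshold") <- v[1]
    return(fg)
  }
  thr <- otsu_threshold(v, n_bins)
  fg <- map$pixels > thr & mask
  fg[is.na(fg)] <- FALSE
  attr(fg, "threshold") <- thr
  fg
}

# Otsu's method on a fixed-bin histogram of the masked values.
otsu_threshold <- function(v, n_bins = 256) {
  rng <- range(v)
  h <- tabulate(pmin(pmax(findInterval(
    v, seq(rng[1], rng[2], length.out = n_bins + 1),
    rightmost.closed = TRUE), 1L), n_bins), nbins = n_bins)
  p <- h / sum(h)
  mids <- (seq_len(n_bins) - 0.5) / n_bins * diff(rng) + rng[1]
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between[-n_bins])]
}

#' Partition a brightness map into isodensity regions
#'
#' Divides the masked intensity range into `n_levels` quantile
#' (equal-pixel-mass) bins; each bin's pixels form one region, ordered
#' dark to bright. Regions may be multiply connected (a level can occur
#' in several patches), matching the patchy topography of degenerating
#' mosaics. The regions partition the outline exactly: every masked
#' pixel belongs to exactly one region, so region areas always sum to
#' the outline area.
#'
#' @param map a [build_brightness_map()] result.
#' @param n_levels number of isodensity levels (>= 1).
#' @return an object of class `isodensity_partition`: `labels` (integer
#'   matrix, 0 outside the outline), `level_bounds` (n x 2), `areas_mm2`,
#'   `n_levels`, `scale`, `origin`, `outline_mask`.
#' @export
trace_isodensity <- function(map, n_levels = 5) {
  stopifnot(inherits(map, "calibrated_image"))
  if (n_levels < 1) stopf("n_levels must be >= 1")
  mask <- map$outline_mask
  v <- map$pixels[mask]
  if (n_levels > length(unique(v))) {
    stopf("n_levels (%d) exceeds the number of distinct map intensities (%d)",
          n_levels, length(unique(v)))
  }
  # quantile (equal-pixel-mass) binning via mid-ranks: tied intensities
  # always share a region, so a step map splits exactly at its steps
  u <- (rank(v, ties.method = "average") - 0.5) / length(v)
  lab_v <- pmin(pmax(as.integer(floor(u * n_levels)) + 1L, 1L), n_levels)
  counts <- tabulate(lab_v, nbins = n_levels)
  if (any(counts == 0)) {
    stopf("quantile levels collapse (heavily tied intensities); reduce n_levels")
  }
  labels <- matrix(0L, nrow(map$pixels), ncol(map$pixels))
  labels[mask] <- lab_v
  bounds <- cbind(level_lo = vapply(1:n_levels,
                                    function(k) min(v[lab_v == k]),
                                    numeric(1)),
                  level_hi = vapply(1:n_levels,
                                    function(k) max(v[lab_v == k]),
                                    numeric(1)))
  new_partition(labels, bounds, map$scale, map$origin, mask)
}

# Validating constructor shared by trace_isodensity and tests.
new_partition <- function(labels, level_bounds, scale, origin, mask) {
  n_levels <- nrow(level_bounds)
  counts <- tabulate(labels[mask], nbins = n_levels)
  if (any(counts == 0)) stopf("isodensity partition has an empty region")
  if (any(labels[mask] < 1L) || any(labels[!mask] != 0L)) {
    stopf("labels must cover the outline exactly (1..n inside, 0 outside)")
  }
  structure(list(labels = labels, level_bounds = level_bounds,
                 areas_mm2 = counts * (scale / 1000)^2,
                 n_levels = n_levels, scale = scale, origin = origin,
                 outline_mask = mask),
            class = "isodensity_partition")
}

#' Region areas of an isodensity partition
#'
#' Areas are pixel counts times the squared pixel size; by construction
#' they sum exactly (in pixel units) to the outline area.
#'
#' @param partition an [trace_isodensity()] result.
#' @param scale um/pixel; defaults to the partition's own scale.
#' @return numeric vector of areas, mm^2, ordered dark to bright.
#' @export
region_areas <- function(partition, scale = partition$scale) {
  counts <- tabulate(partition$labels[partition$outline_mask],
                     nbins = partition$n_levels)
  counts * (scale / 1000)^2
}

#' Outline area of a partition, mm^2
#' @param partition an `isodensity_partition`.
#' @export
outline_area <- function(partition) {
  sum(partition$outline_mask) * (partition$scale / 1000)^2
}

#' Region label at retina coordinates
#'
#' @param partition an `isodensity_partition`.
#' @param x,y retina-centered coordinates, mm (vectorized).
#' @return integer region labels (0 outside the outline).
#' @export
region_at <- function(partition, x, y) {
  ix <- floor((x - partition$origin[1]) * 1000 / partition$scale) + 1L
  iy <- floor((y - partition$origin[2]) * 1000 / partition$scale) + 1L
  n <- dim(partition$labels)
  out <- integer(length(ix))
  ok <- ix >= 1 & ix <= n[1] & iy >= 1 & iy <= n[2]
  out[ok] <- partition$labels[cbind(ix[ok], iy[ok])]
  out
}

#' Isodensity boundary curves
#'
#' Extracts the level curves separating adjacent regions as polylines in
#' retina-centered mm coordinates (the digital equivalent of manually
#' traced isodensity curves).
#'
#' @param map the brightness map the partition was traced from.
#' @param partition the matching `isodensity_partition`.
#' @return a list of data frames (`x`, `y`, mm) with a `level` attribute
#'   each.
#' @export
isodensity_curves <- function(map, partition) {
  m <- map$pixels
  v <- m[map$outline_mask]
  m[!map$outline_mask] <- min(v) - diff(range(v)) * 0.05 - 1e-9
  levels <- partition$level_bounds[-1, "level_lo"]
  cl <- contourLines(x = image_axis(map, 1), y = image_axis(map, 2),
                     z = m, levels = levels)
  lapply(cl, function(ln) {
    structure(data.frame(x = ln$x, y = ln$y), level = ln$level)
  })
}

#' Export isodensity curves as GeoJSON
#'
#' @param curves an [isodensity_curves()] result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
curves_to_geojson <- function(curves, path) {
  features <- lapply(curves, function(cu) {
    list(type = "Feature",
         properties = list(level = attr(cu, "level")),
         geometry = list(type = "LineString",
                         coordinates = mapply(c, cu$x, cu$y,
                                              SIMPLIFY = FALSE)))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features), path,
    auto_unbox = TRUE, digits = 6)
  invisible(path)
}

#' @export
print.isodensity_partition <- function(x, ...) {
  cat(sprintf("<isodensity_partition>  %d levels over %.2f mm^2\n",
              x$n_levels, outline_area(x)))
  for (i in seq_len(x$n_levels)) {
    cat(sprintf("  region %d: [%.3g, %.3g) -> %.3f mm^2\n", i,
                x$level_bounds[i, 1], x$level_bounds[i, 2], x$areas_mm2[i]))
  }
  invisible(x)
}
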