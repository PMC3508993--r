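#' Default pipeline configuration
#'
#' All tunable parameters of a simulate-count-map-estimate run in one
#' place. Any subset can be overridden; unknown names are rejected.
#'
#' @param profile profile kind passed to [make_density_profile()].
#' @param profile_overrides named list of profile overrides.
#' @param seed integer master seed; recorded in every output.
#' @param exclusion_radius hard-core spacing, um.
#' @param montage_scale,field_scale raster scales, um/pixel.
#' @param spot_sigma rendered/expected spot s.d., um.
#' @param snr acquisition signal-to-noise ratio.
#' @param n_levels number of isodensity levels.
#' @param smooth_scale,bg_scale brightness-map scales, um.
#' @param detection a [detect_params()] list.
#' @param reference_total wildtype reference count, or `NULL` to omit
#'   percent-of-wildtype.
#' @param field_side field side, um.
#' @return a list of class `run_config`.
#' @export
run_config <- function(profile = "rd10_st", profile_overrides = list(),
                       seed = 1, exclusion_radius = 1.5,
                       montage_scale = 10, field_scale = 0.25,
                       spot_sigma = 1.2, snr = 10, n_levels = 5,
                       smooth_scale = 100, bg_scale = 500,
                       detection = detect_params(),
                       reference_total = WILDTYPE_REFERENCE_TOTAL,
                       field_side = 125) {
  structure(as.list(environment()), class = "run_config")
}

#' Load a pipeline configuration from JSON or YAML
#'
#' Unset fields fall back to the [run_config()] defaults (echoed in the
#' run log).
#'
#' @param path `.json`, `.yml` or `.yaml` file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stopf("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    stopf("unsupported config format: %s", path)
  }
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stopf("unknown config fields: %s", paste(bad, collapse = ", "))
  if (!is.null(raw$detection)) raw$detection <- do.call(detect_params, raw$detection)
  do.call(run_config, raw)
}

#' Render and count the two fields at every sampling location
#'
#' For each scheme location, renders `fields_per_location` images of the
#' same field box with independent acquisition noise, counts each with
#' [count_field()], and combines them by [combine_location()].
#'
#' Counting runs in two passes. The first pass self-calibrates the
#' single-spot amplitude on every field; a session consensus (median over
#' fields with a trustworthy calibration, i.e. enough isolated
#' shape-validated spots) is then applied uniformly in a second pass.
#' This mirrors configuring the counting routine once per acquisition
#' session: fields at the crowded end of the density range, where
#' isolated spots are too rare to calibrate on, inherit the calibration
#' from sparser fields taken with the same settings.
#'
#' @param mosaic a [sample_mosaic()] result.
#' @param scheme a [make_sampling_scheme()] result.
#' @param config a [run_config()].
#' @return data frame with one row per location: coordinates, meridian,
#'   region, per-field counts, combined density, flags, plus the
#'   ground-truth count (for recovery checks on synthetic data). The
#'   consensus amplitude is attached as attribute `session_unit_amp`.
#' @export
count_scheme_fields <- function(mosaic, scheme, config = run_config()) {
  locs <- scheme$locations
  det <- config$detection
  det$spot_sigma <- config$spot_sigma
  render_one <- function(i, k) {
    center <- c(locs$x[i], locs$y[i])
    img <- render_field(mosaic, center, field_side = scheme$field_side,
                        scale = config$field_scale,
                        spot_sigma = config$spot_sigma, snr = config$snr)
    # the two acquisitions differ by their noise realization
    if (k > 1 && is.finite(config$snr)) {
      nseed <- derive_seed(mosaic$seed, i, k)
      npix <- nrow(img$pixels)
      img$pixels <- pmax(
        img$pixels + with_seed(nseed, matrix(
          rnorm(npix^2, 0, 1 / config$snr) -
            rnorm(npix^2, 0, 1 / config$snr), npix, npix)), 0)
    }
    img
  }
  session_amp <- NULL
  if (is.null(det$unit_amp)) {
    amps <- numeric(0)
    for (i in seq_len(nrow(locs))) {
      cal <- field_unit_amp(render_one(i, 1), det)
      if (is.finite(cal$amp) && cal$n >= 10) amps <- c(amps, cal$amp)
    }
    if (length(amps) >= 3) {
      session_amp <- median(amps)
      det$unit_amp <- session_amp
    }
  }
  rows <- lapply(seq_len(nrow(locs)), function(i) {
    center <- c(locs$x[i], locs$y[i])
    samples <- lapply(seq_len(scheme$fields_per_location), function(k) {
      count_field(render_one(i, k), center, det)
    })
    comb <- combine_location(samples)
    data.frame(x = center[1], y = center[2], meridian = locs$meridian[i],
               region = locs$region[i],
               count_1 = samples[[1]]$count, count_2 = samples[[2]]$count,
               density_mm2 = comb$density,
               truth_count = cones_in_field(mosaic, center,
                                            scheme$field_side),
               flags = paste(comb$flags, collapse = ";"))
  })
  out <- do.call(rbind, rows)
  attr(out, "session_unit_amp") <- session_amp
  out
}

#' Run the whole estimation pipeline on a synthetic retina
#'
#' Executes simulate -> montage -> brightness map -> isodensity partition
#' -> meridian sampling -> field counting -> stratified total, and
#' optionally writes a consolidated report. Identical config and seed
#' reproduce identical results.
#'
#' @param config a [run_config()], or a path accepted by
#'   [read_run_config()].
#' @param out_dir output directory for [write_report()]; `NULL` skips
#'   writing.
#' @return a list of class `pipeline_result` with `config`, `mosaic`,
#'   `montage`, `map`, `clusters`, `partition`, `scheme`, `fields`,
#'   `region_densities`, `estimate`, `summary` and `log`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message("[conetop] ", msg)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
    say("%s: %.2fs", name, proc.time()[["elapsed"]] - t0)
    out
  }
  say("profile=%s seed=%d n_levels=%d montage=%gum/px field=%gum/px snr=%g",
      config$profile, config$seed, config$n_levels, config$montage_scale,
      config$field_scale, config$snr)
  profile <- do.call(make_density_profile,
                     c(list(kind = config$profile), config$profile_overrides))
  mosaic <- stage("simulate", sample_mosaic(profile, config$seed,
                                            config$exclusion_radius))
  say("mosaic: %d cones (expected %.0f)", mosaic$true_total,
      profile_expected_count(profile))
  montage <- stage("montage", render_montage(mosaic, config$montage_scale,
                                             snr = config$snr))
  map <- stage("map", build_brightness_map(montage, config$smooth_scale,
                                           config$bg_scale))
  clusters <- stage("threshold", threshold_clusters(map))
  partition <- stage("partition", trace_isodensity(map, config$n_levels))
  scheme <- stage("scheme", make_sampling_scheme(
    partition, map, montage, field_side = config$field_side))
  fields <- stage("count", count_scheme_fields(mosaic, scheme, config))
  region_densities <- region_density(scheme, fields$density_mm2, partition)
  estimate <- estimate_total(partition, region_densities, scheme,
                             config$reference_total)
  say("total=%.0f truth=%d (error %+.1f%%)", estimate$total,
      mosaic$true_total,
      100 * (estimate$total / mosaic$true_total - 1))
  summary <- list(
    profile = config$profile, seed = config$seed,
    n_levels = partition$n_levels,
    outline_area_mm2 = outline_area(partition),
    sampled_area_mm2 = estimate$sampled_area_mm2,
    sampling_fraction_pct = estimate$sampling_fraction_pct,
    total = estimate$total,
    true_total = mosaic$true_total,
    min_location_density = min(fields$density_mm2, na.rm = TRUE),
    max_location_density = max(fields$density_mm2, na.rm = TRUE),
    percent_of_wildtype = estimate$percent_of_wildtype$ratio_pct,
    percent_of_wildtype_label = estimate$percent_of_wildtype$label)
  res <- structure(list(config = config, mosaic = mosaic, montage = montage,
                        map = map, clusters = clusters,
                        partition = partition, scheme = scheme,
                        fields = fields,
                        region_densities = region_densities,
                        estimate = estimate, summary = summary, log = log),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_report(res, out_dir)
  res
}

#' Write the consolidated pipeline report
#'
#' Emits `summary.json`, `estimate.csv` (per-region densities, areas and
#' contributions), `fields.csv` (per-location counts), the partition as
#' an indexed-label TIFF, isodensity curves as GeoJSON, an overlay TIFF
#' (montage with region boundaries and the 16 sampling locations burned
#' in, for visual QC) and `run.log`.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(result$summary, p, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths <- c(paths, p)
  p <- file.path(dir, "estimate.csv")
  est <- result$estimate$per_region
  names(est) <- c("region_id", "density_mm2", "area_mm2", "contribution")
  write.csv(est, p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "fields.csv")
  write.csv(result$fields, p, row.names = FALSE)
  paths <- c(paths, p)
  part <- result$partition
  p <- file.path(dir, "partition_labels.tif")
  lab <- calibrated_image(part$labels + 0, part$scale, part$origin,
                          part$outline_mask)
  write_image_tiff(lab, p, max_value = part$n_levels)
  paths <- c(paths, p)
  p <- file.path(dir, "isodensity_curves.geojson")
  curves_to_geojson(isodensity_curves(result$map, part), p)
  paths <- c(paths, p)
  p <- file.path(dir, "overlay.tif")
  write_image_tiff(render_overlay(result), p)
  paths <- c(paths, p)
  p <- file.path(dir, "run.log")
  writeLines(result$log, p)
  paths <- c(paths, p)
  invisible(paths)
}

# Montage with isodensity boundaries and sampling locations burned in.
render_overlay <- function(result) {
  mon <- result$montage
  img <- mon$pixels / max(mon$pixels)
  lab <- result$partition$labels
  edge <- lab != 0 &
    (rbind(lab[-1, ], 0L) != lab | rbind(0L, lab[-nrow(lab), ]) != lab |
     cbind(lab[, -1], 0L) != lab | cbind(0L, lab[, -ncol(lab)]) != lab)
  img[edge] <- 1
  locs <- result$scheme$locations
  n <- dim(img)
  for (i in seq_len(nrow(locs))) {
    ix <- floor((locs$x[i] - mon$origin[1]) * 1000 / mon$scale) + 1
    iy <- floor((locs$y[i] - mon$origin[2]) * 1000 / mon$scale) + 1
    xs <- pmax(1, pmin(n[1], (ix - 3):(ix + 3)))
    ys <- pmax(1, pmin(n[2], (iy - 3):(iy + 3)))
    img[xs, iy] <- 1
    img[ix, ys] <- 1
  }
  calibrated_image(img, mon$scale, mon$origin, mon$outline_mask)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result>  profile '%s', seed %d\n",
              x$config$profile, x$config$seed))
  print(x$estimate)
  invisible(x)
}
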