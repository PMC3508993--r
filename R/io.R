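#' Write a calibrated image as 16-bit grayscale TIFF
#'
#' Intensities are scaled by `max_value` (default: the image maximum) to
#' [0, 1] and quantized to 16 bits. The quantization scale and the
#' physical pixel size are returned so datasets can record them in their
#' sidecar manifest (where [read_image_tiff()] recovers them from).
#'
#' @param img a [calibrated_image()].
#' @param path output file.
#' @param max_value intensity mapped to the top of the 16-bit range.
#' @return invisibly, a list with `path`, `max_value` and `scale`.
#' @export
write_image_tiff <- function(img, path, max_value = NULL) {
  max_value <- max_value %||% max(img$pixels)
  if (max_value <= 0) max_value <- 1
  q <- pmin(pmax(img$pixels / max_value, 0), 1)
  # tiff expects row-major [y, x]; our images are [x, y]
  tiff::writeTIFF(t(q), path, bits.per.sample = 16, compression = "none",
                  reduce = FALSE)
  invisible(list(path = path, max_value = max_value, scale = img$scale))
}

#' Read a calibrated image from a 16-bit grayscale TIFF
#'
#' Inverts [write_image_tiff()]: pixel values are rescaled by
#' `max_value`, and the physical pixel size is taken from `scale` (both
#' are recorded in a dataset's manifest at write time).
#'
#' @param path TIFF file.
#' @param max_value intensity scale recorded at write time.
#' @param scale um/pixel.
#' @param origin corner position of pixel (1,1), mm.
#' @return a [calibrated_image()].
#' @export
read_image_tiff <- function(path, max_value = 1, scale = 1,
                            origin = c(0, 0)) {
  q <- tiff::readTIFF(path)
  calibrated_image(t(q) * max_value, scale = scale, origin = origin)
}

#' Write a complete synthetic dataset to disk
#'
#' Writes the montage and each field as 16-bit grayscale TIFF, the
#' ground-truth cone positions as CSV (`x_mm,y_mm`), the generator
#' parameters and seed as JSON, and a manifest listing every file.
#'
#' @param mosaic a [sample_mosaic()] result.
#' @param montage a [render_montage()] image.
#' @param fields named list of field images ([render_field()]).
#' @param dir output directory, created if needed.
#' @return invisibly, the manifest data frame.
#' @export
write_dataset <- function(mosaic, montage, fields, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  add <- function(file, kind, max_value = NA, scale = NA) {
    rows[[length(rows) + 1]] <<- data.frame(
      file = file, kind = kind, max_value = max_value, scale = scale)
  }
  m <- write_image_tiff(montage, file.path(dir, "montage.tif"))
  add("montage.tif", "montage", m$max_value, m$scale)
  names(fields) <- names(fields) %||% sprintf("field_%03d", seq_along(fields))
  for (nm in names(fields)) {
    f <- write_image_tiff(fields[[nm]], file.path(dir, paste0(nm, ".tif")))
    add(paste0(nm, ".tif"), "field", f$max_value, f$scale)
  }
  truth <- data.frame(x_mm = mosaic$positions[, 1],
                      y_mm = mosaic$positions[, 2])
  write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  add("truth.csv", "truth")
  params <- list(
    profile = unclass(mosaic$profile), seed = mosaic$seed,
    exclusion_radius_um = mosaic$exclusion_radius,
    true_total = mosaic$true_total,
    field_origins = lapply(fields, function(f) f$origin))
  jsonlite::write_json(params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  add("params.json", "params")
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
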