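#' Calibrated images
#'
#' A minimal raster container: a nonnegative intensity matrix in `[x, y]`
#' order, a physical pixel size (`scale`, um/pixel), the retina-centered
#' position of the corner of pixel (1,1) (`origin`, mm; pixel centers sit
#' half a pixel in from the corner), and a logical `outline_mask` of the
#' same shape marking tissue pixels.
#'
#' @param pixels numeric matrix, `[x, y]` order.
#' @param scale um/pixel, positive.
#' @param origin length-2 numeric, mm.
#' @param outline_mask logical matrix, same shape as `pixels`; default all
#'   `TRUE`.
#' @return an object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, scale, origin = c(0, 0),
                             outline_mask = NULL) {
  stopifnot(is.matrix(pixels), is.numeric(scale), scale > 0)
  if (is.null(outline_mask)) {
    outline_mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  }
  stopifnot(identical(dim(pixels), dim(outline_mask)))
  structure(list(pixels = pixels, scale = scale, origin = as.numeric(origin),
                 outline_mask = outline_mask),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf(
    "<calibrated_image>  %d x %d px at %.3g um/px (%.2f x %.2f mm), origin (%.2f, %.2f) mm\n",
    nrow(x$pixels), ncol(x$pixels), x$scale,
    nrow(x$pixels) * x$scale / 1000, ncol(x$pixels) * x$scale / 1000,
    x$origin[1], x$origin[2]))
  invisible(x)
}

# mm coordinates of pixel centers along each axis
image_axis <- function(img, axis = 1) {
  n <- dim(img$pixels)[axis]
  img$origin[axis] + ((seq_len(n) - 0.5) * img$scale) / 1000
}

#' Render a high-resolution field image
#'
#' Renders every mosaic cone whose center lies inside the requested square
#' field as an isotropic Gaussian spot of peak amplitude 1 (arbitrary
#' units) on a constant background, with additive Gaussian read noise at
#' the stated peak signal-to-noise ratio. The field must lie fully inside
#' the retinal outline, mirroring the constraint on real confocal
#' sampling.
#'
#' @param mosaic a [sample_mosaic()] result.
#' @param center field center, mm (length 2).
#' @param field_side field side, um.
#' @param scale um/pixel.
#' @param spot_sigma Gaussian spot s.d., um (confocal-scale blur of a cone
#'   outer segment).
#' @param snr peak amplitude / noise s.d.; `Inf` for noiseless renders.
#' @param background constant offset, same units as spot amplitude.
#' @return a [calibrated_image()]; the acquisition-noise seed is derived
#'   from the mosaic seed and the field center so renders are reproducible.
#' @export
render_field <- function(mosaic, center, field_side = 125, scale = 0.25,
                         spot_sigma = 1.2, snr = 10, background = 0.2) {
  R <- mosaic$profile$retina_radius
  h <- field_side / 2000
  corners <- rbind(center + c(-h, -h), center + c(-h, h),
                   center + c(h, -h), center + c(h, h))
  if (any(sqrt(rowSums(corners^2)) > R)) {
    stopf("field at (%.2f, %.2f) mm extends past the retinal outline",
          center[1], center[2])
  }
  npix <- round(field_side / scale)
  p <- mosaic$positions
  inside <- p[, 1] >= center[1] - h & p[, 1] < center[1] + h &
            p[, 2] >= center[2] - h & p[, 2] < center[2] + h
  px <- (p[inside, 1] - (center[1] - h)) * 1000 / scale
  py <- (p[inside, 2] - (center[2] - h)) * 1000 / scale
  img <- cpp_render_spots(px, py, spot_sigma / scale, 1, npix, npix)
  img <- img + background
  if (is.finite(snr)) {
    nseed <- derive_seed(mosaic$seed, round(center[1] * 1e4),
                         round(center[2] * 1e4), npix)
    img <- img + with_seed(nseed, matrix(rnorm(npix^2, 0, 1 / snr),
                                         npix, npix))
    img[img < 0] <- 0
  }
  calibrated_image(img, scale, origin = center - h)
}

#' Render a whole-mount montage
#'
#' Emulates the low-resolution tiled overview of a stained whole mount:
#' cones are binned into coarse pixels and blurred so that individual
#' cells merge into local brightness, making pixel intensity a monotone
#' increasing function of local cone density (bright cone-rich areas
#' alternating with dark depleted zones). Additive Gaussian read noise is
#' applied at the stated SNR relative to the brightest tissue.
#'
#' @param mosaic a [sample_mosaic()] result.
#' @param scale um/pixel; should be coarse enough that single cones blur
#'   together (default 10).
#' @param blur_sigma Gaussian blur s.d. in pixels.
#' @param snr robust peak intensity / noise s.d.; `Inf` disables noise.
#' @param background constant offset as a fraction of the robust peak.
#' @return a [calibrated_image()] whose `outline_mask` marks the retina.
#' @export
render_montage <- function(mosaic, scale = 10, blur_sigma = 1.5, snr = 10,
                           background = 0.05) {
  R <- mosaic$profile$retina_radius
  npix <- ceiling(2 * R * 1000 / scale)
  p <- mosaic$positions
  ix <- floor((p[, 1] + R) * 1000 / scale) + 1
  iy <- floor((p[, 2] + R) * 1000 / scale) + 1
  ok <- ix >= 1 & ix <= npix & iy >= 1 & iy <= npix
  counts <- matrix(0, npix, npix)
  if (any(ok)) {
    tab <- table(factor(ix[ok] + (iy[ok] - 1) * npix,
                        levels = seq_len(npix^2)))
    counts <- matrix(as.numeric(tab), npix, npix)
  }
  img <- gauss_blur(counts, blur_sigma)
  ax <- ((seq_len(npix) - 0.5) * scale) / 1000 - R
  mask <- outer(ax, ax, function(x, y) sqrt(x^2 + y^2) <= R)
  peak <- if (any(img[mask] > 0)) quantile(img[mask], 0.99) else 1
  img <- img + background * peak
  if (is.finite(snr)) {
    img <- img + with_seed(derive_seed(mosaic$seed, npix, 7L),
                           matrix(rnorm(npix^2, 0, peak / snr), npix, npix))
    img[img < 0] <- 0
  }
  calibrated_image(img, scale, origin = c(-R, -R), outline_mask = mask)
}

# Gaussian smoothing via EBImage's 2-D convolution, replicate boundary.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  size <- 2 * ceiling(3 * sigma) + 1
  k <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma)
  as.matrix(EBImage::imageData(EBImage::filter2(m, k, boundary = "replicate")))
}
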