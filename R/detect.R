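#' Detection settings for cone spot counting
#'
#' @param spot_sigma expected Gaussian spot s.d., um.
#' @param unit_amp known peak amplitude of a single spot (image units);
#'   `NULL` (default) self-calibrates from isolated spots, which keeps the
#'   detector invariant to uniform intensity rescaling.
#' @param cand_frac relative height (fraction of the robust dynamic range)
#'   a local maximum must reach to seed amplitude calibration.
#' @param stop_frac stop threshold of the greedy subtraction loop, as a
#'   fraction of the matched-filter template peak.
#' @param iso_factor isolation radius for calibration spots, in units of
#'   `spot_sigma`.
#' @param shape_tol maximum relative r.m.s. residual of the local
#'   spot-plus-neighbours fit for a calibration spot to count as a clean
#'   single.
#' @param max_calib maximum number of calibration spots fitted.
#' @param expected_side nominal field side, um; a field deviating more
#'   than 10 percent triggers a warning flag.
#' @param max_iter hard cap on subtraction iterations.
#' @return a list of class `detect_params`.
#' @export
detect_params <- function(spot_sigma = 1.2, unit_amp = NULL,
                          cand_frac = 0.25, stop_frac = 0.54,
                          iso_factor = 2.5,
                          shape_tol = 0.04, max_calib = 400,
                          expected_side = 125, max_iter = 20000) {
  structure(as.list(environment()), class = "detect_params")
}

#' Detect individual cones in a high-resolution field image
#'
#' Replaces the proprietary object-recognition routine used on confocal
#' fields. Three stages:
#' \enumerate{
#' \item \emph{Calibration}: the single-spot peak amplitude is estimated by
#'   local least-squares fits (spot + neighbouring spots + local constant)
#'   around isolated intensity maxima; fits with non-Gaussian residual
#'   structure (e.g. an unresolved partner spot) are rejected and the
#'   median of the clean singles is taken.
#' \item \emph{Matched filtering and mean removal}: the image is convolved
#'   with the expected spot kernel and its global mean subtracted, which
#'   removes the background and the mean continuum formed by overlapping
#'   spot tails, so counting never depends on a background estimate.
#' \item \emph{Greedy template subtraction} (matching pursuit with the
#'   fixed-amplitude high-passed template) peels one spot's worth of
#'   signal per iteration until the residual reaches the noise floor.
#'   Because each subtraction is flux-quantized, two spots merged into a
#'   single maximum are still counted twice -- the norm at the upper end
#'   of degenerating-retina densities (50,000-85,000 cones/mm^2 with
#'   ~1.2 um spots).
#' }
#'
#' Degenerate inputs (empty or saturated fields) yield zero detections
#' plus a `flags` attribute rather than an error, so a whole sampling run
#' is never aborted by one bad field.
#'
#' @param image a [calibrated_image()] of a sampling field.
#' @param params a [detect_params()] list.
#' @return an n x 2 matrix of sub-pixel spot centers (`x_um`, `y_um`,
#'   relative to the field corner) with attributes `flags` (character),
#'   `unit_amp` and `background` (local-constant estimate from the
#'   calibration fits, `NA` when amplitude was supplied).
#' @export
detect_cones <- function(image, params = detect_params()) {
  stopifnot(inherits(image, "calibrated_image"))
  img <- image$pixels
  scale <- image$scale
  side <- nrow(img) * scale
  flags <- character(0)
  if (abs(side - params$expected_side) > 0.1 * params$expected_side) {
    warnf("field side %.1f um deviates >10%% from the nominal %.0f um",
          side, params$expected_side)
    flags <- c(flags, "off_nominal_side")
  }
  empty_result <- function(flags, unit_amp = NA_real_, bg = NA_real_) {
    structure(matrix(numeric(0), ncol = 2,
                     dimnames = list(NULL, c("x_um", "y_um"))),
              flags = flags, unit_amp = unit_amp, background = bg)
  }
  sp <- params$spot_sigma / scale
  # Read noise from the second difference: spot structure at the expected
  # blur contributes little curvature per pixel, so the Laplacian MAD stays
  # noise-dominated even on crowded fields.
  n1 <- nrow(img)
  lap <- img[3:n1, , drop = FALSE] - 2 * img[2:(n1 - 1), , drop = FALSE] +
    img[1:(n1 - 2), , drop = FALSE]
  noise <- mad(lap) / sqrt(6)
  if (diff(range(img)) == 0) return(empty_result(c(flags, "empty")))
  if (mean(img >= max(img) - 1e-12) > 0.002) {
    warnf("field appears saturated; detections suppressed")
    return(empty_result(c(flags, "saturated")))
  }
  imf <- gauss_blur(img, sp)
  noise_mf <- noise * sqrt(1 / (4 * pi * sp^2))
  sig_t <- sp * sqrt(2)  # spot s.d. in the matched image
  imz <- imf - mean(imf) # removes background + mean spot continuum
  hi <- quantile(imz, 0.999)
  if (hi <= max(8 * noise_mf, 1e-12)) {
    return(empty_result(c(flags, "empty")))
  }
  bg_est <- NA_real_
  calib_n <- NA_integer_
  if (!is.null(params$unit_amp)) {
    A <- params$unit_amp
  } else {
    im1 <- gauss_blur(img, 2)
    cal <- calibrate_amplitude(im1, sp, noise, params, sig1 = 2)
    if (!is.finite(cal$amp)) {
      # crowded-field fallback: relax the shape gate; the result is biased
      # toward merged pairs, so it is flagged and a session-level
      # calibration (see count_scheme_fields) should be preferred
      params2 <- params
      params2$shape_tol <- 2.5 * params$shape_tol
      cal <- calibrate_amplitude(im1, sp, noise, params2, sig1 = 2)
      if (is.finite(cal$amp)) flags <- c(flags, "weak_calibration")
    } else if (cal$n < 5) {
      flags <- c(flags, "weak_calibration")
    }
    A <- cal$amp
    bg_est <- cal$background
    calib_n <- cal$n
    if (!is.finite(A) || A < 5 * noise) {
      return(empty_result(c(flags, "low_snr"), A, bg_est))
    }
  }
  amp_t <- A / 2  # matched-filter peak of one spot
  flat <- amp_t * 2 * pi * sig_t^2 / length(imz)  # template flux / pixel
  stop_thr <- max(5 * noise_mf, params$stop_frac * amp_t)
  det <- cpp_clean_detect(imz, sig_t, amp_t, flat, stop_thr,
                          params$max_iter)
  x_um <- det$x * scale
  y_um <- det$y * scale
  keep <- x_um >= 0 & x_um < side & y_um >= 0 & y_um < side
  out <- cbind(x_um = x_um[keep], y_um = y_um[keep])
  structure(out, flags = flags, unit_amp = A, background = bg_est,
            calib_n = calib_n)
}

# Single-spot peak amplitude (raw-image units), from local least-squares
# fits around isolated intensity maxima of the lightly denoised image. Each
# fit models the candidate, every neighbouring candidate in reach and a
# local constant; candidates whose residual exceeds shape_tol of their
# amplitude (unresolved partners, debris) are rejected. Returns the median
# fitted amplitude, rescaled for the denoising blur, plus the median local
# constant as a background estimate.
calibrate_amplitude <- function(im1, sp, noise, params, sig1 = 1) {
  sig_v <- sqrt(sp^2 + sig1^2)
  f1 <- sp^2 / sig_v^2
  noise1 <- noise * sqrt(1 / (4 * pi * sig1^2))
  med <- median(im1)
  rmax <- quantile(im1, 0.999)
  if (rmax - med <= max(6 * noise1, 1e-12)) {
    return(list(amp = NA_real_, background = NA_real_))
  }
  thr <- med + max(6 * noise1, params$cand_frac * (rmax - med))
  cand <- cpp_local_maxima(im1, thr, max(1L, as.integer(round(sp / 2))))
  x <- cand$x; y <- cand$y
  n <- length(x)
  if (n == 0) return(list(amp = NA_real_, background = NA_real_))
  nnd <- if (n == 1) Inf else {
    d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
    diag(d2) <- Inf
    sqrt(apply(d2, 1, min))
  }
  iso <- which(nnd > params$iso_factor * sp)
  if (length(iso) > params$max_calib) {
    iso <- iso[round(seq(1, length(iso), length.out = params$max_calib))]
  }
  w <- ceiling(2.5 * sig_v)
  reach <- w + 3 * sig_v
  nx <- nrow(im1); ny <- ncol(im1)
  amps <- bgs <- numeric(0)
  for (i in iso) {
    ix <- round(x[i] + 0.5); iy <- round(y[i] + 0.5)
    if (ix - w < 1 || ix + w > nx || iy - w < 1 || iy + w > ny) next
    xs <- (ix - w):(ix + w)
    ys <- (iy - w):(iy + w)
    patch <- as.vector(im1[xs, ys])
    near <- which(abs(x - x[i]) < reach & abs(y - y[i]) < reach)
    near <- c(i, setdiff(near, i))
    X <- vapply(near, function(j) {
      as.vector(exp(-(outer((xs - 0.5 - x[j])^2,
                            (ys - 0.5 - y[j])^2, "+")) / (2 * sig_v^2)))
    }, numeric(length(patch)))
    X <- cbind(X, 1)
    fit <- tryCatch(qr.solve(X, patch), error = function(e) NULL)
    if (is.null(fit)) next
    a <- fit[1]
    if (!is.finite(a) || a <= 0) next
    res <- patch - X %*% fit
    # weight the residual toward the candidate center: misfit there means
    # an unresolved partner (reject), while unmodeled structure at the
    # patch rim only reflects the crowded surround
    wgt <- as.vector(exp(-(outer((xs - 0.5 - x[i])^2,
                                 (ys - 0.5 - y[i])^2, "+")) /
                           (2 * sig_v^2)))
    wrms <- sqrt(sum(wgt * res^2) / sum(wgt))
    if (wrms < params$shape_tol * a) {
      amps <- c(amps, a)
      bgs <- c(bgs, fit[length(fit)])
    }
  }
  if (!length(amps)) {
    return(list(amp = NA_real_, background = NA_real_, n = 0L))
  }
  m0 <- median(amps)
  band <- amps > 0.5 * m0 & amps < 1.5 * m0
  if (any(band)) m0 <- median(amps[band])
  list(amp = m0 / f1, background = median(bgs), n = length(amps))
}

#' Session amplitude calibration for one field
#'
#' Runs only the calibration stage of [detect_cones()] (noise estimate,
#' denoised maxima, local least-squares spot fits) without the counting
#' loop. Used to pool a consensus single-spot amplitude across the fields
#' of one acquisition session.
#'
#' @param image a [calibrated_image()].
#' @param params a [detect_params()].
#' @return list with `amp`, `background`, `n` (validated spots).
#' @export
field_unit_amp <- function(image, params = detect_params()) {
  img <- image$pixels
  n1 <- nrow(img)
  if (diff(range(img)) == 0) {
    return(list(amp = NA_real_, background = NA_real_, n = 0L))
  }
  lap <- img[3:n1, , drop = FALSE] - 2 * img[2:(n1 - 1), , drop = FALSE] +
    img[1:(n1 - 2), , drop = FALSE]
  noise <- mad(lap) / sqrt(6)
  sp <- params$spot_sigma / image$scale
  calibrate_amplitude(gauss_blur(img, 2), sp, noise, params, sig1 = 2)
}

#' Convert a field count to a density
#'
#' @param count nonnegative integer.
#' @param field_side field side, um.
#' @return density in cones/mm^2 (exact arithmetic:
#'   `count / (field_side/1000)^2`).
#' @examples
#' field_density(781, 125)  # 49,984 cones/mm^2
#' @export
field_density <- function(count, field_side = 125) {
  if (!is.numeric(field_side) || field_side <= 0) {
    stopf("field_side must be positive (got %s)", field_side)
  }
  count / (field_side / 1000)^2
}

#' Count one field image
#'
#' Runs [detect_cones()] and packages the result with its location and
#' density.
#'
#' @param image a [calibrated_image()].
#' @param location field center, mm.
#' @param params a [detect_params()].
#' @return an object of class `field_sample` with `location`,
#'   `field_side`, `detections`, `count`, `density` and `flags`.
#' @export
count_field <- function(image, location = c(NA, NA),
                        params = detect_params()) {
  det <- detect_cones(image, params)
  side <- nrow(image$pixels) * image$scale
  structure(list(location = as.numeric(location), field_side = side,
                 detections = det[, , drop = FALSE], count = nrow(det),
                 density = field_density(nrow(det), side),
                 flags = attr(det, "flags"),
                 unit_amp = attr(det, "unit_amp")),
            class = "field_sample")
}

#' Combine the two fields collected at one location
#'
#' The per-location density is the arithmetic mean of the two field
#' densities. If one field is flagged (saturated, too dim, off-nominal),
#' the other is used alone and the flag propagates; if both are flagged
#' the location density is `NA`.
#'
#' @param fields list of `field_sample` objects sharing one location.
#' @return a list with `location`, `density`, `flags`, `n_used`.
#' @export
combine_location <- function(fields) {
  stopifnot(length(fields) >= 1)
  loc <- fields[[1]]$location
  for (f in fields) {
    if (!all(is.na(loc)) && !isTRUE(all.equal(f$location, loc))) {
      stopf("fields combined at one location must share that location")
    }
  }
  bad <- vapply(fields, function(f)
    any(f$flags %in% c("saturated", "low_snr")), logical(1))
  flags <- unique(unlist(lapply(fields, function(f) f$flags)))
  dens <- vapply(fields[!bad], function(f) f$density, numeric(1))
  list(location = loc,
       density = if (length(dens)) mean(dens) else NA_real_,
       flags = flags, n_used = length(dens))
}

#' @export
print.field_sample <- function(x, ...) {
  cat(sprintf("<field_sample>  %d cones in %.0f um field -> %.0f cones/mm^2%s\n",
              x$count, x$field_side, x$density,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}
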