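# VNIR reflectance calibration and vegetation indices.

#' Fit a per-band empirical line from calibration tarps
#'
#' Least-squares line `radiance = gain * reflectance + offset` fitted
#' independently in every band from the tarp field reflectances and their
#' image radiances. With the three standard tarps (white, silver, black) the
#' fit is overdetermined by one point; per-band residual RMS is kept as a
#' diagnostic.
#'
#' @param tarp_radiance numeric matrix, tarps x bands, of at-sensor radiance.
#' @param tarp_reflectance numeric matrix, tarps x bands, of field-measured
#'   tarp reflectance.
#' @param wavelengths_nm optional band-center wavelengths carried through for
#'   diagnostics and error messages.
#' @return An object of class `empirical_line` with per-band `gain`, `offset`
#'   and `residual_rms`.
#' @export
empirical_line_fit <- function(tarp_radiance, tarp_reflectance,
                               wavelengths_nm = NULL) {
  tarp_radiance <- as.matrix(tarp_radiance)
  tarp_reflectance <- as.matrix(tarp_reflectance)
  if (!all(dim(tarp_radiance) == dim(tarp_reflectance))) {
    stop("radiance and reflectance matrices must have identical shape",
         call. = FALSE)
  }
  if (nrow(tarp_radiance) < 2) {
    stop("at least two tarps are required", call. = FALSE)
  }
  nb <- ncol(tarp_radiance)
  band_label <- function(b) {
    if (is.null(wavelengths_nm)) sprintf("band %d", b)
    else sprintf("band %d (%.1f nm)", b, wavelengths_nm[b])
  }
  gain <- offset <- rms <- numeric(nb)
  for (b in seq_len(nb)) {
    x <- tarp_reflectance[, b]; y <- tarp_radiance[, b]
    sxx <- sum((x - mean(x))^2)
    if (sxx < 1e-12 * max(1, mean(x)^2)) {
      stop(sprintf("tarp reflectances are collinear in %s: cannot fit empirical line",
                   band_label(b)), call. = FALSE)
    }
    g <- sum((x - mean(x)) * (y - mean(y))) / sxx
    o <- mean(y) - g * mean(x)
    if (g <= 0) {
      stop(sprintf("non-positive empirical-line gain in %s", band_label(b)),
           call. = FALSE)
    }
    gain[b] <- g; offset[b] <- o
    rms[b] <- sqrt(mean((y - (g * x + o))^2))
  }
  structure(list(gain = gain, offset = offset, residual_rms = rms,
                 wavelengths_nm = wavelengths_nm, n_tarps = nrow(tarp_radiance)),
            class = "empirical_line")
}

#' @export
print.empirical_line <- function(x, ...) {
  cat(sprintf("<empirical_line> %d bands, %d tarps; gain [%.4g, %.4g], offset [%.4g, %.4g]\n",
              length(x$gain), x$n_tarps, min(x$gain), max(x$gain),
              min(x$offset), max(x$offset)))
  invisible(x)
}

#' Apply an empirical-line model to an at-sensor radiance cube
#'
#' Per band, `reflectance = (radiance - offset) / gain`, then clamped to
#' `clamp_range` (bright targets can legitimately exceed 1 under noise; hard
#' failure would be wrong). Clamp counts are stored on the result.
#'
#' @param cube a radiance [spectral_cube()].
#' @param model an [empirical_line()] fit with one gain/offset per cube band.
#' @param clamp_range two-element clamping interval for reflectance.
#' @return A reflectance [spectral_cube()] with a `clamped` field holding
#'   `c(low = ..., high = ...)` counts.
#' @export
apply_empirical_line <- function(cube, model, clamp_range = c(0, 1.5)) {
  if (cube$units != "radiance") {
    stop("`cube` must carry units tag 'radiance'", call. = FALSE)
  }
  nb <- dim(cube$values)[3]
  if (length(model$gain) != nb) {
    stop(sprintf("model has %d bands but cube has %d", length(model$gain), nb),
         call. = FALSE)
  }
  npix <- prod(dim(cube$values)[1:2])
  v <- (cube$values - rep(model$offset, each = npix)) /
    rep(model$gain, each = npix)
  n_low <- sum(v < clamp_range[1], na.rm = TRUE)
  n_high <- sum(v > clamp_range[2], na.rm = TRUE)
  v <- clamp(v, clamp_range[1], clamp_range[2])
  out <- spectral_cube(v, cube$wavelengths, cube$gsd, cube$x0, cube$y0,
                       units = "reflectance")
  out$clamped <- c(low = n_low, high = n_high)
  out
}

index_from_bands <- function(cube, fun, targets_nm, name) {
  if (cube$units != "reflectance") {
    stop("vegetation indices require a reflectance cube", call. = FALSE)
  }
  idx <- vapply(targets_nm, function(t) nearest_band(cube, t), integer(1))
  used <- cube$wavelengths[idx]
  d <- dim(cube$values)
  bands <- lapply(idx, function(b) matrix(cube$values[, , b], d[1], d[2]))
  raster_layer(fun(bands), gsd = cube$gsd, x0 = cube$x0, y0 = cube$y0,
               units = "unitless", name = name, wavelengths_nm = used)
}

#' NDVI map from a reflectance cube
#'
#' Normalized difference vegetation index `(R_nir - R_red)/(R_nir + R_red)`
#' using the bands nearest `red_nm` and `nir_nm` (defaults 680 and 800 nm).
#' Pixels with a zero band sum are set missing.
#'
#' @param cube a reflectance [spectral_cube()].
#' @param red_nm,nir_nm target band centers in nm.
#' @return A [raster_layer()] carrying the wavelengths actually used.
#' @export
ndvi <- function(cube, red_nm = 680, nir_nm = 800) {
  index_from_bands(cube, function(b) {
    red <- b[[1]]; nir <- b[[2]]
    den <- nir + red
    out <- (nir - red) / den
    out[den == 0] <- NA_real_
    out
  }, c(red_nm, nir_nm), "ndvi")
}

#' Water Band Index map from a reflectance cube
#'
#' Ratio of reflectance at 900 nm to 970 nm (liquid-water absorption
#' feature); sensitive to canopy water content. Pixels with zero denominator
#' are set missing.
#'
#' @param cube a reflectance [spectral_cube()].
#' @param num_nm,den_nm target band centers in nm (defaults 900 and 970).
#' @return A [raster_layer()].
#' @export
wbi <- function(cube, num_nm = 900, den_nm = 970) {
  index_from_bands(cube, function(b) {
    out <- b[[1]] / b[[2]]
    out[b[[2]] == 0] <- NA_real_
    out
  }, c(num_nm, den_nm), "wbi")
}

#' VNIR albedo map from a reflectance cube
#'
#' Unweighted mean reflectance over all bands whose centers fall in
#' `range_nm` (inclusive; default 450-900 nm).
#'
#' @param cube a reflectance [spectral_cube()].
#' @param range_nm two-element wavelength interval in nm.
#' @return A [raster_layer()] carrying the band wavelengths averaged.
#' @export
albedo_vnir <- function(cube, range_nm = c(450, 900)) {
  if (cube$units != "reflectance") {
    stop("vegetation indices require a reflectance cube", call. = FALSE)
  }
  sel <- which(cube$wavelengths >= range_nm[1] & cube$wavelengths <= range_nm[2])
  if (!length(sel)) {
    stop(sprintf("no bands with centers in [%g, %g] nm", range_nm[1], range_nm[2]),
         call. = FALSE)
  }
  d <- dim(cube$values)
  m <- cube$values[, , sel, drop = FALSE]
  dim(m) <- c(d[1] * d[2], length(sel))
  vals <- matrix(rowMeans(m), d[1], d[2])
  raster_layer(vals, gsd = cube$gsd, x0 = cube$x0, y0 = cube$y0,
               units = "unitless", name = "albedo",
               wavelengths_nm = cube$wavelengths[sel])
}
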