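# Lightweight in-memory raster containers on a local metric grid.
#
# Convention used throughout: coordinates are scene meters with the origin at
# the scene's south-west corner, x increasing east and y increasing north.
# Matrix rows index y (row 1 is the southernmost row), columns index x, and
# the center of pixel (r, c) sits at (x0 + (c - 0.5) * gsd,
# y0 + (r - 0.5) * gsd).

#' Construct a single-band raster layer
#'
#' @param values numeric matrix; rows index y (south to north), columns x.
#' @param gsd ground sampling distance in meters.
#' @param x0,y0 scene coordinates of the raster's south-west corner (meters).
#' @param units free-text units tag (e.g. "radiance", "kelvin", "unitless").
#' @param name layer name.
#' @param wavelengths_nm optional wavelengths (nm) actually used to derive the
#'   layer (carried by vegetation-index maps).
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(values, gsd, x0 = 0, y0 = 0, units = "unitless",
                         name = "layer", wavelengths_nm = NULL) {
  stopifnot(is.matrix(values), is.numeric(gsd), gsd > 0)
  structure(
    list(values = values, gsd = gsd, x0 = x0, y0 = y0, units = units,
         name = name, wavelengths_nm = wavelengths_nm),
    class = "raster_layer"
  )
}

#' @export
print.raster_layer <- function(x, ...) {
  cat(sprintf("<raster_layer '%s'> %d x %d px @ %.2f m, units: %s\n",
              x$name, nrow(x$values), ncol(x$values), x$gsd, x$units))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  range [%.4g, %.4g], %d missing\n", rng[1], rng[2],
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.raster_layer <- function(x) dim(x$values)

raster_extent <- function(x) {
  c(xmin = unname(x$x0),
    xmax = unname(x$x0 + ncol(x$values) * x$gsd),
    ymin = unname(x$y0),
    ymax = unname(x$y0 + nrow(x$values) * x$gsd))
}

pixel_centers_x <- function(x) x$x0 + (seq_len(ncol(x$values)) - 0.5) * x$gsd
pixel_centers_y <- function(x) x$y0 + (seq_len(nrow(x$values)) - 0.5) * x$gsd

#' Construct a spectral cube
#'
#' A georeferenced (local metric grid) 3-D array of VNIR radiance or
#' reflectance with an explicit wavelength axis.
#'
#' @param values 3-D numeric array `[row, col, band]` (rows index y).
#' @param wavelengths_nm strictly increasing band-center wavelengths in nm.
#' @param gsd ground sampling distance in meters.
#' @param x0,y0 scene coordinates of the south-west corner.
#' @param units `"radiance"` (W m-2 sr-1 nm-1, arbitrary consistent scale) or
#'   `"reflectance"` (unitless).
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(values, wavelengths_nm, gsd, x0 = 0, y0 = 0,
                          units = c("reflectance", "radiance")) {
  units <- match.arg(units)
  stopifnot(length(dim(values)) == 3L)
  if (dim(values)[3] != length(wavelengths_nm)) {
    stop("number of bands does not match length of `wavelengths_nm`",
         call. = FALSE)
  }
  if (length(wavelengths_nm) > 1 && any(diff(wavelengths_nm) <= 0)) {
    stop("`wavelengths_nm` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(values = values, wavelengths = as.numeric(wavelengths_nm),
         gsd = gsd, x0 = x0, y0 = y0, units = units),
    class = "spectral_cube"
  )
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<spectral_cube> %d x %d px, %d bands (%.1f-%.1f nm) @ %.2f m, %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              x$gsd, x$units))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$values)

#' Index of the band nearest a target wavelength
#'
#' @param cube a [spectral_cube()].
#' @param target_nm target wavelength in nm. Must lie within the cube's
#'   spectral range extended by 5 nm on each side.
#' @return Integer band index; ties between two equally near centers resolve
#'   to the shorter wavelength.
#' @export
nearest_band <- function(cube, target_nm) {
  w <- cube$wavelengths
  if (length(w) == 0) stop("cube has no bands", call. = FALSE)
  if (target_nm < min(w) - 5 || target_nm > max(w) + 5) {
    stop(sprintf("target wavelength %.1f nm outside cube range [%.1f, %.1f] nm (+/- 5 nm)",
                 target_nm, min(w), max(w)), call. = FALSE)
  }
  which.min(abs(w - target_nm))
}

# Map scene coordinates to (row, col); errors if any point is outside.
coords_to_rc <- function(layer, x, y) {
  ext <- raster_extent(layer)
  bad <- x < ext["xmin"] | x > ext["xmax"] | y < ext["ymin"] | y > ext["ymax"]
  if (any(bad)) {
    stop(sprintf("%d coordinate(s) outside raster extent [%g, %g] x [%g, %g]",
                 sum(bad), ext["xmin"], ext["xmax"], ext["ymin"], ext["ymax"]),
         call. = FALSE)
  }
  col <- clamp(floor((x - layer$x0) / layer$gsd) + 1L, 1L, ncol(layer$values))
  row <- clamp(floor((y - layer$y0) / layer$gsd) + 1L, 1L, nrow(layer$values))
  cbind(row = row, col = col)
}

#' Sample raster values at point coordinates
#'
#' Nearest-pixel lookup (`footprint = 1`) or the mean of an odd n x n pixel
#' window centered on the containing pixel. Missing pixels propagate: a
#' window containing any `NA` returns `NA`.
#'
#' @param layer a [raster_layer()].
#' @param x,y coordinate vectors in scene meters.
#' @param footprint odd window size in pixels (default 1, nearest pixel).
#' @return Numeric vector of sampled values.
#' @export
extract_at <- function(layer, x, y, footprint = 1L) {
  stopifnot(length(x) == length(y))
  footprint <- as.integer(footprint)
  if (footprint < 1L || footprint %% 2L == 0L) {
    stop("`footprint` must be an odd positive integer", call. = FALSE)
  }
  rc <- coords_to_rc(layer, x, y)
  v <- layer$values
  if (footprint == 1L) return(v[rc])
  half <- (footprint - 1L) %/% 2L
  vapply(seq_len(nrow(rc)), function(i) {
    rows <- clamp(seq(rc[i, 1] - half, rc[i, 1] + half), 1L, nrow(v))
    cols <- clamp(seq(rc[i, 2] - half, rc[i, 2] + half), 1L, ncol(v))
    mean(v[unique(rows), unique(cols)])
  }, numeric(1))
}

#' Mean raster value over a rectangular plot with an edge buffer
#'
#' Averages pixels whose centers fall inside the rectangle shrunk inward by
#' `buffer_m` on every side.
#'
#' @param layer a [raster_layer()].
#' @param rect named vector or list with `xmin`, `xmax`, `ymin`, `ymax`.
#' @param buffer_m inward edge buffer in meters (default 0).
#' @return Mean of the selected pixels (`NA` if any selected pixel is missing).
#' @export
extract_rect_mean <- function(layer, rect, buffer_m = 0) {
  rect <- as.list(rect)
  xmin <- rect$xmin + buffer_m; xmax <- rect$xmax - buffer_m
  ymin <- rect$ymin + buffer_m; ymax <- rect$ymax - buffer_m
  if (xmax <= xmin || ymax <= ymin) {
    stop("edge buffer leaves an empty rectangle", call. = FALSE)
  }
  cx <- pixel_centers_x(layer); cy <- pixel_centers_y(layer)
  cols <- which(cx >= xmin & cx <= xmax)
  rows <- which(cy >= ymin & cy <= ymax)
  if (!length(rows) || !length(cols)) {
    stop("no pixel centers inside the buffered rectangle", call. = FALSE)
  }
  mean(layer$values[rows, cols])
}
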