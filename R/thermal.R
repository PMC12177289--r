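# Single-channel broadband land-surface-temperature retrieval.
#
# At-sensor radiance model for one band-effective thermal channel:
#   L_sensor = (eps * B(T_s) + (1 - eps) * L_down) * tau + L_up
# with tau the band-effective atmospheric transmittance and L_down / L_up the
# downwelling and upwelling atmospheric radiances. Three calibration tarps of
# known emissivity and surface temperature give three such equations, linear
# in (u, v, w) = (tau, tau * L_down, L_up), which are solved exactly.

#' Construct an atmospheric state for the thermal band
#'
#' @param tau band-effective transmittance, in (0, 1].
#' @param l_down,l_up downwelling and upwelling atmospheric radiance
#'   (W m-2 sr-1 um-1), both >= 0.
#' @return An object of class `atmospheric_state`.
#' @export
atmospheric_state <- function(tau, l_down, l_up) {
  if (!is.finite(tau) || tau <= 0 || tau > 1) {
    stop(sprintf("transmittance tau = %.6g outside (0, 1]", tau), call. = FALSE)
  }
  if (l_down < 0 || l_up < 0) {
    stop("atmospheric radiances must be nonnegative", call. = FALSE)
  }
  structure(list(tau = tau, l_down = l_down, l_up = l_up),
            class = "atmospheric_state")
}

#' @export
print.atmospheric_state <- function(x, ...) {
  cat(sprintf("<atmospheric_state> tau = %.4f, L_down = %.4f, L_up = %.4f (W m-2 sr-1 um-1)\n",
              x$tau, x$l_down, x$l_up))
  invisible(x)
}

#' At-sensor thermal radiance from surface and atmosphere
#'
#' Forward band-effective radiative transfer for one thermal channel.
#'
#' @param t_surface surface temperature(s), kelvin.
#' @param emissivity surface emissivity (scalar or same length).
#' @param atm an [atmospheric_state()].
#' @param band a [band_response()].
#' @return At-sensor radiance, W m-2 sr-1 um-1.
#' @export
thermal_at_sensor <- function(t_surface, emissivity, atm,
                              band = band_response()) {
  b <- planck_band_radiance(t_surface, band)
  (emissivity * b + (1 - emissivity) * atm$l_down) * atm$tau + atm$l_up
}

#' Tarp emissivity from paired radiometric and contact temperatures
#'
#' Broadband emissivity of a calibration tarp from an infrared-thermometer
#' reading and a thermocouple reading of the same surface, via the
#' Stefan-Boltzmann relation: emissivity = (T_IRT / T_thermocouple)^4.
#' Values above 1 (possible under measurement error) are clipped to 1 with a
#' warning.
#'
#' @param t_irt infrared-thermometer temperature(s), kelvin.
#' @param t_thermocouple thermocouple temperature(s), kelvin.
#' @return Emissivity in (0, 1].
#' @export
tarp_emissivity <- function(t_irt, t_thermocouple) {
  if (any(t_irt <= 0) || any(t_thermocouple <= 0)) {
    stop("temperatures must be positive (kelvin)", call. = FALSE)
  }
  e <- (t_irt / t_thermocouple)^4
  if (any(e > 1)) {
    warning(sprintf("%d emissivity value(s) > 1 clipped to 1", sum(e > 1)))
    e <- pmin(e, 1)
  }
  e
}

#' Solve band-effective atmospheric parameters from three calibration tarps
#'
#' Each tarp of emissivity eps_i and ground temperature T_i observed at
#' radiance L_i contributes the linear equation
#' `L_i = eps_i B(T_i) u + (1 - eps_i) v + w` with (u, v, w) =
#' (tau, tau * L_down, L_up). The exact 3x3 solve returns
#' `atmospheric_state(u, v / u, w)` after checking conditioning and physical
#' admissibility.
#'
#' @param tarps data frame with columns `emissivity`, `t_surface` (kelvin) and
#'   `radiance` (at-sensor, W m-2 sr-1 um-1); one row per tarp, at least 3.
#' @param band a [band_response()].
#' @param max_condition reciprocal-condition floor: the solve aborts when
#'   `rcond < 1/max_condition`.
#' @return An [atmospheric_state()].
#' @export
solve_atmosphere <- function(tarps, band = band_response(),
                             max_condition = 1e10) {
  need <- c("emissivity", "t_surface", "radiance")
  if (!all(need %in% names(tarps))) {
    stop("`tarps` needs columns emissivity, t_surface, radiance", call. = FALSE)
  }
  if (nrow(tarps) < 3) stop("three tarps are required", call. = FALSE)
  tarps <- tarps[1:3, ]
  b <- planck_band_radiance(tarps$t_surface, band)
  a <- cbind(tarps$emissivity * b, 1 - tarps$emissivity, rep(1, 3))
  rc <- rcond(a)
  if (!is.finite(rc) || rc < 1 / max_condition) {
    # name the most collinear pair of tarp equations
    ang <- function(i, j) {
      ci <- a[i, ] / sqrt(sum(a[i, ]^2)); cj <- a[j, ] / sqrt(sum(a[j, ]^2))
      abs(sum(ci * cj))
    }
    prs <- rbind(c(1, 2), c(1, 3), c(2, 3))
    worst <- prs[which.max(apply(prs, 1, function(p) ang(p[1], p[2]))), ]
    nm <- if ("name" %in% names(tarps)) tarps$name else seq_len(3)
    stop(sprintf("degenerate tarp system (rcond = %.3g): tarps '%s' and '%s' are nearly collinear",
                 rc, nm[worst[1]], nm[worst[2]]), call. = FALSE)
  }
  sol <- solve(a, tarps$radiance)
  u <- sol[1]; v <- sol[2]; w <- sol[3]
  if (u <= 0 || u > 1 + 1e-9 || v < -1e-9 || w < -1e-9) {
    stop(sprintf("tarp solve produced unphysical atmosphere (tau = %.6g, tau*L_down = %.6g, L_up = %.6g)",
                 u, v, w), call. = FALSE)
  }
  atmospheric_state(min(u, 1), max(v, 0) / min(u, 1), max(w, 0))
}

#' Atmospherically correct an at-sensor thermal raster
#'
#' Converts at-sensor radiance to ground-leaving radiance:
#' `(L_sensor - L_up) / tau` per pixel.
#'
#' @param image a [raster_layer()] of at-sensor thermal radiance.
#' @param atm an [atmospheric_state()]; `tau` below 1e-3 is rejected.
#' @return A [raster_layer()] of ground-leaving radiance.
#' @export
to_ground_brightness <- function(image, atm) {
  if (atm$tau < 1e-3) stop("transmittance below 1e-3 floor", call. = FALSE)
  out <- image
  out$values <- (image$values - atm$l_up) / atm$tau
  out$name <- "ground_radiance"
  out
}

#' Emissivity model for the NDVI-threshold method
#'
#' @param eps_soil bare-soil emissivity (default 0.95, dry sandy soil).
#' @param eps_veg dense-vegetation emissivity (default 0.985).
#' @param ndvi_soil,ndvi_veg NDVI thresholds delimiting bare soil and dense
#'   vegetation (defaults 0.2 and 0.5).
#' @return An object of class `emissivity_model`.
#' @export
emissivity_model <- function(eps_soil = 0.95, eps_veg = 0.985,
                             ndvi_soil = 0.2, ndvi_veg = 0.5) {
  if (!(eps_soil > 0 && eps_soil <= eps_veg && eps_veg <= 1)) {
    stop("need 0 < eps_soil <= eps_veg <= 1", call. = FALSE)
  }
  if (!(ndvi_soil < ndvi_veg)) stop("need ndvi_soil < ndvi_veg", call. = FALSE)
  structure(list(eps_soil = eps_soil, eps_veg = eps_veg,
                 ndvi_soil = ndvi_soil, ndvi_veg = ndvi_veg),
            class = "emissivity_model")
}

#' Per-pixel emissivity from NDVI thresholds
#'
#' Vegetation fraction `P_v = (NDVI - NDVI_s) / (NDVI_v - NDVI_s)` clipped to
#' `[0, 1]`; emissivity `eps_s + (eps_v - eps_s) * P_v`, i.e. `eps_s` below the
#' soil threshold, `eps_v` above the vegetation threshold and linear between,
#' continuous at both thresholds.
#'
#' @param ndvi a [raster_layer()] of NDVI, or a numeric vector/matrix.
#' @param model an [emissivity_model()].
#' @return A list with `emissivity` and `p_v`, each matching the input type.
#' @export
emissivity_from_ndvi <- function(ndvi, model = emissivity_model()) {
  is_layer <- inherits(ndvi, "raster_layer")
  v <- if (is_layer) ndvi$values else ndvi
  p_v <- clamp((v - model$ndvi_soil) / (model$ndvi_veg - model$ndvi_soil), 0, 1)
  eps <- model$eps_soil + (model$eps_veg - model$eps_soil) * p_v
  if (is_layer) {
    e <- ndvi; e$values <- eps; e$name <- "emissivity"; e$units <- "unitless"
    p <- ndvi; p$values <- p_v; p$name <- "vegetation_fraction"
    list(emissivity = e, p_v = p)
  } else {
    list(emissivity = eps, p_v = p_v)
  }
}

#' Resample an NDVI map to the thermal grid by nearest pixel center
#'
#' For every thermal pixel center, takes the value of the finer-resolution
#' pixel whose center is nearest; exact ties resolve to the smaller row/column
#' index (row-major order).
#'
#' @param ndvi a [raster_layer()] on the fine (VNIR) grid.
#' @param template a [raster_layer()] defining the thermal grid, or a list
#'   with `nrow`, `ncol`, `gsd`, `x0`, `y0`.
#' @return A [raster_layer()] on the thermal grid.
#' @export
resample_to_grid <- function(ndvi, template) {
  if (inherits(template, "raster_layer")) {
    tg <- list(nrow = nrow(template$values), ncol = ncol(template$values),
               gsd = template$gsd, x0 = template$x0, y0 = template$y0)
  } else tg <- template
  src_ext <- raster_extent(ndvi)
  dst_x <- tg$x0 + (seq_len(tg$ncol) - 0.5) * tg$gsd
  dst_y <- tg$y0 + (seq_len(tg$nrow) - 0.5) * tg$gsd
  if (max(dst_x) < src_ext["xmin"] || min(dst_x) > src_ext["xmax"] ||
      max(dst_y) < src_ext["ymin"] || min(dst_y) > src_ext["ymax"]) {
    stop("source and destination extents are disjoint", call. = FALSE)
  }
  ci <- nearest_index_1d(ncol(ndvi$values), ndvi$gsd, ndvi$x0, dst_x)
  ri <- nearest_index_1d(nrow(ndvi$values), ndvi$gsd, ndvi$y0, dst_y)
  raster_layer(ndvi$values[ri, ci, drop = FALSE], gsd = tg$gsd,
               x0 = tg$x0, y0 = tg$y0, units = ndvi$units,
               name = ndvi$name, wavelengths_nm = ndvi$wavelengths_nm)
}

#' Retrieve land surface temperature from at-sensor thermal radiance
#'
#' Per pixel: `B(T_s) = ((L_sensor - L_up)/tau - (1 - eps) L_down) / eps`,
#' then a monotone Planck inversion. Pixels whose corrected radiance falls
#' outside the attainable Planck range over `t_bounds` are flagged missing and
#' counted.
#'
#' @param image a [raster_layer()] of at-sensor thermal radiance.
#' @param atm an [atmospheric_state()].
#' @param emissivity a [raster_layer()] (or matrix) of per-pixel emissivity on
#'   the thermal grid; values must be positive.
#' @param band a [band_response()].
#' @param t_bounds physical temperature bracket in kelvin.
#' @return A list of class `temperature_map`: `temperature` (raster, kelvin),
#'   `emissivity`, and `n_missing` (count of non-invertible pixels).
#' @export
retrieve_lst <- function(image, atm, emissivity, band = band_response(),
                         t_bounds = c(260, 360)) {
  eps <- if (inherits(emissivity, "raster_layer")) emissivity$values else emissivity
  if (any(eps <= 0, na.rm = TRUE)) {
    stop("emissivity must be positive", call. = FALSE)
  }
  if (!all(dim(eps) == dim(image$values))) {
    stop("emissivity map and thermal image dimensions differ", call. = FALSE)
  }
  ground <- (image$values - atm$l_up) / atm$tau
  b_surf <- (ground - (1 - eps) * atm$l_down) / eps
  lo <- planck_band_radiance(t_bounds[1], band)
  hi <- planck_band_radiance(t_bounds[2], band)
  invalid <- !is.na(b_surf) & (b_surf < lo | b_surf > hi)
  b_surf[invalid] <- NA_real_
  t_s <- matrix(invert_planck(as.vector(b_surf), band, t_bounds),
                nrow(b_surf), ncol(b_surf))
  out_t <- image
  out_t$values <- t_s; out_t$units <- "kelvin"; out_t$name <- "lst"
  eps_layer <- if (inherits(emissivity, "raster_layer")) emissivity else {
    raster_layer(eps, image$gsd, image$x0, image$y0, name = "emissivity")
  }
  structure(list(temperature = out_t, emissivity = eps_layer,
                 n_missing = sum(invalid)),
            class = "temperature_map")
}

#' @export
print.temperature_map <- function(x, ...) {
  rng <- range(x$temperature$values, na.rm = TRUE)
  cat(sprintf("<temperature_map> %d x %d px, T_s in [%.2f, %.2f] K, %d missing\n",
              nrow(x$temperature$values), ncol(x$temperature$values),
              rng[1], rng[2], x$n_missing))
  invisible(x)
}
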