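# Forward simulation of at-sensor VNIR and thermal imagery, including the
# three calibration tarps.

#' Build the calibration-tarp records for a scene
#'
#' Places three tarps (white, silver, black) in the southern scene margin and
#' fills in their field-measured properties: flat VNIR reflectance spectra,
#' thermal emissivity, thermocouple temperature, and the implied
#' infrared-thermometer temperature `T_IRT = emissivity^(1/4) *
#' T_thermocouple` (the Stefan-Boltzmann relation the tarp-emissivity
#' estimate inverts).
#'
#' @param layout an [make_layout()] result.
#' @param config a [scene_config()].
#' @param wavelengths_nm VNIR wavelength grid for the reflectance spectra.
#' @return A list of class `tarp_set`: `records` (data frame with `name`,
#'   `emissivity`, `t_thermocouple`, `t_irt` and rectangle columns) and
#'   `reflectance` (tarps x bands matrix).
#' @export
make_tarps <- function(layout, config = scene_config(),
                       wavelengths_nm = vnir_wavelengths(config)) {
  tc <- config$tarps
  size <- tc$size_m
  y0 <- 10
  if (config$layout$margin_y < size + 12) {
    stop("southern margin too small to place the calibration tarps",
         call. = FALSE)
  }
  x_starts <- 15 + (seq_along(tc$names) - 1) * (size + 12)
  records <- data.frame(
    name = tc$names,
    emissivity = unname(tc$emissivity[tc$names]),
    t_thermocouple = unname(tc$t_thermocouple[tc$names]),
    xmin = x_starts, xmax = x_starts + size,
    ymin = y0, ymax = y0 + size,
    stringsAsFactors = FALSE
  )
  records$t_irt <- records$emissivity^(1 / 4) * records$t_thermocouple
  refl <- outer(unname(tc$reflectance[tc$names]),
                rep(1, length(wavelengths_nm)))
  rownames(refl) <- tc$names
  structure(list(records = records, reflectance = refl,
                 wavelengths_nm = wavelengths_nm),
            class = "tarp_set")
}

vnir_gain_offset <- function(config, wavelengths_nm) {
  vc <- config$vnir_cal
  gain <- vc$gain0 + vc$gain_slope * (wavelengths_nm - 400)
  offset <- vc$offset0 * exp(-(wavelengths_nm - 400) / vc$offset_decay_nm)
  if (any(gain <= 0)) {
    stop("VNIR calibration configuration produces non-positive gains",
         call. = FALSE)
  }
  list(gain = gain, offset = offset)
}

#' Forward-simulate the at-sensor VNIR radiance cube
#'
#' Applies the linear at-sensor model `radiance_b = gain_b * reflectance_b +
#' offset_b (+ noise)` band by band, paints the calibration tarps into the
#' image, and extracts their image radiances (mean over tarp pixels).
#'
#' @param truth a [make_scene_truth()] result.
#' @param config a [scene_config()].
#' @param seed integer seed for the sensor noise.
#' @param noise logical; add per-band Gaussian sensor noise (default `TRUE`).
#' @param tarps a [make_tarps()] result (built from the config when `NULL`).
#' @return A list: `cube` (radiance [spectral_cube()]), `tarps` (the tarp
#'   set), `tarp_radiance` (tarps x bands matrix of image radiances) and the
#'   true `gain`/`offset` used.
#' @export
forward_vnir <- function(truth, config = scene_config(), seed = 1L,
                         noise = TRUE, tarps = NULL) {
  wl <- truth$reflectance$wavelengths
  cal <- vnir_gain_offset(config, wl)
  if (is.null(tarps)) tarps <- make_tarps(truth$layout, config, wl)
  g <- truth$grid
  v <- truth$reflectance$values
  cx <- (seq_len(g$nx) - 0.5) * g$gsd
  cy <- (seq_len(g$ny) - 0.5) * g$gsd
  tarp_px <- lapply(seq_len(nrow(tarps$records)), function(i) {
    r <- tarps$records[i, ]
    list(rows = which(cy >= r$ymin & cy <= r$ymax),
         cols = which(cx >= r$xmin & cx <= r$xmax))
  })
  for (i in seq_along(tarp_px)) {
    px <- tarp_px[[i]]
    v[px$rows, px$cols, ] <- rep(tarps$reflectance[i, ],
                                 each = length(px$rows) * length(px$cols))
  }
  npix <- g$ny * g$nx
  rad <- v * rep(cal$gain, each = npix) + rep(cal$offset, each = npix)
  sd_b <- if (noise) config$sensor$vnir_noise_sd else 0
  if (sd_b > 0) {
    rad <- rad + with_seed(stage_seed(seed, "forward_vnir"),
                           stats::rnorm(length(rad), 0, sd_b))
  }
  tarp_radiance <- t(vapply(seq_along(tarp_px), function(i) {
    px <- tarp_px[[i]]
    vapply(seq_along(wl), function(b) mean(rad[px$rows, px$cols, b]),
           numeric(1))
  }, numeric(length(wl))))
  rownames(tarp_radiance) <- tarps$records$name
  list(cube = spectral_cube(rad, wl, g$gsd, g$x0, g$y0, units = "radiance"),
       tarps = tarps, tarp_radiance = tarp_radiance,
       gain = cal$gain, offset = cal$offset)
}

#' Forward-simulate the at-sensor broadband thermal image
#'
#' Box-averages the truth blackbody radiance field from the VNIR grid to the
#' thermal grid (radiance mixes linearly, so `B(T)` is averaged and inverted
#' rather than temperature itself), assigns per-pixel emissivity on the
#' thermal grid with the same NDVI-threshold law the retrieval uses (nearest
#' VNIR pixel NDVI), and applies the band-effective radiative transfer
#' `L = (eps * B + (1 - eps) * L_down) * tau + L_up`, painting the tarps in
#' and optionally adding Gaussian sensor noise last.
#'
#' @param truth a [make_scene_truth()] result.
#' @param atm an [atmospheric_state()] (built from the config when `NULL`).
#' @param config a [scene_config()].
#' @param seed integer seed for the sensor noise.
#' @param noise logical; add thermal sensor noise equivalent to
#'   `config$sensor$thermal_noise_k` kelvin (default `TRUE`).
#' @param tarps a [make_tarps()] result (built from the config when `NULL`).
#' @return A list: `image` (at-sensor radiance [raster_layer()] on the
#'   thermal grid), `t_eff` (effective truth temperature on the thermal
#'   grid), `emissivity` and `p_v` (thermal-grid maps used in the forward
#'   model), `tarp_mask` (logical matrix marking tarp pixels, whose
#'   emissivity does not follow the NDVI law), `tarps` (records augmented
#'   with `t_surface` and `radiance`), `atm` and `band`.
#' @export
forward_thermal <- function(truth, atm = NULL, config = scene_config(),
                            seed = 1L, noise = TRUE, tarps = NULL) {
  if (is.null(atm)) atm <- do.call(atmospheric_state, config$atmosphere)
  band <- thermal_band_from_config(config)
  g <- truth$grid
  tg_gsd <- config$sensor$thermal_gsd
  nx_t <- floor(g$nx * g$gsd / tg_gsd)
  ny_t <- floor(g$ny * g$gsd / tg_gsd)
  if (nx_t < 1 || ny_t < 1) stop("thermal grid is empty", call. = FALSE)

  b_fine <- matrix(fast_band_radiance(as.vector(truth$temperature), band),
                   g$ny, g$nx)
  b_bar <- box_average(b_fine, g$gsd, ny_t, nx_t, tg_gsd)
  t_eff <- matrix(invert_planck(as.vector(b_bar), band), ny_t, nx_t)

  template <- list(nrow = ny_t, ncol = nx_t, gsd = tg_gsd, x0 = g$x0, y0 = g$y0)
  # emissivity on the thermal grid from the nearest VNIR pixel's NDVI
  nd_map <- resample_to_grid(ndvi(truth$reflectance), template)
  eps_model <- do.call(emissivity_model, config$emissivity)
  eps <- emissivity_from_ndvi(nd_map, eps_model)

  radiance <- (eps$emissivity$values * b_bar +
                 (1 - eps$emissivity$values) * atm$l_down) * atm$tau + atm$l_up

  if (is.null(tarps)) tarps <- make_tarps(truth$layout, config)
  rec <- tarps$records
  rec$t_surface <- rec$t_thermocouple
  rec$radiance <- thermal_at_sensor(rec$t_surface, rec$emissivity, atm, band)
  cx_t <- (seq_len(nx_t) - 0.5) * tg_gsd
  cy_t <- (seq_len(ny_t) - 0.5) * tg_gsd
  tarp_mask <- matrix(FALSE, ny_t, nx_t)
  for (i in seq_len(nrow(rec))) {
    rows <- which(cy_t >= rec$ymin[i] & cy_t <= rec$ymax[i])
    cols <- which(cx_t >= rec$xmin[i] & cx_t <= rec$xmax[i])
    radiance[rows, cols] <- rec$radiance[i]
    t_eff[rows, cols] <- rec$t_surface[i]
    eps$emissivity$values[rows, cols] <- rec$emissivity[i]
    tarp_mask[rows, cols] <- TRUE
  }

  if (noise && config$sensor$thermal_noise_k > 0) {
    sd_l <- config$sensor$thermal_noise_k * planck_band_deriv(300, band)
    radiance <- radiance + with_seed(stage_seed(seed, "forward_thermal"),
      matrix(stats::rnorm(length(radiance), 0, sd_l), ny_t, nx_t))
  }

  list(image = raster_layer(radiance, tg_gsd, g$x0, g$y0,
                            units = "radiance", name = "thermal_at_sensor"),
       t_eff = raster_layer(t_eff, tg_gsd, g$x0, g$y0,
                            units = "kelvin", name = "t_eff"),
       emissivity = eps$emissivity, p_v = eps$p_v, tarp_mask = tarp_mask,
       tarps = rec, atm = atm, band = band)
}
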