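# Ground-truth scene fields: endmember spectra, cover fields, water,
# temperature, emissivity and the mixed reflectance cube.

#' Parametric endmember reflectance spectra
#'
#' Smooth parametric curves for the three scene endmembers: green vegetation
#' (low visible reflectance with a small 550 nm bump, logistic red edge to a
#' NIR plateau, and a Gaussian liquid-water absorption at 970 nm whose depth
#' scales with canopy water content), litter (flat and bright, no 970 nm
#' dip) and bare soil (linearly brightening with wavelength).
#'
#' @param wavelengths_nm wavelength grid in nm.
#' @param config a [scene_config()] (only `$endmembers` is used).
#' @param water canopy water scalar in `[0, 1]` applied to the green
#'   endmember's absorption feature.
#' @return A 3 x n matrix with rows `green`, `litter`, `soil`.
#' @export
endmember_spectra <- function(wavelengths_nm, config = scene_config(),
                              water = 0) {
  em <- config$endmembers
  w <- wavelengths_nm
  green <- em$green_vis +
    em$green_bump * exp(-((w - 550) / 40)^2) +
    (em$green_nir - em$green_vis) /
      (1 + exp(-(w - em$red_edge_nm) / em$red_edge_width_nm))
  green <- green * (1 - water_absorption(w, em) * water)
  litter <- em$litter_base + em$litter_slope * (w - 400)
  soil <- em$soil_min + (em$soil_max - em$soil_min) * (w - 400) / 600
  m <- rbind(green = green, litter = litter, soil = soil)
  if (any(m < 0) || any(m > 1)) {
    stop("endmember configuration produces reflectance outside [0, 1]",
         call. = FALSE)
  }
  m
}

# Fractional absorption of the green endmember at unit water content.
water_absorption <- function(wavelengths_nm, em) {
  em$water_depth * exp(-((wavelengths_nm - em$water_center_nm) /
                           em$water_sigma_nm)^2)
}

#' Generate the ground-truth scene
#'
#' Builds per-pixel truth fields on the VNIR grid: fractional cover of green
#' vegetation, litter and bare soil (summing to 1), canopy water content,
#' surface temperature, NDVI-threshold emissivity, and the cover-weighted
#' endmember reflectance cube. Inside plots, cover follows the plot's
#' treatment conditions (shared with [sample_cover_tables()]) plus spatially
#' correlated noise; outside plots a constant background mix applies.
#' Temperature decreases with green cover and water content:
#' `T = T_base - a * green - b * water + correlated noise`.
#'
#' @param layout an [make_layout()] result.
#' @param config a [scene_config()].
#' @param seed integer seed.
#' @return An object of class `scene_truth` with fields `cover` (list of
#'   matrices `green`, `litter`, `soil`), `water`, `temperature` (kelvin
#'   matrix), `emissivity` ([raster_layer()]), `reflectance`
#'   ([spectral_cube()]), `grid`, `layout` and `conditions`.
#' @export
make_scene_truth <- function(layout, config = scene_config(), seed = 1L) {
  gsd <- config$sensor$vnir_gsd
  nx <- unname(floor(layout$extent["width"] / gsd))
  ny <- unname(floor(layout$extent["height"] / gsd))
  cc <- config$cover
  tc <- config$temperature
  cond <- plot_conditions(layout, config, seed)

  cx <- (seq_len(nx) - 0.5) * gsd
  cy <- (seq_len(ny) - 0.5) * gsd

  res <- with_seed(stage_seed(seed, "scene_truth"), {
    green <- matrix(cc$background["green"], ny, nx)
    bg_nonveg <- 1 - cc$background["green"]
    bg_litter <- if (bg_nonveg > 0) cc$background["litter"] / bg_nonveg else 0
    litter_share <- matrix(bg_litter, ny, nx)
    for (i in seq_len(nrow(cond$plots))) {
      p <- layout$plots[i, ]
      rows <- which(cy >= p$ymin & cy <= p$ymax)
      cols <- which(cx >= p$xmin & cx <= p$xmax)
      green[rows, cols] <- cond$plots$veg[i]
      litter_share[rows, cols] <-
        cc$litter_share[cond$plots$management[i]]
    }
    green <- clamp(green + noise_field(ny, nx, cc$field_corr_len, cc$field_sd),
                   0, 1)
    litter <- litter_share * (1 - green)
    soil <- (1 - green) - litter
    water <- clamp(config$water$scale * green *
                     (1 + noise_field(ny, nx, cc$field_corr_len,
                                      config$water$noise_sd)), 0, 1)
    temperature <- tc$base_k - tc$cool_green * green - tc$cool_water * water +
      noise_field(ny, nx, tc$corr_len, tc$noise_sd)
    list(green = green, litter = litter, soil = soil, water = water,
         temperature = temperature)
  })

  wl <- vnir_wavelengths(config)
  em <- endmember_spectra(wl, config)
  absorb <- water_absorption(wl, config$endmembers)
  cube <- array(0, dim = c(ny, nx, length(wl)))
  for (b in seq_along(wl)) {
    cube[, , b] <- res$green * em["green", b] * (1 - absorb[b] * res$water) +
      res$litter * em["litter", b] + res$soil * em["soil", b]
  }
  refl <- spectral_cube(cube, wl, gsd, 0, 0, units = "reflectance")

  nd <- ndvi(refl)
  eps <- emissivity_from_ndvi(nd, do.call(emissivity_model, config$emissivity))

  structure(list(
    cover = res[c("green", "litter", "soil")],
    water = res$water,
    temperature = res$temperature,
    emissivity = eps$emissivity,
    p_v = eps$p_v,
    reflectance = refl,
    grid = list(nx = nx, ny = ny, gsd = gsd, x0 = 0, y0 = 0),
    layout = layout,
    conditions = cond
  ), class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d x %d px @ %g m, %d bands; T in [%.1f, %.1f] K\n",
              x$grid$ny, x$grid$nx, x$grid$gsd,
              length(x$reflectance$wavelengths),
              min(x$temperature), max(x$temperature)))
  invisible(x)
}
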