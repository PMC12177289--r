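# Scene configuration: one structured object controls layout, species pool,
# effect sizes, endmembers, atmosphere, sensor and calibration targets.

#' Default synthetic-scene configuration
#'
#' Returns the full nested configuration for the synthetic prairie scene:
#' experiment layout (8 blocks x 3 plots of ~0.40 ha on a 600 m x 400 m
#' scene), treatment effect sizes on ground cover and composition, endmember
#' spectra parameters, surface-temperature coupling, thermal atmosphere,
#' sensor models and calibration-tarp properties. Any element can be
#' overridden by passing a nested list, e.g.
#' `scene_config(layout = list(n_blocks = 4))`.
#'
#' Effect-size defaults encode the qualitative treatment pattern of the
#' restoration experiment the simulator emulates: seeding raises vegetation
#' cover, richness and the C4/forb share; burning removes litter, exposes
#' soil, suppresses C3 grasses and boosts green cover and canopy water, so
#' burned and higher-diversity plots end up with higher NDVI, WBI and albedo
#' and lower surface temperature.
#'
#' @param ... named nested lists merged over the defaults.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(...) {
  cfg <- list(
    layout = list(
      n_blocks = 8L,       # blocks of 3 plots, management alternating by block
      block_cols = 4L,     # blocks arranged in a block_cols-wide grid
      plot_w = 100,        # plot east-west extent (m); 100 x 40 m = 0.40 ha
      plot_h = 40,         # plot north-south extent (m)
      plot_gap = 5,        # gap between plots within a block (m)
      block_gap = 20,      # gap between blocks (m)
      margin_x = 70,       # scene margin west/east of the block grid (m)
      margin_y = 60        # scene margin south/north of the block grid (m)
    ),
    sensor = list(
      vnir_range_nm = c(400, 1000),
      vnir_step_nm = 2.3,  # band spacing ~ spectral resolution
      vnir_gsd = 1.0,      # m
      thermal_gsd = 1.4,   # m
      vnir_noise_sd = 0.005,   # radiance units per band
      thermal_noise_k = 1.5,   # kelvin-equivalent sensor noise
      thermal_band = list(lambda_min_um = 7.5, lambda_max_um = 14,
                          step_um = 0.02, shape = "boxcar")
    ),
    atmosphere = list(tau = 0.95, l_down = 1.5, l_up = 0.8),
    emissivity = list(eps_soil = 0.95, eps_veg = 0.985,
                      ndvi_soil = 0.2, ndvi_veg = 0.5),
    endmembers = list(
      green_vis = 0.05,      # green-vegetation visible baseline reflectance
      green_bump = 0.02,     # green-peak bump at 550 nm
      green_nir = 0.60,      # NIR plateau reflectance
      red_edge_nm = 715,     # logistic red-edge midpoint
      red_edge_width_nm = 10,
      water_depth = 0.35,    # fractional 970 nm absorption at water = 1
      water_center_nm = 970,
      water_sigma_nm = 25,
      litter_base = 0.18,    # flat litter (bright in the visible, well below
                             # the green NIR plateau) without the 970 nm dip
      litter_slope = 2e-5,   # per nm
      soil_min = 0.10,       # soil reflectance at 400 nm
      soil_max = 0.28        # soil reflectance at 1000 nm
    ),
    cover = list(
      veg_mean = c(control = 0.55, mid = 0.78, high = 0.85),
      burn_veg_boost = 0.10,           # extra green cover in burned plots
      litter_share = c(burn = 0.25, hay = 0.75),  # litter share of non-veg
      burn_modifier = c(C3 = 0.7, C4 = 1.1, forb = 1.15),
      plot_sd = 0.04,        # between-plot latent establishment effect
      comp_tilt = 4,         # latent effect tilt on C4/forb vs C3 weights
      location_sd = 0.05,    # quadrat-to-quadrat vegetation cover noise
      litter_sd = 0.08,      # quadrat litter-share noise
      species_lnorm_sd = 0.6,  # per-species quadrat abundance noise (log sd)
      min_share = 0.005,     # quadrat species shares below this are absent
      field_sd = 0.06,       # pixel-level cover noise in the scene truth
      field_corr_len = 8,    # pixels
      background = c(green = 0.35, litter = 0.35, soil = 0.30)
    ),
    water = list(scale = 0.8, noise_sd = 0.3),
    temperature = list(base_k = 318, cool_green = 12, cool_water = 5,
                       noise_sd = 0.8, corr_len = 10),
    vnir_cal = list(gain0 = 1.5, gain_slope = -5e-4,   # gain(lambda), > 0
                    offset0 = 0.08, offset_decay_nm = 300),
    tarps = list(
      names = c("white", "silver", "black"),
      reflectance = c(white = 0.85, silver = 0.45, black = 0.05),
      emissivity = c(white = 0.92, silver = 0.80, black = 0.96),
      t_thermocouple = c(white = 305, silver = 315, black = 325),
      size_m = 9
    )
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over)))) {
      stop("overrides must be named", call. = FALSE)
    }
    for (nm in names(over)) {
      if (!nm %in% names(cfg)) {
        stop(sprintf("unknown configuration section '%s'", nm), call. = FALSE)
      }
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], as.list(over[[nm]]))
    }
  }
  structure(cfg, class = "scene_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Reads nested overrides from YAML and merges them over [scene_config()]
#' defaults.
#'
#' @param path path to a YAML file whose top-level keys are configuration
#'   sections.
#' @return A `scene_config` list.
#' @export
read_scene_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                               call. = FALSE)
  over <- yaml::read_yaml(path)
  do.call(scene_config, over)
}

vnir_wavelengths <- function(config) {
  r <- config$sensor$vnir_range_nm
  seq(r[1], r[2], by = config$sensor$vnir_step_nm)
}

thermal_band_from_config <- function(config) {
  do.call(band_response, config$sensor$thermal_band)
}
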