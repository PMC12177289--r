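# Shared fixtures: small configurations and toy rasters built in code.

# Two-block scene (one burned, one hayed block): smallest layout exercising
# both managements and all three seeding levels.
tiny_config <- function(...) {
  scene_config(layout = list(n_blocks = 2L, block_cols = 1L,
                             margin_x = 20, margin_y = 25), ...)
}

# Monte-Carlo configuration: the full 8-block design with narrow margins and
# a coarser spectral grid to keep replicated end-to-end runs affordable.
mc_config <- function(...) {
  scene_config(layout = list(margin_x = 20, margin_y = 25),
               sensor = list(vnir_step_nm = 9.2), ...)
}

# Memoized pipeline run shared by tests that only inspect its outputs.
.fixture_env <- new.env()
pipeline_fixture <- function() {
  if (is.null(.fixture_env$res)) {
    .fixture_env$res <- run_pipeline(tiny_config(), seed = 7, noise = TRUE)
  }
  .fixture_env$res
}

# Toy reflectance cube: constant value per band over an nr x nc grid.
toy_cube <- function(band_values, wavelengths, nr = 4, nc = 5, gsd = 1,
                     units = "reflectance") {
  v <- array(rep(band_values, each = nr * nc), dim = c(nr, nc, length(band_values)))
  spectral_cube(v, wavelengths, gsd, units = units)
}

# Minimal cover table for hand-checked diversity arithmetic.
toy_cover_table <- function(covers, groups, items = NULL,
                            plot_id = 1L, location_id = 1L,
                            x = 50, y = 45,
                            seeding = "control", management = "burn") {
  if (is.null(items)) items <- paste0("sp", seq_along(covers))
  df <- data.frame(plot_id = plot_id, location_id = location_id,
                   type = "center", x = x, y = y,
                   seeding = seeding, management = management,
                   item = items, group = groups, percent_cover = covers,
                   stringsAsFactors = FALSE)
  class(df) <- c("cover_table", "data.frame")
  df
}
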