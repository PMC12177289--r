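# End-to-end pipeline: simulate -> calibrate -> indices -> retrieve LST ->
# survey -> linkage, with a reproducibility manifest.

#' Run the full synthetic-scene analysis pipeline
#'
#' Executes every stage in order on one seeded synthetic scene: experiment
#' layout, quadrat cover tables, ground truth, forward VNIR and thermal
#' simulation, empirical-line calibration, vegetation indices, tarp-anchored
#' atmospheric solve and LST retrieval, edge filtering and diversity
#' metrics, community matrix with rare-species filter and Bray-Curtis
#' distances, and the grouped regressions and ANCOVA contrasts of every
#' index against Shannon diversity and C3 cover. Identical config and seed
#' reproduce identical outputs.
#'
#' @param config a [scene_config()].
#' @param seed integer root seed; every stage derives its own stream from it.
#' @param noise logical; include sensor noise (default `TRUE`).
#' @param out_dir optional directory; when given, stage outputs are written
#'   as CSV/ENVI files plus a JSON run manifest.
#' @param edge_buffer_m edge filter buffer in meters (default 5).
#' @param rare_threshold rare-species threshold in percent (default 5).
#' @return A list with all stage outputs (`layout`, `cover`, `truth`,
#'   `vnir`, `thermal`, `reflectance`, `indices`, `atm`, `lst`,
#'   `diversity`, `community`, `bray`, `linkage`, `regressions`, `ancova`)
#'   and `manifest`.
#' @export
run_pipeline <- function(config = scene_config(), seed = 1L, noise = TRUE,
                         out_dir = NULL, edge_buffer_m = 5,
                         rare_threshold = 5) {
  t0 <- Sys.time()
  layout <- make_layout(config, seed)
  cover <- sample_cover_tables(layout, config, seed)
  truth <- make_scene_truth(layout, config, seed)
  vnir <- forward_vnir(truth, config, seed, noise = noise)
  thermal <- forward_thermal(truth, config = config, seed = seed,
                             noise = noise)

  el <- empirical_line_fit(vnir$tarp_radiance, vnir$tarps$reflectance,
                           wavelengths_nm = vnir$cube$wavelengths)
  reflectance <- apply_empirical_line(vnir$cube, el)
  indices <- list(ndvi = ndvi(reflectance), wbi = wbi(reflectance),
                  albedo = albedo_vnir(reflectance))

  tarp_rec <- thermal$tarps
  tarp_rec$emissivity_est <- tarp_emissivity(tarp_rec$t_irt,
                                             tarp_rec$t_thermocouple)
  atm <- solve_atmosphere(
    data.frame(name = tarp_rec$name, emissivity = tarp_rec$emissivity_est,
               t_surface = tarp_rec$t_thermocouple,
               radiance = tarp_rec$radiance),
    thermal$band)
  nd_thermal <- resample_to_grid(indices$ndvi, thermal$image)
  eps <- emissivity_from_ndvi(nd_thermal,
                              do.call(emissivity_model, config$emissivity))
  lst <- retrieve_lst(thermal$image, atm, eps$emissivity, thermal$band)

  filtered <- edge_filter(cover, layout, edge_buffer_m)
  diversity <- diversity_metrics(filtered)
  community <- relative_cover_matrix(filtered)
  community_f <- rare_species_filter(community, rare_threshold)
  bray <- bray_curtis(community_f)

  linkage <- build_linkage_dataset(diversity, indices, lst)
  responses <- c("ndvi", "wbi", "albedo", "temperature")
  regressions <- do.call(rbind, c(
    lapply(responses, function(r)
      grouped_regressions(linkage, r, "shannon_species")),
    lapply(responses, function(r)
      grouped_regressions(linkage, r, "cover_c3"))))
  ancova_tests <- do.call(rbind, lapply(responses, function(r) {
    do.call(rbind, lapply(c("management", "seeding"), function(g) {
      do.call(rbind, lapply(c("shannon_species", "cover_c3"), function(p) {
        a <- ancova(linkage, r, p, g)
        data.frame(response = r, predictor = p, group = g,
                   interaction_f = a$interaction_f,
                   interaction_p = a$interaction_p,
                   group_f = a$group_f, group_p = a$group_p,
                   stringsAsFactors = FALSE)
      }))
    }))
  }))

  manifest <- list(
    package_version = as.character(utils::packageVersion("prairiescape")),
    seed = seed, noise = noise,
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    scene_px = c(ny = truth$grid$ny, nx = truth$grid$nx),
    n_bands = length(truth$reflectance$wavelengths),
    n_plots = nrow(layout$plots),
    n_locations = length(unique(paste(cover$plot_id, cover$location_id))),
    n_locations_retained = nrow(diversity),
    n_edge_dropped = attr(filtered, "n_dropped"),
    n_species_total = ncol(community),
    n_species_retained = attr(community_f, "n_retained"),
    reflectance_clamped = as.list(reflectance$clamped),
    lst_missing = lst$n_missing,
    atmosphere = list(tau = atm$tau, l_down = atm$l_down, l_up = atm$l_up),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  out <- list(layout = layout, cover = cover, truth = truth, vnir = vnir,
              thermal = thermal, empirical_line = el,
              reflectance = reflectance, indices = indices, atm = atm,
              lst = lst, diversity = diversity, community = community_f,
              bray = bray, linkage = linkage, regressions = regressions,
              ancova = ancova_tests, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_csv(layout$plots, file.path(out_dir, "layout_plots.csv"))
    write_table_csv(cover, file.path(out_dir, "cover_table.csv"))
    write_table_csv(diversity, file.path(out_dir, "diversity.csv"))
    write_table_csv(as.data.frame(linkage),
                    file.path(out_dir, "linkage_dataset.csv"))
    write_table_csv(regressions, file.path(out_dir, "regressions.csv"))
    write_table_csv(ancova_tests, file.path(out_dir, "ancova.csv"))
    utils::write.csv(community_f, file.path(out_dir, "community_matrix.csv"))
    utils::write.csv(bray, file.path(out_dir, "bray_curtis.csv"))
    for (nm in names(indices)) {
      write_raster(indices[[nm]], file.path(out_dir, paste0(nm, ".bsq")))
    }
    write_raster(lst$temperature, file.path(out_dir, "lst.bsq"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Tabulate grouped regressions like the treatment tables
#'
#' Reshapes a [grouped_regressions()] result into the wide layout used for
#' reporting: one row per response, columns overall / burn / hay / control /
#' mid / high, cells `r2` with significance code (`ns` when p >= 0.05).
#'
#' @param regressions output of [grouped_regressions()] (possibly several
#'   responses bound together) for one predictor.
#' @return A character data frame, rows = responses.
#' @export
regression_table <- function(regressions) {
  cols <- c("all", "burn", "hay", "control", "mid", "high")
  responses <- unique(regressions$response)
  out <- do.call(rbind, lapply(responses, function(r) {
    row <- vapply(cols, function(g) {
      m <- regressions[regressions$response == r & regressions$group == g, ]
      if (!nrow(m)) return("-")
      if (m$code == "ns") "ns" else sprintf("%.3g%s", m$r2, m$code)
    }, character(1))
    data.frame(response = r, t(row), stringsAsFactors = FALSE)
  }))
  names(out) <- c("response", "overall", "burn", "hay", "control", "mid",
                  "high")
  rownames(out) <- NULL
  out
}
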