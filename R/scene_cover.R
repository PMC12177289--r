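# Species pool and quadrat cover simulation.

#' Default prairie species pool
#'
#' Eighteen species in three functional groups (C3 grasses, C4 grasses,
#' forbs) with relative abundance weights per seeding treatment. Control
#' plots are dominated by smooth brome (C3) and a weedy forb; the mid mix
#' spreads cover over short/mid-stature natives; the high mix is dominated by
#' tall C4 grasses with a diverse forb component.
#'
#' @return A list of class `species_pool`: `species` (data frame with
#'   `species`, `group`) and `weights` (species x seeding matrix of
#'   nonnegative relative abundances).
#' @export
default_species_pool <- function() {
  species <- data.frame(
    species = c("smooth_brome", "kentucky_bluegrass", "western_wheatgrass",
                "canada_wildrye",
                "indiangrass", "big_bluestem", "switchgrass",
                "little_bluestem", "sideoats_grama", "prairie_dropseed",
                "field_bindweed", "goldenrod", "black_eyed_susan",
                "purple_coneflower", "yarrow", "prairie_clover",
                "wild_bergamot", "heath_aster"),
    group = c(rep("C3", 4), rep("C4", 6), rep("forb", 8)),
    stringsAsFactors = FALSE
  )
  weights <- cbind(
    control = c(70, 8, 0, 0,   6, 0, 0, 0, 0, 0,   14, 2, 0, 0, 0, 0, 0, 0),
    mid     = c(14, 4, 5, 6,   4, 0, 0, 10, 9, 7,   3, 6, 8, 8, 5, 6, 3, 2),
    high    = c(5, 2, 3, 3,   20, 12, 8, 5, 3, 2,   1, 5, 6, 6, 4, 6, 5, 4)
  )
  rownames(weights) <- species$species
  structure(list(species = species, weights = weights),
            class = "species_pool")
}

# Per-plot ground-truth conditions shared by the cover sampler and the scene
# truth, so quadrat tables and imagery stay spatially consistent. A latent
# establishment effect per plot shifts vegetation cover and tilts composition
# from C3 toward C4/forbs.
plot_conditions <- function(layout, config = scene_config(), seed = 1L,
                            pool = default_species_pool()) {
  cc <- config$cover
  if (any(pool$weights < 0)) {
    stop("species pool weights must be nonnegative", call. = FALSE)
  }
  if (any(cc$veg_mean < 0) || any(cc$veg_mean > 1) ||
      any(cc$litter_share < 0) || any(cc$litter_share > 1)) {
    stop("cover configuration produces covers outside [0, 1]", call. = FALSE)
  }
  plots <- layout$plots
  n <- nrow(plots)
  latent <- with_seed(stage_seed(seed, "plot_conditions"),
                      stats::rnorm(n, 0, cc$plot_sd))
  veg <- clamp(cc$veg_mean[plots$seeding] +
                 cc$burn_veg_boost * (plots$management == "burn") + latent,
               0.05, 0.98)
  litter <- cc$litter_share[plots$management] * (1 - veg)
  bare <- (1 - veg) - litter
  grp <- pool$species$group
  shares <- t(vapply(seq_len(n), function(i) {
    w <- pool$weights[, plots$seeding[i]]
    if (plots$management[i] == "burn") w <- w * cc$burn_modifier[grp]
    tilt <- ifelse(grp == "C3", exp(-cc$comp_tilt * latent[i]),
                   exp(cc$comp_tilt * latent[i]))
    w <- w * tilt
    w / sum(w)
  }, numeric(nrow(pool$species))))
  colnames(shares) <- pool$species$species
  list(plots = cbind(plots[, c("plot_id", "block_id", "seeding", "management")],
                     veg = unname(veg), litter = unname(litter),
                     bare = unname(bare), latent = latent),
       shares = shares, pool = pool)
}

#' Simulate quadrat species percent-cover tables
#'
#' Draws a percent-cover record for every survey location of the layout:
#' per-species vegetation cover (quadrat total vegetation cover <= 100) plus
#' explicit litter and bare-soil rows, so each location's rows sum to 100.
#' Treatment effects hold in expectation: seeding raises richness and the
#' C4/forb share; burning lowers litter and the C3 share and raises bare
#' soil.
#'
#' @param layout an [make_layout()] result.
#' @param config a [scene_config()].
#' @param seed integer seed.
#' @param pool a [default_species_pool()]-shaped species pool.
#' @return A data frame of class `cover_table` with one row per location x
#'   recorded item: `plot_id`, `location_id`, `type`, `x`, `y`, `seeding`,
#'   `management`, `item` (species name, `"litter"` or `"bare_soil"`),
#'   `group` (`"C3"`, `"C4"`, `"forb"` or `"ground"`) and `percent_cover`.
#' @export
sample_cover_tables <- function(layout, config = scene_config(), seed = 1L,
                                pool = default_species_pool()) {
  cc <- config$cover
  design <- make_survey_design(layout)
  cond <- plot_conditions(layout, config, seed, pool)
  grp <- pool$species$group
  nsp <- nrow(pool$species)
  rows <- with_seed(stage_seed(seed, "cover_tables"), {
    lapply(seq_len(nrow(design)), function(i) {
      p <- which(cond$plots$plot_id == design$plot_id[i])
      veg_loc <- clamp(cond$plots$veg[p] + stats::rnorm(1, 0, cc$location_sd),
                       0.02, 0.99)
      sh <- cond$shares[p, ] * stats::rlnorm(nsp, 0, cc$species_lnorm_sd)
      sh <- sh / sum(sh)
      sh[sh < cc$min_share] <- 0
      sh <- sh / sum(sh)
      rem <- 1 - veg_loc
      litter_share <- clamp(
        cc$litter_share[cond$plots$management[p]] +
          stats::rnorm(1, 0, cc$litter_sd), 0, 1)
      cover <- c(sh * veg_loc, litter_share * rem,
                 (1 - litter_share) * rem) * 100
      keep <- cover > 0 | c(rep(FALSE, nsp), TRUE, TRUE)
      data.frame(
        plot_id = design$plot_id[i], location_id = design$location_id[i],
        type = design$type[i], x = design$x[i], y = design$y[i],
        seeding = cond$plots$seeding[p],
        management = cond$plots$management[p],
        item = c(pool$species$species, "litter", "bare_soil")[keep],
        group = c(grp, "ground", "ground")[keep],
        percent_cover = cover[keep],
        stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cover_table", "data.frame")
  out
}
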