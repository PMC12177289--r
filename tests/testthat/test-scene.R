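test_that("default layout has 24 plots in 8 blocks with balanced treatments", {
  lay <- make_layout(scene_config(), seed = 1)
  expect_equal(nrow(lay$plots), 24L)
  expect_equal(nrow(lay$blocks), 8L)
  # each block holds one plot of each seeding level and a single management
  for (b in unique(lay$plots$block_id)) {
    sub <- lay$plots[lay$plots$block_id == b, ]
    expect_setequal(sub$seeding, c("control", "mid", "high"))
    expect_equal(length(unique(sub$management)), 1L)
  }
  expect_equal(sum(lay$plots$management == "burn"), 12L)
  # all plots inside the scene extent
  expect_true(all(lay$plots$xmin >= 0 & lay$plots$xmax <= lay$extent["width"]))
  expect_true(all(lay$plots$ymin >= 0 & lay$plots$ymax <= lay$extent["height"]))
  # plot rectangles are pairwise disjoint
  p <- lay$plots
  for (i in seq_len(nrow(p) - 1)) {
    for (j in seq(i + 1, nrow(p))) {
      ox <- min(p$xmax[i], p$xmax[j]) - max(p$xmin[i], p$xmin[j])
      oy <- min(p$ymax[i], p$ymax[j]) - max(p$ymin[i], p$ymin[j])
      expect_false(ox > 0 && oy > 0)
    }
  }
})

test_that("layout generation is deterministic and respects size limits", {
  a <- make_layout(scene_config(), seed = 11)
  b <- make_layout(scene_config(), seed = 11)
  expect_identical(a, b)
  c <- make_layout(scene_config(), seed = 12)
  expect_false(identical(a$plots$seeding, c$plots$seeding))
  one <- make_layout(scene_config(layout = list(n_blocks = 1L)), seed = 1)
  expect_equal(nrow(one$plots), 3L)
  expect_setequal(one$plots$seeding, c("control", "mid", "high"))
  expect_error(make_layout(scene_config(layout = list(plot_w = -5))), "extent")
})

test_that("survey design yields 15 locations per plot (9 transect-derived + 6 subplots)", {
  lay <- make_layout(tiny_config(), seed = 1)
  d <- make_survey_design(lay)
  counts <- table(d$plot_id)
  expect_true(all(counts == 15))
  one <- d[d$plot_id == 1, ]
  expect_equal(sum(one$type %in% c("center", "transect")), 9L)
  expect_equal(sum(one$type == "subplot"), 6L)
  # no subplots leaves only the 9 transect-derived locations
  d9 <- make_survey_design(lay, subplots = FALSE)
  expect_true(all(table(d9$plot_id) == 9))
  # all locations inside their plot
  p <- lay$plots[match(d$plot_id, lay$plots$plot_id), ]
  expect_true(all(d$x >= p$xmin & d$x <= p$xmax &
                    d$y >= p$ymin & d$y <= p$ymax))
  small <- make_layout(scene_config(layout = list(plot_w = 25, plot_h = 25,
                                                  n_blocks = 1L)), 1)
  expect_error(make_survey_design(small), "30 m")
})

test_that("spectral design yields 60 positions per plot, 15 per transect arm", {
  lay <- make_layout(tiny_config(), seed = 1)
  d <- make_spectral_design(lay)
  expect_true(all(table(d$plot_id) == 60))
  north <- make_spectral_design(lay, arms = "N")
  expect_true(all(table(north$plot_id) == 15))
  p <- lay$plots[match(d$plot_id, lay$plots$plot_id), ]
  expect_true(all(d$x >= p$xmin & d$x <= p$xmax &
                    d$y >= p$ymin & d$y <= p$ymax))
})

test_that("cover tables are deterministic, conserved and carry the treatments", {
  cfg <- tiny_config()
  lay <- make_layout(cfg, 2)
  a <- sample_cover_tables(lay, cfg, 5)
  b <- sample_cover_tables(lay, cfg, 5)
  expect_identical(a, b)
  expect_false(identical(a, sample_cover_tables(lay, cfg, 6)))
  # per location: vegetation <= 100 and vegetation + litter + bare == 100
  sums <- tapply(a$percent_cover, paste(a$plot_id, a$location_id), sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  veg <- a$group != "ground"
  veg_sum <- tapply(a$percent_cover[veg],
                    paste(a$plot_id, a$location_id)[veg], sum)
  expect_true(all(veg_sum <= 100 + 1e-9))
  expect_true(all(a$percent_cover >= 0))
  expect_true(all(!duplicated(a[, c("plot_id", "location_id", "item")])))
})

test_that("configured treatment effects hold in expectation across draws", {
  cfg <- tiny_config()
  lay <- make_layout(cfg, 3)
  litter_by_mgmt <- function(tab) {
    lit <- tab[tab$item == "litter", ]
    tapply(lit$percent_cover, lit$management, mean)
  }
  stats <- sapply(1:10, function(s) {
    tab <- sample_cover_tables(lay, cfg, s)
    div <- diversity_metrics(tab)
    c(litter_by_mgmt(tab),
      rich_control = mean(div$richness[div$seeding == "control"]),
      rich_high = mean(div$richness[div$seeding == "high"]),
      c3_control = mean(div$cover_c3[div$seeding == "control"]),
      c3_high = mean(div$cover_c3[div$seeding == "high"]),
      bare_burn = mean(div$bare_fraction[div$management == "burn"]),
      bare_hay = mean(div$bare_fraction[div$management == "hay"]))
  })
  m <- rowMeans(stats)
  expect_lt(m["burn"], m["hay"])                 # burning lowers litter
  expect_gt(m["rich_high"], m["rich_control"])   # seeding raises richness
  expect_lt(m["c3_high"], m["c3_control"])       # seeding lowers C3 share
  expect_gt(m["bare_burn"], m["bare_hay"])       # burning exposes soil
})

test_that("scene truth mixes pure pixels to their endmember spectra", {
  # outside-plot background forced to pure green vegetation, no field noise
  cfg <- tiny_config(cover = list(background = c(green = 1, litter = 0,
                                                 soil = 0),
                                  field_sd = 0),
                     water = list(scale = 0.5, noise_sd = 0))
  lay <- make_layout(cfg, 1)
  tr <- make_scene_truth(lay, cfg, 1)
  wl <- tr$reflectance$wavelengths
  em <- endmember_spectra(wl, cfg)
  ec <- cfg$endmembers
  absorb <- ec$water_depth * exp(-((wl - ec$water_center_nm) /
                                     ec$water_sigma_nm)^2)
  want <- em["green", ] * (1 - absorb * 0.5)
  got <- tr$reflectance$values[2, 2, ]   # a corner pixel outside every plot
  expect_equal(got, unname(want), tolerance = 1e-12)
  expect_equal(tr$cover$green[2, 2], 1)
})

test_that("cover fractions sum to one and truth obeys its physical ranges", {
  cfg <- tiny_config()
  lay <- make_layout(cfg, 4)
  tr <- make_scene_truth(lay, cfg, 4)
  s <- tr$cover$green + tr$cover$litter + tr$cover$soil
  expect_lt(max(abs(s - 1)), 1e-9)
  expect_true(all(tr$cover$green >= 0 & tr$cover$green <= 1))
  expect_true(all(tr$reflectance$values >= 0 & tr$reflectance$values <= 1))
  expect_true(all(tr$temperature > 280 & tr$temperature < 330))
  expect_true(all(tr$water >= 0))
  # temperature is anticorrelated with green cover
  expect_lt(cor(as.vector(tr$temperature), as.vector(tr$cover$green)), 0)
})

test_that("null temperature coupling yields a flat expected field", {
  cfg <- tiny_config(temperature = list(cool_green = 0, cool_water = 0,
                                        noise_sd = 0))
  lay <- make_layout(cfg, 1)
  tr <- make_scene_truth(lay, cfg, 1)
  expect_true(all(tr$temperature == cfg$temperature$base_k))
})

test_that("WBI increases with the simulator's water content", {
  wl <- seq(850, 1000, by = 2.3)
  cfg <- scene_config()
  w_levels <- c(0, 0.3, 0.6, 0.9)
  wbis <- vapply(w_levels, function(w) {
    em <- endmember_spectra(wl, cfg, water = w)
    cube <- toy_cube(em["green", ], wl, nr = 1, nc = 1)
    wbi(cube)$values[1, 1]
  }, numeric(1))
  expect_true(all(diff(wbis) > 0))
})

test_that("forward VNIR is linear in reflectance with brighter tarps brighter", {
  cfg <- tiny_config(vnir_cal = list(gain0 = 1, gain_slope = 0, offset0 = 0))
  lay <- make_layout(cfg, 1)
  tr <- make_scene_truth(lay, cfg, 1)
  fv <- forward_vnir(tr, cfg, 1, noise = FALSE)
  # unit gain, zero offset: radiance equals reflectance off the tarps
  expect_equal(fv$cube$values[2, 2, ], tr$reflectance$values[2, 2, ],
               tolerance = 1e-12)
  expect_true(all(fv$tarp_radiance["white", ] > fv$tarp_radiance["black", ]))
  bad <- tiny_config(vnir_cal = list(gain0 = -1))
  expect_error(forward_vnir(tr, bad, 1, noise = FALSE), "gain")
})

test_that("noise-free empirical line on simulated tarps recovers the truth", {
  cfg <- tiny_config()
  lay <- make_layout(cfg, 1)
  tr <- make_scene_truth(lay, cfg, 1)
  fv <- forward_vnir(tr, cfg, 1, noise = FALSE)
  fit <- empirical_line_fit(fv$tarp_radiance, fv$tarps$reflectance)
  expect_lt(max(abs(fit$gain - fv$gain) / fv$gain), 1e-9)
  expect_lt(max(abs(fit$offset - fv$offset)), 1e-9)
})

test_that("transparent-atmosphere unit-emissivity thermal image is the Planck field", {
  cfg <- tiny_config(emissivity = list(eps_soil = 1, eps_veg = 1),
                     atmosphere = list(tau = 1, l_down = 0, l_up = 0))
  lay <- make_layout(cfg, 1)
  tr <- make_scene_truth(lay, cfg, 1)
  ft <- forward_thermal(tr, config = cfg, seed = 1, noise = FALSE)
  off <- !ft$tarp_mask
  b <- planck_band_radiance(as.vector(ft$t_eff$values[off]), ft$band)
  expect_equal(as.vector(ft$image$values[off]), b, tolerance = 1e-6)
})

test_that("same seed reproduces bit-identical truth and imagery", {
  cfg <- tiny_config()
  lay <- make_layout(cfg, 9)
  t1 <- make_scene_truth(lay, cfg, 9)
  t2 <- make_scene_truth(lay, cfg, 9)
  expect_identical(t1$temperature, t2$temperature)
  expect_identical(t1$reflectance$values, t2$reflectance$values)
  f1 <- forward_vnir(t1, cfg, 9)
  f2 <- forward_vnir(t2, cfg, 9)
  expect_identical(f1$cube$values, f2$cube$values)
})
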