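test_that("edge filter drops locations by point-to-boundary distance", {
  lay <- make_layout(tiny_config(), seed = 1)
  p <- lay$plots[1, ]
  tab <- toy_cover_table(c(50, 30), c("C3", "forb"))
  # duplicate the rows for three locations at chosen offsets from the edge
  make_loc <- function(id, x, y) {
    t <- toy_cover_table(c(50, 30), c("C3", "forb"),
                         location_id = id, x = x, y = y)
    t$plot_id <- p$plot_id
    t
  }
  tab <- rbind(make_loc(1, (p$xmin + p$xmax) / 2, (p$ymin + p$ymax) / 2),
               make_loc(2, p$xmin + 3, p$ymin + 20),   # 3 m from west edge
               make_loc(3, p$xmin + 5, p$ymin + 20))   # exactly 5 m
  class(tab) <- c("cover_table", "data.frame")
  out <- edge_filter(tab, lay, 5)
  expect_setequal(unique(out$location_id), c(1, 3))
  expect_equal(attr(out, "n_dropped"), 1L)
  # zero buffer keeps everything
  out0 <- edge_filter(tab, lay, 0)
  expect_equal(attr(out0, "n_dropped"), 0L)
  expect_equal(nrow(out0), nrow(tab))
  # locations outside their plot are data errors
  bad <- rbind(tab, {
    t <- make_loc(4, p$xmin - 10, p$ymin); t
  })
  class(bad) <- c("cover_table", "data.frame")
  expect_error(edge_filter(bad, lay, 5), "outside")
})

test_that("survey locations of the generated design survive the 5 m edge filter", {
  cfg <- tiny_config()
  lay <- make_layout(cfg, 1)
  tab <- sample_cover_tables(lay, cfg, 1)
  out <- edge_filter(tab, lay, 5)
  expect_equal(attr(out, "n_dropped"), 0L)
})

test_that("Shannon diversity hits the uniform and monoculture limits", {
  uni <- diversity_metrics(toy_cover_table(c(20, 20, 20),
                                           c("C3", "C4", "forb")))
  expect_equal(uni$richness, 3)
  expect_equal(uni$shannon_species, log(3), tolerance = 1e-12)
  expect_equal(uni$shannon_functional, log(3), tolerance = 1e-12)
  mono <- diversity_metrics(toy_cover_table(80, "C3"))
  expect_equal(mono$richness, 1)
  expect_equal(mono$shannon_species, 0)
  # equal covers maximize H at ln(richness)
  uneven <- diversity_metrics(toy_cover_table(c(50, 9, 1),
                                              c("C3", "C4", "forb")))
  expect_lt(uneven$shannon_species, log(3))
})

test_that("functional-group Shannon matches hand arithmetic and aggregation bound", {
  tab <- toy_cover_table(c(60, 30, 10), c("C4", "C3", "forb"))
  d <- diversity_metrics(tab)
  expect_equal(d$shannon_functional, 0.8979457248567797, tolerance = 1e-12)
  expect_equal(d$cover_c4, 60)
  expect_equal(d$cover_c3, 30)
  expect_equal(d$cover_forb, 10)
  # property: aggregating species into groups can only lose entropy
  set.seed(31)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    covers <- runif(k, 1, 40)
    groups <- sample(c("C3", "C4", "forb"), k, replace = TRUE)
    d <- diversity_metrics(toy_cover_table(covers, groups))
    expect_lte(d$shannon_functional, d$shannon_species + 1e-12)
    expect_lte(d$shannon_species, log(d$richness) + 1e-12)
  }
})

test_that("ground rows are excluded from diversity but kept as fractions", {
  tab <- toy_cover_table(c(40, 20, 25, 15), c("C3", "C4", "ground", "ground"),
                         items = c("a", "b", "litter", "bare_soil"))
  d <- diversity_metrics(tab)
  expect_equal(d$richness, 2)
  p <- c(40, 20) / 60
  expect_equal(d$shannon_species, -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(d$veg_fraction, 0.6)
  expect_equal(d$litter_fraction, 0.25)
  expect_equal(d$bare_fraction, 0.15)
  bad <- toy_cover_table(c(10, 10), c("C3", "weird"))
  expect_error(diversity_metrics(bad), "functional group")
})

test_that("relative cover matrix normalizes plot rows over vegetation only", {
  t1 <- toy_cover_table(c(30, 10, 20), c("C3", "C4", "ground"),
                        items = c("a", "b", "litter"), plot_id = 1)
  t2 <- toy_cover_table(c(10, 30, 40), c("C3", "forb", "ground"),
                        items = c("a", "c", "bare_soil"), plot_id = 2)
  tab <- rbind(t1, t2)
  class(tab) <- c("cover_table", "data.frame")
  m <- relative_cover_matrix(tab)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(m["1", c("a", "b", "c")], c(a = 0.75, b = 0.25, c = 0))
  expect_equal(m["2", c("a", "b", "c")], c(a = 0.25, b = 0, c = 0.75))
  expect_true(all(abs(rowSums(m) - 1) < 1e-12))
  # plot-level aggregation is the mean over locations first
  t1b <- toy_cover_table(c(10, 30), c("C3", "C4"), items = c("a", "b"),
                         plot_id = 1, location_id = 2)
  tab2 <- rbind(t1, t1b)
  class(tab2) <- c("cover_table", "data.frame")
  m2 <- relative_cover_matrix(tab2)
  expect_equal(unname(m2["1", c("a", "b")]), c(0.5, 0.5))
  # a vegetation-free plot is excluded with a warning
  t3 <- toy_cover_table(100, "ground", items = "litter", plot_id = 3)
  tab3 <- rbind(t1, t2, t3)
  class(tab3) <- c("cover_table", "data.frame")
  expect_warning(m3 <- relative_cover_matrix(tab3), "without vegetation")
  expect_equal(nrow(m3), 2L)
})

test_that("rare-species filter removes below-threshold species and is idempotent", {
  m <- rbind(p1 = c(0.50, 0.46, 0.04), p2 = c(0.60, 0.36, 0.04))
  colnames(m) <- c("a", "b", "c")
  attr(m, "units") <- "fraction"
  f <- rare_species_filter(m, 5)
  expect_equal(colnames(f), c("a", "b"))
  expect_equal(attr(f, "n_removed"), 1L)
  expect_identical(unclass(rare_species_filter(f, 5))[, ], f[, ])
  # threshold 0 removes nothing
  expect_equal(ncol(rare_species_filter(m, 0)), 3L)
  # percent-scaled matrices use the threshold directly
  mp <- m * 100
  attr(mp, "units") <- "percent"
  expect_equal(ncol(rare_species_filter(mp, 5)), 2L)
  # mean statistic: species b max 0.46 but mean 0.41
  expect_equal(ncol(rare_species_filter(m, 45, stat = "mean")), 1L)
  expect_equal(ncol(rare_species_filter(m, 45, stat = "max")), 2L)
})

test_that("Bray-Curtis hits its extremes and hand value, and is a proper distance", {
  m <- rbind(a = c(0.7, 0.3, 0), b = c(0.2, 0.3, 0.5),
             same1 = c(0.5, 0.5, 0), same2 = c(0.5, 0.5, 0),
             left = c(1, 0, 0), right = c(0, 0, 1))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 0.5, tolerance = 1e-12)
  expect_equal(d["same1", "same2"], 0)
  expect_equal(d["left", "right"], 1)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  expect_error(bray_curtis(rbind(c(-1, 2))), "nonnegative")
  z <- rbind(a = c(1, 0), z1 = c(0, 0), z2 = c(0, 0))
  dz <- bray_curtis(z)
  expect_true(is.na(dz["z1", "z2"]))
})

test_that("box summaries follow the quartile and 1.5 IQR whisker rules", {
  b <- box_summary(1:9, rep("control", 9), rep("burn", 9))
  expect_equal(b$median, 5)
  expect_equal(b$q1, 3)
  expect_equal(b$q3, 7)
  expect_equal(b$whisker_lo, 1)
  expect_equal(b$whisker_hi, 9)
  expect_equal(b$n_outliers, 0L)
  const <- box_summary(rep(2, 5), rep("mid", 5), rep("hay", 5))
  expect_equal(const$q1, const$q3)
  expect_equal(const$n_outliers, 0L)
  # a single extreme point beyond 1.5 IQR is an outlier
  v <- c(1:9, 100)
  out <- box_summary(v, rep("high", 10), rep("burn", 10))
  expect_equal(out$n_outliers, 1L)
  expect_equal(out$outliers[[1]], 100)
  expect_lt(out$whisker_hi, 100)
  expect_warning(
    box_summary(c(1, 2), c("control", "mid"), c("burn", "hay")),
    "omitted")
})
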