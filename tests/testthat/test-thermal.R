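test_that("tarp emissivity follows the Stefan-Boltzmann temperature ratio", {
  expect_equal(tarp_emissivity(310, 310), 1.0)
  expect_equal(tarp_emissivity(310, 312.5), 0.968381956096, tolerance = 1e-12)
  expect_warning(e <- tarp_emissivity(313, 312.5), "clipped")
  expect_equal(e, 1.0)
  expect_error(tarp_emissivity(-1, 300), "positive")
})

test_that("three-tarp solve recovers the atmosphere exactly from forward radiances", {
  band <- band_response()
  truth <- atmospheric_state(0.8, 2.0, 1.5)
  tarps <- data.frame(name = c("a", "b", "c"),
                      emissivity = c(0.88, 0.93, 0.97),
                      t_surface = c(300, 310, 320))
  tarps$radiance <- thermal_at_sensor(tarps$t_surface, tarps$emissivity,
                                      truth, band)
  est <- solve_atmosphere(tarps, band)
  expect_equal(est$tau, truth$tau, tolerance = 1e-9)
  expect_equal(est$l_down, truth$l_down, tolerance = 1e-9)
  expect_equal(est$l_up, truth$l_up, tolerance = 1e-9)
})

test_that("transparent-atmosphere tarps recover the identity atmosphere", {
  band <- band_response()
  truth <- atmospheric_state(1, 0, 0)
  tarps <- data.frame(emissivity = c(0.85, 0.92, 0.99),
                      t_surface = c(295, 308, 322))
  tarps$radiance <- thermal_at_sensor(tarps$t_surface, tarps$emissivity,
                                      truth, band)
  est <- solve_atmosphere(tarps, band)
  expect_equal(est$tau, 1, tolerance = 1e-9)
  expect_equal(est$l_down, 0, tolerance = 1e-9)
  expect_equal(est$l_up, 0, tolerance = 1e-9)
})

test_that("degenerate tarp sets raise an error naming the collinear pair", {
  band <- band_response()
  tarps <- data.frame(name = c("white", "silver", "black"),
                      emissivity = c(0.9, 0.9, 0.95),
                      t_surface = c(300, 300, 315),
                      radiance = c(8, 8, 9))
  expect_error(solve_atmosphere(tarps, band), "white.*silver|silver.*white")
})

test_that("ground-brightness correction inverts the atmospheric terms", {
  band <- band_response()
  atm <- atmospheric_state(0.9, 1.2, 0.7)
  eps <- matrix(c(0.95, 0.97, 0.985, 1), 2, 2)
  ts <- matrix(c(295, 305, 315, 300), 2, 2)
  l <- raster_layer(matrix(thermal_at_sensor(as.vector(ts), as.vector(eps),
                                             atm, band), 2, 2), gsd = 1)
  ground <- to_ground_brightness(l, atm)
  b <- matrix(planck_band_radiance(as.vector(ts), band), 2, 2)
  expect_equal(ground$values, eps * b + (1 - eps) * atm$l_down,
               tolerance = 1e-12)
  ident <- to_ground_brightness(l, atmospheric_state(1, 5, 0))
  expect_identical(ident$values, l$values)
  expect_error(to_ground_brightness(l, atmospheric_state(5e-4, 0, 0)),
               "floor")
})

test_that("NDVI-threshold emissivity hits the endpoint values and stays continuous", {
  m <- emissivity_model()
  e <- emissivity_from_ndvi(c(0.1, 0.19, 0.6, 0.9), m)$emissivity
  expect_identical(e[1:2], c(0.95, 0.95))
  expect_identical(e[3:4], c(0.985, 0.985))
  mid <- emissivity_from_ndvi(0.35, m)  # P_v = 0.5
  expect_equal(mid$p_v, 0.5)
  expect_equal(mid$emissivity, 0.9675)
  h <- 1e-9
  for (thr in c(m$ndvi_soil, m$ndvi_veg)) {
    left <- emissivity_from_ndvi(thr - h, m)$emissivity
    right <- emissivity_from_ndvi(thr + h, m)$emissivity
    expect_equal(left, right, tolerance = 1e-6)
  }
  expect_error(emissivity_model(ndvi_soil = 0.5, ndvi_veg = 0.2), "ndvi")
  expect_error(emissivity_model(eps_soil = 0.99, eps_veg = 0.95), "eps")
})

test_that("nearest-pixel resampling matches hand-resolved assignments", {
  # 4 x 4 source at 1 m; 2 x 2 destination at 2 m. Destination centers sit
  # exactly between two source centers: ties resolve to the smaller index.
  src <- raster_layer(matrix(1:16, 4, 4), gsd = 1)
  out <- resample_to_grid(src, list(nrow = 2, ncol = 2, gsd = 2, x0 = 0, y0 = 0))
  expect_equal(out$values, src$values[c(1, 3), c(1, 3)])
  # identical grids are the identity
  same <- resample_to_grid(src, src)
  expect_identical(same$values, src$values)
  # constant in, constant out on an incommensurate grid
  const <- raster_layer(matrix(7, 5, 5), gsd = 1)
  out2 <- resample_to_grid(const, list(nrow = 3, ncol = 3, gsd = 1.4,
                                       x0 = 0, y0 = 0))
  expect_true(all(out2$values == 7))
  far <- list(nrow = 2, ncol = 2, gsd = 1, x0 = 100, y0 = 100)
  expect_error(resample_to_grid(src, far), "disjoint")
})

test_that("LST retrieval inverts the forward model pixelwise", {
  band <- band_response()
  atm <- atmospheric_state(0.92, 1.4, 0.9)
  set.seed(42)
  ts <- matrix(runif(100, 290, 320), 10, 10)
  eps <- matrix(runif(100, 0.95, 0.985), 10, 10)
  img <- raster_layer(matrix(thermal_at_sensor(as.vector(ts), as.vector(eps),
                                               atm, band), 10, 10), gsd = 1.4)
  res <- retrieve_lst(img, atm, eps, band)
  expect_lt(max(abs(res$temperature$values - ts)), 1e-4)
  expect_equal(res$n_missing, 0)
  # unit emissivity and identity atmosphere reduce to plain Planck inversion
  img2 <- raster_layer(matrix(planck_band_radiance(as.vector(ts), band),
                              10, 10), gsd = 1.4)
  res2 <- retrieve_lst(img2, atmospheric_state(1, 0, 0),
                       matrix(1, 10, 10), band)
  expect_equal(res2$temperature$values, ts, tolerance = 1e-5)
  expect_error(retrieve_lst(img, atm, matrix(0, 10, 10), band), "positive")
})

test_that("retrieval flags non-invertible pixels as missing with a count", {
  band <- band_response()
  atm <- atmospheric_state(1, 0, 0)
  vals <- matrix(planck_band_radiance(c(300, 300, 300, 300), band), 2, 2)
  vals[1, 1] <- planck_band_radiance(260, band) * 0.5  # below attainable range
  res <- retrieve_lst(raster_layer(vals, 1.4), atm, matrix(1, 2, 2), band)
  expect_equal(res$n_missing, 1)
  expect_true(is.na(res$temperature$values[1, 1]))
  expect_equal(res$temperature$values[2, 2], 300, tolerance = 1e-5)
})
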