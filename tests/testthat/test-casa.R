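test_that("FPAR clamps at the stretch limits and blends the two stretches", {
  expect_equal(fpar(0.1, 0.1, 0.8), 0.001)
  expect_equal(fpar(-0.5, 0.1, 0.8), 0.001)
  expect_equal(fpar(0.8, 0.1, 0.8), 0.95)
  expect_equal(fpar(0.9, 0.1, 0.8), 0.95)
  # hand evaluation of the alpha = 0.5 blend at NDVI = 0.5
  lo <- 0.001; hi <- 0.95
  f_ndvi <- (0.5 - 0.1) * (hi - lo) / (0.8 - 0.1) + lo
  sr <- 1.5 / 0.5; sr_min <- 1.1 / 0.9; sr_max <- 1.8 / 0.2
  f_sr <- (sr - sr_min) * (hi - lo) / (sr_max - sr_min) + lo
  expect_equal(fpar(0.5, 0.1, 0.8), 0.5 * f_ndvi + 0.5 * f_sr)
  # monotone non-decreasing in NDVI
  v <- fpar(seq(-1, 0.99, by = 0.01), 0.1, 0.8)
  expect_true(all(diff(v) >= -1e-12))
  expect_error(fpar(0.5, 0.5, 0.5), "degenerate")
})

test_that("APAR is half the radiation times FPAR", {
  expect_equal(apar(0, 0.5), 0)
  expect_equal(apar(400, 0.5), 100)
  expect_true(all(apar(c(100, 200), c(0.95, 0.95)) <=
                    0.475 * c(100, 200) + 1e-12))
  expect_error(apar(-5, 0.5), "negative")
})

test_that("temperature stress matches its closed forms and limits", {
  ts <- temperature_stress(20, 20)
  expect_equal(ts$te1, 1.0)                       # 0.8 + 0.4 - 0.2
  expect_equal(temperature_stress(0, 0)$te1, 0.8)
  # Te2 vanishes at extreme cold and is near-maximal at the optimum
  expect_lt(temperature_stress(-80, 20)$te2, 1e-4)
  grid <- seq(-30, 60, by = 0.05)
  te2 <- temperature_stress(grid, 20)$te2
  expect_lt(abs(grid[which.max(te2)] - 20), 3)
  expect_gt(temperature_stress(20, 20)$te2, 0.98 * max(te2))
  expect_true(all(te2 <= 1.1814))
  expect_error(temperature_stress(10, Inf), "finite")
})

test_that("water stress interpolates between the dry floor and saturation", {
  expect_equal(water_stress_from_ratio(0), 0.5)
  expect_equal(water_stress_from_ratio(1), 1)
  expect_equal(water_stress_from_ratio(0.6), 0.8)
  # zero precipitation gives the dry floor through the full submodel
  we <- water_stress(matrix(0, 2, 2), matrix(15, 2, 2),
                     matrix(40, 2, 2))
  expect_equal(we[, ], matrix(0.5, 2, 2))
  # wetter months never decrease the stress scalar
  hi <- matrix(40, 1, 1)
  w <- vapply(c(5, 20, 80, 200),
              function(p) water_stress(matrix(p, 1, 1),
                                       matrix(18, 1, 1), hi)[1, 1], 0)
  expect_true(all(diff(w) >= -1e-12))
})

test_that("NPP composes multiplicatively with the documented hand value", {
  expect_equal(npp_from_components(100, 1.0, 0.9, 0.8, 0.389), 28.008,
               tolerance = 1e-9)
  expect_equal(npp_from_components(100, 0, 0.9, 0.8, 0.389), 0)
  # zero radiation forces zero NPP through the full monthly path
  out <- npp_monthly(ndvi = matrix(0.5, 2, 2), sol = matrix(0, 2, 2),
                     temp = matrix(20, 2, 2), prec = matrix(50, 2, 2),
                     t_opt = matrix(20, 2, 2), heat_index = matrix(40, 2, 2),
                     eps_max = 0.389, ndvi_min = 0.1, ndvi_max = 0.8)
  expect_equal(out, matrix(0, 2, 2))
})

test_that("annual NPP is the sum of months and respects the analytic bound", {
  tr <- small_truth(seed = 21)
  clim <- generate_climate(tr)
  ndvi <- generate_ndvi_series(tr)
  res <- casa_annual(ndvi, clim, tr$labels)
  expect_equal(Reduce(`+`, res$monthly), res$annual$values,
               tolerance = 1e-6)
  expect_true(all(res$annual$values >= 0))
  eps <- matrix(NA_real_, nrow(tr$labels$values), ncol(tr$labels$values))
  for (ci in seq_along(tr$classes)) {
    eps[tr$labels$values == ci] <- default_epsilon_max()[[tr$classes[ci]]]
  }
  for (t in 1:12) {
    bound <- 0.5 * clim[[t]]$layers$sol * 0.95 * 1.0 * 1.1814 * eps
    expect_true(all(res$monthly[[t]] <= bound + 1e-9))
  }
})

test_that("carbon totals convert units and scale with pixel area", {
  g <- grid_raster(matrix(500, 1, 1), res = 16)
  expect_equal(total_carbon(g, matrix(TRUE, 1, 1), pixel_area = 256), 0.128)
  expect_equal(total_carbon(g, matrix(TRUE, 1, 1), pixel_area = 512), 0.256)
  expect_warning(tot <- total_carbon(g, matrix(FALSE, 1, 1)), "empty mask")
  expect_equal(tot, 0)
})

test_that("point validation recovers identity, offsets and anticorrelation", {
  m <- matrix(runif(400, 100, 600), 20, 20)
  est <- grid_raster(m, res = 16)
  v0 <- validate_npp(est, est, n_points = 30, seed = 2)
  expect_equal(v0$rmse, 0)
  expect_equal(v0$r, 1)
  voff <- validate_npp(est, grid_raster(m + 10, res = 16), 30, seed = 2)
  expect_equal(voff$rmse, 10)
  expect_equal(voff$r, 1)
  vneg <- validate_npp(est, grid_raster(-m, res = 16), 30, seed = 2)
  expect_equal(vneg$r, -1)
  expect_error(validate_npp(est, grid_raster(matrix(1, 20, 20), res = 16),
                            30, seed = 1), "zero variance")
})

test_that("inverse-distance interpolation honours station values", {
  tmpl <- grid_raster(matrix(0, 4, 4), res = 10, xmin = 0, ymax = 40)
  st <- data.frame(x = c(5, 35), y = c(35, 5), value = c(0, 100))
  out <- idw_interpolate(st, tmpl)
  expect_equal(out$values[1, 1], 0)       # coincident station is exact
  expect_equal(out$values[4, 4], 100)
  mid <- out$values[2, 2]
  expect_gt(mid, 0); expect_lt(mid, 100)
})
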