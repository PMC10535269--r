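test_that("zero-variance configuration yields exactly the configured means", {
  tr <- small_truth(seed = 3, sd_scale = 0)
  sc <- generate_scene(tr, tr$dates[3])
  lab <- sc$labels$values
  for (ci in seq_along(tr$classes)) {
    mu <- tr$spectra[[tr$classes[ci]]]$mean[3, ]
    for (b in seq_along(mu)) {
      vals <- sc$scene$layers[[b]][lab == ci]
      expect_equal(unname(vals), rep(unname(mu[b]), length(vals)))
    }
  }
})

test_that("empirical per-class band means match configuration (law of large numbers)", {
  tr <- synth_truth(seed = 11)          # 120x120: ~2900 px per class
  sc <- generate_scene(tr, tr$dates[1])
  lab <- sc$labels$values
  for (ci in seq_along(tr$classes)) {
    sp <- tr$spectra[[tr$classes[ci]]]
    n <- sum(lab == ci)
    for (b in 1:8) {
      emp <- mean(sc$scene$layers[[b]][lab == ci])
      sd_eff <- sqrt(sp$sd[1, b]^2 + (sp$gain_sd * sp$mean[1, b])^2)
      expect_lt(abs(emp - sp$mean[1, b]), 4 * sd_eff / sqrt(n) + 1e-12)
    }
  }
})

test_that("scene generation is deterministic and rejects unknown dates", {
  tr <- small_truth(seed = 5)
  a <- generate_scene(tr, tr$dates[2])
  b <- generate_scene(tr, tr$dates[2])
  expect_identical(a$scene$layers, b$scene$layers)
  expect_error(generate_scene(tr, "2021-01-01"), "unknown acquisition date")
})

test_that("configured and empirical J-M agree at pixel-level sample sizes", {
  tr <- synth_truth(seed = 9)
  sc <- generate_scene(tr, tr$dates[3])
  lab <- as.vector(sc$labels$values)
  b6 <- as.vector(sc$scene$layers$B6)
  keep <- lab %in% c(4, 5)              # the two tree classes
  sm <- class_summaries(matrix(b6[keep], ncol = 1,
                               dimnames = list(NULL, "B6")),
                        lab[keep])
  emp <- jm_distance(sm[["4"]], sm[["5"]], mode = "univariate-mean")
  conf <- configured_jm(tr, tr$dates[3], "other_forests", "e_ulmoides",
                        bands = "B6")
  expect_lt(abs(emp - conf), 0.05)
})

test_that("sample points respect spacing, counts and the 3:1 split", {
  tr <- synth_truth(seed = 2)
  samp <- sample_points(tr$labels, survey_counts(), min_distance = 20,
                        seed = 4)
  expect_equal(nrow(samp), 208)
  expect_equal(as.vector(table(samp$class)[names(survey_counts())]),
               unname(survey_counts()))
  d <- as.matrix(dist(samp[, c("x", "y")]))
  expect_gte(min(d[upper.tri(d)]), 20)
  # per-class split: train = floor(3n/4), e.g. 39 -> 29 train / 10 test
  ulm <- samp[samp$class == "e_ulmoides", ]
  expect_equal(sum(ulm$partition == "train"), 29)
  expect_equal(sum(ulm$partition == "test"), 10)
  for (cl in levels(samp$class)) {
    n <- sum(samp$class == cl)
    expect_equal(sum(samp$class == cl & samp$partition == "train"),
                 floor(3 * n / 4))
  }
})

test_that("single eligible pixel with zero spacing returns its centre", {
  lab <- matrix(1L, 3, 3); lab[2, 2] <- 2L
  g <- grid_raster(lab, res = 10, xmin = 0, ymax = 30)
  attr(g, "classes") <- c("a", "b")
  samp <- sample_points(g, c(b = 1), min_distance = 0, seed = 1)
  expect_equal(samp$x, 15)
  expect_equal(samp$y, 15)
})

test_that("infeasible spacing fails naming the class", {
  lab <- matrix(1L, 4, 4)
  g <- grid_raster(lab, res = 16, xmin = 0, ymax = 64)
  attr(g, "classes") <- "onlyclass"
  expect_error(sample_points(g, c(onlyclass = 16), min_distance = 500),
               "onlyclass")
})

test_that("climate grids follow the configured sinusoid", {
  tr <- synth_truth(seed = 6)
  # noiseless check: exact seasonal value everywhere
  tr0 <- tr
  for (v in names(tr0$climate)) tr0$climate[[v]]$noise_sd <- 0
  clim0 <- generate_climate(tr0, months = 7)
  p <- tr0$climate$sol
  expected <- p$mean + p$amplitude * cos(2 * pi * (7 - p$peak_month) / 12)
  expect_equal(unique(as.vector(clim0$month_07$layers$sol)), expected)
  # noisy check: July temperature grid mean within 0.05 of the configured mean
  clim <- generate_climate(tr)
  pt <- tr$climate$temp
  july <- pt$mean + pt$amplitude * cos(2 * pi * (7 - pt$peak_month) / 12)
  expect_lt(abs(mean(clim$month_07$layers$temp) - july), 0.05)
  # physical floors
  for (m in clim) {
    expect_gte(min(m$layers$sol), 0)
    expect_gte(min(m$layers$prec), 0)
  }
  # determinism
  expect_identical(generate_climate(tr)[[1]]$layers,
                   generate_climate(tr)[[1]]$layers)
  # misconfiguration: seasonal minimum below zero
  bad <- tr
  bad$climate$sol$amplitude <- bad$climate$sol$mean + 10
  expect_error(generate_climate(bad), "amplitude")
})

test_that("occurrences concentrate on the configured driver", {
  tr <- synth_truth(seed = 8)
  inp <- generate_sdm_inputs(tr, n_occurrences = 150, n_background = 1500,
                             seed = 21)
  z <- inp$bioclim_std$layers$BIO17
  g <- inp$suitability
  at <- function(pts) z[as.matrix(grid_cell_at(g, pts$x, pts$y))]
  expect_gt(mean(at(inp$presence)), mean(at(inp$background)) + 0.5)
  # determinism
  inp2 <- generate_sdm_inputs(tr, n_occurrences = 150, n_background = 1500,
                              seed = 21)
  expect_identical(inp$presence, inp2$presence)
  expect_error(generate_sdm_inputs(tr, n_occurrences = 5), "at least 10")
})

test_that("null suitability weights give uniform occurrences", {
  tr <- synth_truth(seed = 12, suit_intercept = 0,
                    suit_weights = c(BIO17 = 0))
  inp <- generate_sdm_inputs(tr, n_occurrences = 400, n_background = 4000,
                             seed = 3)
  g <- inp$suitability
  expect_equal(unique(as.vector(g$values)), 0.5)
  for (v in c("BIO17", "BIO4")) {
    z <- inp$bioclim_std$layers[[v]]
    mp <- mean(z[as.matrix(grid_cell_at(g, inp$presence$x, inp$presence$y))])
    mb <- mean(z[as.matrix(grid_cell_at(g, inp$background$x,
                                        inp$background$y))])
    se <- sqrt(1 / 400 + 1 / 4000)
    expect_lt(abs(mp - mb), 4 * se)
  }
})

test_that("held-out AUC of the true generating surface exceeds 0.9", {
  tr <- synth_truth(seed = 14)
  inp <- generate_sdm_inputs(tr, n_occurrences = 120, n_background = 2000,
                             seed = 5)
  sv <- inp$suitability$values
  ps <- sv[as.matrix(grid_cell_at(inp$suitability, inp$presence$x,
                                  inp$presence$y))]
  bs <- sv[as.matrix(grid_cell_at(inp$suitability, inp$background$x,
                                  inp$background$y))]
  expect_gt(roc_auc(ps, bs), 0.9)
})
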