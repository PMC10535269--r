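sdm_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- synth_truth(seed = 2)
      inp <- generate_sdm_inputs(tr, n_occurrences = 120,
                                 n_background = 2000, seed = 42)
      pres <- grid_extract(inp$bioclim, inp$presence$x, inp$presence$y)
      bg <- grid_extract(inp$bioclim, inp$background$x, inp$background$y)
      cache <<- list(truth = tr, inputs = inp, pres = pres, bg = bg)
    }
    cache
  }
})

test_that("constant covariates give the uniform null model", {
  pres <- matrix(3, 30, 2, dimnames = list(NULL, c("BIO1", "BIO2")))
  bg <- matrix(3, 200, 2, dimnames = list(NULL, c("BIO1", "BIO2")))
  fit <- maxent_fit(pres, bg)
  expect_true(all(fit$lambda == 0))
  r <- maxent_raw(fit, bg)
  expect_equal(r, rep(1 / 200, 200))
  expect_equal(unique(round(maxent_predict_logistic(fit, bg), 10)), 0.5)
})

test_that("raw output always sums to one over the training background", {
  fx <- sdm_fixture()
  for (b in c(0.5, 1, 2)) {
    fit <- maxent_fit(fx$pres, fx$bg, maxent_config(beta = b))
    expect_equal(sum(maxent_raw(fit, fx$bg)), 1, tolerance = 1e-10)
  }
})

test_that("a linear-feature fit recovers the driver's sign and monotonicity", {
  fx <- sdm_fixture()
  cfg <- maxent_config(feature_classes = "linear")
  fit <- maxent_fit(fx$pres, fx$bg, cfg)
  lam17 <- fit$lambda[fit$feature_names == "BIO17:lin"]
  expect_gt(lam17, 0)
  # prediction is monotone in the driver when the others are held fixed
  scan <- matrix(rep(colMeans(fx$bg), each = 50), 50,
                 dimnames = list(NULL, colnames(fx$bg)))
  scan[, "BIO17"] <- seq(min(fx$bg[, "BIO17"]), max(fx$bg[, "BIO17"]),
                         length.out = 50)
  p <- maxent_predict_logistic(fit, scan)
  expect_true(all(diff(p) >= -1e-12))
})

test_that("strong regularization shrinks every weight to zero", {
  fx <- sdm_fixture()
  fit <- maxent_fit(fx$pres, fx$bg, maxent_config(beta = 1e6))
  expect_true(all(fit$lambda == 0))
})

test_that("the L1 path never gains active features as beta grows", {
  fx <- sdm_fixture()
  nnz <- vapply(c(0.5, 1, 2, 4, 8, 16), function(b) {
    sum(maxent_fit(fx$pres, fx$bg, maxent_config(beta = b))$lambda != 0)
  }, 0)
  expect_true(all(diff(nnz) <= 0))
})

test_that("rank AUC handles separation, reversal, ties and the null", {
  expect_equal(roc_auc(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_equal(roc_auc(c(1, 2, 3), c(5, 6, 7)), 0)
  expect_warning(a <- roc_auc(rep(1, 5), rep(1, 9)), "identical")
  expect_equal(a, 0.5)
  set.seed(8)
  np <- 200; nb <- 2000
  a0 <- roc_auc(rnorm(np), rnorm(nb))
  se <- sqrt((np + nb + 1) / (12 * np * nb))
  expect_lt(abs(a0 - 0.5), 3 * se)
  expect_error(roc_auc(numeric(0), 1:3), "at least one")
})

test_that("AUC is invariant to strictly monotone score transforms", {
  set.seed(9)
  p <- runif(50); b <- runif(500)
  a <- roc_auc(p, b)
  expect_equal(roc_auc(exp(3 * p), exp(3 * b)), a)
  expect_equal(roc_auc(log(p + 1), log(b + 1)), a)
})

test_that("percent contributions normalize to 100 and crown the driver", {
  fx <- sdm_fixture()
  fit <- maxent_fit(fx$pres, fx$bg)
  imp <- variable_importance(fit, fx$pres, fx$bg, "percent_contribution")
  expect_equal(sum(imp$percent_contribution), 100, tolerance = 0.1)
  expect_equal(imp$variable[which.max(imp$percent_contribution)], "BIO17")
})

test_that("permutation importance singles out the informative variable", {
  fx <- sdm_fixture()
  fit <- maxent_fit(fx$pres, fx$bg)
  imp <- variable_importance(fit, fx$pres, fx$bg, "permutation", seed = 4)
  expect_equal(imp$variable[which.max(imp$permutation_importance)], "BIO17")
  expect_equal(sum(imp$permutation_importance), 100, tolerance = 0.1)
  one <- variable_importance(
    maxent_fit(fx$pres[, "BIO17", drop = FALSE],
               fx$bg[, "BIO17", drop = FALSE]),
    fx$pres[, "BIO17", drop = FALSE], fx$bg[, "BIO17", drop = FALSE],
    "permutation")
  expect_equal(one$permutation_importance, 100)
})

test_that("jackknife gain is highest with the driver alone", {
  fx <- sdm_fixture()
  vars <- c("BIO17", "BIO1", "BIO5", "BIO12")
  fit <- maxent_fit(fx$pres[, vars], fx$bg[, vars])
  jk <- variable_importance(fit, fx$pres[, vars], fx$bg[, vars], "jackknife")
  expect_equal(jk$variable[which.max(jk$gain_with_only)], "BIO17")
  # dropping the driver loses more gain than dropping a noise layer
  loss <- fit$gain - jk$gain_without
  expect_equal(jk$variable[which.max(loss)], "BIO17")
})

test_that("bootstrap replicates are deterministic under a fixed seed", {
  fx <- sdm_fixture()
  r1 <- maxent_replicates(fx$pres, fx$bg, n_replicates = 3, seed = 6)
  r2 <- maxent_replicates(fx$pres, fx$bg, n_replicates = 3, seed = 6)
  expect_identical(r1$auc, r2$auc)
  expect_true(all(r1$auc >= 0 & r1$auc <= 1))
})

test_that("logistic prediction on a stack propagates missing cells", {
  fx <- sdm_fixture()
  fit <- maxent_fit(fx$pres, fx$bg)
  stack <- fx$inputs$bioclim
  stack$layers$BIO1[1, 1] <- NA
  p <- maxent_predict_logistic(fit, stack)
  expect_true(is.na(p$values[1, 1]))
  ok <- !is.na(p$values)
  expect_true(all(p$values[ok] > 0 & p$values[ok] < 1))
  stack$layers$BIO1 <- NULL
  expect_error(maxent_predict_logistic(fit, stack), "missing covariate")
})

test_that("suitability zoning tiles the probability range", {
  vals <- matrix(c(0.1, 0.2, 0.4, 0.6), 2, 2)
  z <- classify_suitability(grid_raster(vals, res = 1000), "fixed_breaks")
  expect_equal(as.vector(z$grades$values), c(1L, 2L, 3L, 4L))
  expect_equal(z$labels[4], "high_suitable")
  low <- classify_suitability(grid_raster(matrix(0.05, 3, 3), res = 1000),
                              "fixed_breaks")
  expect_equal(unique(as.vector(low$grades$values)), 1L)
  clusters <- matrix(rep(c(0.05, 0.3, 0.45, 0.65), each = 25), 10, 10)
  nb <- classify_suitability(grid_raster(clusters, res = 1000),
                             "natural_breaks")
  expect_equal(length(unique(as.vector(nb$grades$values))), 4)
  expect_error(classify_suitability(grid_raster(matrix(0.5, 3, 3),
                                                res = 1000),
                                    "natural_breaks"), "distinct")
})

test_that("areas are pixel counts times squared resolution", {
  g <- grid_raster(matrix(1L, 10, 10), res = 1)
  attr(g, "classes") <- "only"
  a <- area_by_class(g, resolution_km = 1)
  expect_equal(a$area_km2, 100)
  a2 <- area_by_class(g, resolution_km = 0.5)
  expect_equal(a2$area_km2, 25)
  mixed <- grid_raster(matrix(c(1L, 2L, 2L, NA), 2, 2), res = 1)
  am <- area_by_class(mixed, 1)
  expect_equal(sum(am$n_pixels), 3)
})
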