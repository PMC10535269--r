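toy_data <- function(n = 40) {
  # two well-separated classes in two features
  x <- rbind(cbind(rnorm(n, 0, 0.1), rnorm(n, 0, 0.1)),
             cbind(rnorm(n, 5, 0.1), rnorm(n, 5, 0.1)))
  colnames(x) <- c("f1", "f2")
  list(x = x, y = factor(rep(c("a", "b"), each = n)))
}

test_that("a separable toy problem is learned perfectly and deterministically", {
  set.seed(1)
  d <- toy_data()
  fit <- rf_train(d$x, d$y, classifier_config(n_trees = 100, seed = 3))
  expect_equal(as.character(predict(fit, d$x)), as.character(d$y))
  fit2 <- rf_train(d$x, d$y, classifier_config(n_trees = 100, seed = 3))
  expect_identical(predict(fit, d$x), predict(fit2, d$x))
  v <- predict(fit, d$x, votes = TRUE)
  expect_equal(dim(v$votes), c(80L, 2L))
})

test_that("the sqrt(p) rule takes the floor with a minimum of one", {
  set.seed(2)
  x <- matrix(rnorm(60 * 11), 60, 11,
              dimnames = list(NULL, paste0("f", 1:11)))
  y <- factor(rep(c("a", "b"), 30))
  fit <- rf_train(x, y, classifier_config(n_trees = 10, seed = 1))
  expect_equal(fit$forest$mtry, 3)        # floor(sqrt(11))
  fit1 <- rf_train(x[, 1, drop = FALSE], y,
                   classifier_config(n_trees = 10, seed = 1))
  expect_equal(fit1$forest$mtry, 1)
  expect_error(rf_train(x, factor(rep("a", 60)),
                        classifier_config(n_trees = 5)), "single-class")
  x[1, 1] <- NA
  expect_error(rf_train(x, y, classifier_config(n_trees = 5)), "missing")
})

test_that("overall accuracy is invariant to class relabelling", {
  set.seed(4)
  d <- toy_data(30)
  x <- rbind(d$x, cbind(rnorm(30, 2.5, 1.5), rnorm(30, 2.5, 1.5)))
  colnames(x) <- c("f1", "f2")
  y <- factor(c(as.character(d$y), rep("c", 30)))
  idx <- sample(90, 60)
  cfg <- classifier_config(n_trees = 100, seed = 9)
  oa_of <- function(lab) {
    fit <- rf_train(x[idx, ], lab[idx], cfg)
    cm <- confusion_matrix(as.character(lab[-idx]),
                           as.character(predict(fit, x[-idx, ])),
                           classes = levels(lab))
    overall_accuracy(cm)
  }
  # order-preserving renaming: labels are names, not an ordering
  relab <- factor(c(a = "x1", b = "x2", c = "x3")[as.character(y)])
  expect_equal(oa_of(y), oa_of(relab))
})

test_that("comparison harness shares one partition and applies the tie rules", {
  tr <- small_truth(seed = 7)
  sc <- generate_scene(tr, tr$dates[3])$scene
  samp <- sample_points(tr$labels, survey_counts(), 20, seed = 3)
  cmp <- evaluate_combinations(sc, samp, band_combinations("models")[1:3],
                               classifier_config(n_trees = 100, seed = 2))
  expect_equal(nrow(cmp$table), 3)
  expect_equal(cmp$partition_hash, paste(samp$partition, collapse = ""))
  ord <- order(-cmp$table$oa, -cmp$table$pa, cmp$table$model)
  expect_equal(cmp$winner, cmp$table$model[ord[1]])
  # restricting the registry to one model makes it the winner
  one <- evaluate_combinations(sc, samp, band_combinations("models")[2],
                               classifier_config(n_trees = 50, seed = 2))
  expect_equal(one$winner, "model2")
  # no test samples of the target class aborts
  samp2 <- samp
  samp2$partition[samp2$class == "e_ulmoides"] <- "train"
  expect_error(evaluate_combinations(sc, samp2, band_combinations("models")[1],
                                     classifier_config(n_trees = 10)),
               "no test samples")
})

test_that("duplicated features leave accuracy within two points on a separable scene", {
  tr <- small_truth(seed = 10, sd_scale = 0.5)
  sc <- generate_scene(tr, tr$dates[3])$scene
  samp <- sample_points(tr$labels, survey_counts(), 20, seed = 5)
  train <- samp$partition == "train"
  combo <- band_combinations("models")$model4
  ft <- build_feature_table(sc, samp, combo)
  cfg <- classifier_config(n_trees = 200, seed = 6)
  oa <- function(feats) {
    fit <- rf_train(feats[train, ], samp$class[train], cfg)
    cm <- confusion_matrix(as.character(samp$class[!train]),
                           as.character(predict(fit, feats[!train, ])),
                           classes = levels(samp$class))
    overall_accuracy(cm)
  }
  dup <- cbind(ft$features, ft$features)
  colnames(dup) <- c(colnames(ft$features),
                     paste0(colnames(ft$features), "_dup"))
  expect_lte(abs(oa(ft$features) - oa(dup)), 2)
})

test_that("raster classification recovers labels and propagates nodata", {
  tr <- small_truth(seed = 13, sd_scale = 0.5)
  sc <- generate_scene(tr, tr$dates[3])
  samp <- sample_points(tr$labels, survey_counts(), 20, seed = 8)
  combo <- band_combinations("models")$model8
  ft <- build_feature_table(sc$scene, samp, combo)
  fit <- rf_train(ft$features[samp$partition == "train", ],
                  samp$class[samp$partition == "train"],
                  classifier_config(n_trees = 200, seed = 4))
  # nodata block in one band propagates
  sc$scene$layers$B4[1:5, 1:5] <- NA
  out <- classify_raster(fit, sc$scene, combo)
  expect_true(all(is.na(out$values[1:5, 1:5])))
  ok <- !is.na(out$values)
  expect_gt(mean(out$values[ok] == sc$labels$values[ok]), 0.95)
  expect_equal(attr(out, "classes"), levels(samp$class))
  # schema mismatch is refused
  expect_error(classify_raster(fit, sc$scene,
                               band_combinations("models")$model1),
               "feature-order")
})

test_that("a constant raster matching a training point maps to its class", {
  set.seed(5)
  d <- toy_data()
  colnames(d$x) <- c("B1", "B2")
  fit <- rf_train(d$x, d$y, classifier_config(n_trees = 50, seed = 2))
  layers <- list(B1 = matrix(d$x[1, 1], 4, 4), B2 = matrix(d$x[1, 2], 4, 4))
  sc <- grid_stack(layers, res = 1, xmin = 0, ymax = 4)
  combo <- list(id = "toy", bands = c("B1", "B2"), indices = character(0))
  out <- classify_raster(fit, sc, combo)
  expect_true(all(out$values == match("a", fit$classes)))
})
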