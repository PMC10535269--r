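#' Random-forest classifier configuration
#'
#' @param n_trees number of trees (default 500, where out-of-bag error has
#'   stabilized for scenes like these).
#' @param max_features `"sqrt"` for `floor(sqrt(p))` features per split
#'   (minimum 1), or an explicit integer.
#' @param seed integer seed making training deterministic.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(n_trees = 500, max_features = "sqrt",
                              seed = 1) {
  stopifnot(n_trees >= 1)
  structure(list(n_trees = n_trees, max_features = max_features,
                 seed = seed), class = "classifier_config")
}

mtry_for <- function(config, p) {
  if (identical(config$max_features, "sqrt")) {
    max(1L, floor(sqrt(p)))
  } else {
    m <- as.integer(config$max_features)
    if (m < 1 || m > p) stop("max_features outside [1, p]")
    m
  }
}

#' Train a random forest on a feature table
#'
#' Thin deterministic wrapper around [randomForest::randomForest()]; the
#' bespoke logic of this module is the comparison harness and the raster
#' application, not the learner.
#'
#' @param features numeric matrix (no missing values).
#' @param labels factor of class labels (>= 2 classes).
#' @param config a [classifier_config()].
#' @return a `fitted_classifier` with the forest, feature schema and config.
#' @export
rf_train <- function(features, labels, config = classifier_config()) {
  features <- as.matrix(features)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("training error: single-class input")
  if (anyNA(features)) stop("training error: missing feature values")
  fit <- with_seed(config$seed, {
    randomForest::randomForest(
      x = features, y = labels, ntree = config$n_trees,
      mtry = mtry_for(config, ncol(features)))
  })
  structure(list(forest = fit, schema = colnames(features),
                 classes = levels(labels), config = config),
            class = "fitted_classifier")
}

#' Predict classes (and vote proportions) for a feature matrix
#'
#' @param object a `fitted_classifier`.
#' @param features matrix whose columns match the training schema.
#' @param votes if TRUE, also return per-class vote proportions.
#' @param ... unused.
#' @return factor of predictions, or list(pred, votes).
#' @export
predict.fitted_classifier <- function(object, features, votes = FALSE, ...) {
  features <- as.matrix(features)
  if (!identical(colnames(features), object$schema)) {
    stop("feature-order error: columns must match the training schema (",
         paste(object$schema, collapse = ","), ")")
  }
  pred <- stats::predict(object$forest, features)
  if (!votes) return(pred)
  list(pred = pred, votes = stats::predict(object$forest, features,
                                           type = "prob"))
}

#' Compare band-combination models on a fixed train/test split
#'
#' Builds the feature table of every registry model from the same scene and
#' the same sample partition, trains one forest per model on the shared
#' training set, and scores OA, Kappa, and target-class PA/UA on the shared
#' test set. The winner is the highest OA; ties break by target-class PA,
#' then by lowest model id.
#'
#' @param scene `grid_stack` for the chosen date.
#' @param samples data.frame from [sample_points()] (its `partition` column
#'   is used as-is for every model).
#' @param registry list of combinations, e.g. `band_combinations("models")`.
#' @param config a [classifier_config()].
#' @param target_class class whose PA/UA is reported.
#' @return list: `table` (one row per model), `winner` (model id),
#'   `fits` (fitted classifiers), `partition_hash`.
#' @export
evaluate_combinations <- function(scene, samples, registry,
                                  config = classifier_config(),
                                  target_class = "e_ulmoides") {
  train <- samples$partition == "train"
  if (sum(samples$partition == "test" & samples$class == target_class) == 0) {
    stop("comparison aborted: no test samples of the target class")
  }
  part_hash <- paste(samples$partition, collapse = "")
  rows <- list(); fits <- list()
  for (cb in registry) {
    ft <- build_feature_table(scene, samples, cb)
    fit <- rf_train(ft$features[train, , drop = FALSE],
                    samples$class[train], config)
    pred <- predict(fit, ft$features[!train, , drop = FALSE])
    cm <- confusion_matrix(as.character(samples$class[!train]),
                           as.character(pred),
                           classes = levels(samples$class))
    rows[[cb$id]] <- data.frame(
      model = cb$id,
      n_features = ncol(ft$features),
      oa = overall_accuracy(cm),
      kappa = kappa_coefficient(cm),
      pa = producer_accuracy(cm, target_class),
      ua = user_accuracy(cm, target_class))
    fits[[cb$id]] <- fit
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ord <- order(-tab$oa, -tab$pa, tab$model)
  list(table = tab, winner = tab$model[ord[1]], fits = fits,
       partition_hash = part_hash, target_class = target_class)
}

#' Classify every pixel of a scene with a fitted model
#'
#' Builds the model's feature vector at every pixel (bands plus indices) and
#' predicts a class label; any pixel with a missing input becomes NA.
#'
#' @param fit a `fitted_classifier`.
#' @param scene `grid_stack` with bands B1..B8.
#' @param combo the registry entry the model was trained on.
#' @return `grid_raster` of integer class codes, `classes` attribute giving
#'   the code-to-name legend.
#' @export
classify_raster <- function(fit, scene, combo) {
  cols <- c(combo$bands, combo$indices)
  if (!identical(cols, fit$schema)) {
    stop("feature-order error: combo does not match the training schema")
  }
  d <- grid_dim(scene)
  n <- prod(d)
  feats <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  for (b in combo$bands) feats[, b] <- as.vector(scene$layers[[b]])
  for (ix in combo$indices) {
    def <- INDEX_DEFS[[ix]]
    num <- as.vector(scene$layers[[def[["num"]]]])
    den0 <- as.vector(scene$layers[[def[["den"]]]])
    s <- num + den0
    v <- (num - den0) / s
    v[!is.na(s) & s == 0] <- NA_real_
    feats[, ix] <- v
  }
  ok <- stats::complete.cases(feats)
  out <- rep(NA_integer_, n)
  if (any(ok)) {
    pred <- predict(fit, feats[ok, , drop = FALSE])
    out[ok] <- as.integer(factor(as.character(pred), levels = fit$classes))
  }
  g <- grid_raster(matrix(out, d[1], d[2]), res = scene$res,
                   xmin = scene$xmin, ymax = scene$ymax)
  attr(g, "classes") <- fit$classes
  g
}
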