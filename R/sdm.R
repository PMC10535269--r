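#' Maximum-entropy species distribution model
#'
#' A presence-background Gibbs model: the raw output is
#' `exp(lambda . f(x)) / Z` normalized over the background, fitted by
#' maximizing the L1-regularized mean presence log-likelihood with cyclic
#' coordinate-wise penalized Newton updates. Feature classes are linear,
#' quadratic and hinge expansions of the covariates, each scaled to
#' \[0, 1\]. Logistic output follows the conventional entropy-linked
#' transform.
#'
#' @name sdm
NULL

#' MaxEnt run configuration
#'
#' @param feature_classes subset of `c("linear", "quadratic", "hinge")`.
#' @param n_hinge_knots interior knots per variable (each yields a forward
#'   and a reverse hinge feature).
#' @param beta regularization multiplier (larger = sparser model).
#' @param max_iter coordinate-descent cycle cap (default 1000).
#' @param tol convergence tolerance on the penalized-gain improvement per
#'   cycle (default 1e-5).
#' @return a `maxent_config` list.
#' @export
maxent_config <- function(feature_classes = c("linear", "quadratic", "hinge"),
                          n_hinge_knots = 3, beta = 1, max_iter = 1000,
                          tol = 1e-5) {
  stopifnot(all(feature_classes %in% c("linear", "quadratic", "hinge")),
            beta >= 0, max_iter >= 1)
  structure(list(feature_classes = feature_classes,
                 n_hinge_knots = n_hinge_knots, beta = beta,
                 max_iter = max_iter, tol = tol), class = "maxent_config")
}

# Build the feature expansion for a raw covariate matrix (columns = vars),
# given per-variable scaling ranges. Returns matrix in [0,1] with an
# owner-variable index attribute.
expand_features <- function(X, ranges, config) {
  vars <- colnames(X)
  feats <- list(); owner <- character(0)
  for (v in vars) {
    lo <- ranges[v, 1]; hi <- ranges[v, 2]
    z <- if (hi > lo) pmin(1, pmax(0, (X[, v] - lo) / (hi - lo))) else
      rep(0.5, nrow(X))
    if ("linear" %in% config$feature_classes) {
      feats[[paste0(v, ":lin")]] <- z; owner <- c(owner, v)
    }
    if ("quadratic" %in% config$feature_classes) {
      feats[[paste0(v, ":quad")]] <- z^2; owner <- c(owner, v)
    }
    if ("hinge" %in% config$feature_classes && config$n_hinge_knots > 0) {
      knots <- seq_len(config$n_hinge_knots) / (config$n_hinge_knots + 1)
      for (t in knots) {
        feats[[sprintf("%s:hf%.2f", v, t)]] <- pmax(0, (z - t) / (1 - t))
        feats[[sprintf("%s:hr%.2f", v, t)]] <- pmax(0, (t - z) / t)
        owner <- c(owner, v, v)
      }
    }
  }
  F <- do.call(cbind, feats)
  attr(F, "owner") <- owner
  F
}

#' Fit a maximum-entropy model to presence and background covariates
#'
#' @param pres matrix/data.frame of presence-point covariates (columns
#'   named, e.g. BIO1..BIO19).
#' @param bg matrix/data.frame of background covariates, same columns.
#' @param config a [maxent_config()].
#' @return a `maxent_model`: feature weights `lambda`, scaling ranges,
#'   background normalizer, entropy, training gain, per-variable gain
#'   contributions, and the config.
#' @export
maxent_fit <- function(pres, bg, config = maxent_config()) {
  pres <- as.matrix(pres); bg <- as.matrix(bg)
  stopifnot(identical(colnames(pres), colnames(bg)))
  if (anyNA(pres) || anyNA(bg) || any(!is.finite(pres)) || any(!is.finite(bg))) {
    stop("non-finite covariate values in presence or background data")
  }
  vars <- colnames(pres)
  all_x <- rbind(pres, bg)
  ranges <- cbind(apply(all_x, 2, min), apply(all_x, 2, max))
  rownames(ranges) <- vars
  Fp <- expand_features(pres, ranges, config)
  Fb <- expand_features(bg, ranges, config)
  owner <- attr(Fb, "owner")
  q <- ncol(Fb); m <- nrow(Fp); n <- nrow(Fb)
  fbar <- colMeans(Fp)
  sdp <- apply(Fp, 2, stats::sd)
  pen <- config$beta * pmax(sdp, 0.05) / sqrt(m)

  lambda <- numeric(q)
  eta <- numeric(n)
  mp <- 0                       # mean presence eta, tracked incrementally
  # gain relative to the uniform background distribution
  lme <- function(v) { mx <- max(v); mx + log(mean(exp(v - mx))) }
  gain <- mp - lme(eta)
  pgain <- gain
  contrib <- stats::setNames(numeric(length(vars)), vars)
  iters <- 0L
  for (cycle in seq_len(config$max_iter)) {
    iters <- cycle
    pgain0 <- pgain
    max_step <- 0
    for (j in seq_len(q)) {
      mx <- max(eta)
      e <- exp(eta - mx)
      w <- e / sum(e)
      fj <- Fb[, j]
      ew <- sum(w * fj)
      vw <- sum(w * fj * fj) - ew^2
      g <- fbar[j] - ew
      h <- vw + 1e-6
      z <- lambda[j] + g / h
      lam_new <- sign(z) * max(0, abs(z) - pen[j] / h)
      delta <- lam_new - lambda[j]
      if (delta == 0) next
      delta <- max(-1, min(1, delta))   # step clamp against overshoot
      lambda[j] <- lambda[j] + delta
      eta <- eta + delta * fj
      mp <- mp + delta * fbar[j]
      max_step <- max(max_step, abs(delta))
      gain_new <- mp - lme(eta)
      contrib[owner[j]] <- contrib[owner[j]] + (gain_new - gain)
      gain <- gain_new
    }
    pgain <- gain - sum(pen * abs(lambda))
    if (abs(pgain - pgain0) < config$tol || max_step < 1e-7) break
  }
  mx <- max(eta)
  logZ <- mx + log(sum(exp(eta - mx)))      # sum over background
  r <- exp(eta - logZ)                      # sums to 1 over background
  H <- -sum(r * log(pmax(r, 1e-300)))
  structure(list(lambda = lambda, feature_names = colnames(Fb),
                 owner = owner, ranges = ranges, vars = vars,
                 logZ = logZ, entropy = H, gain = gain,
                 penalized_gain = pgain, contrib = contrib,
                 iterations = iters, config = config,
                 n_presence = m, n_background = n),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> %d vars, %d features (%d non-zero), gain %.4f, %d cycles\n",
    length(x$vars), length(x$lambda), sum(x$lambda != 0), x$gain,
    x$iterations))
  invisible(x)
}

# Linear predictor eta for raw covariate rows.
maxent_eta <- function(model, X) {
  F <- expand_features(as.matrix(X)[, model$vars, drop = FALSE],
                       model$ranges, model$config)
  as.vector(F %*% model$lambda)
}

#' Raw (relative occurrence rate) scores for covariate rows
#'
#' Normalized so the training background sums to 1.
#' @param model a `maxent_model`.
#' @param X covariate matrix with the training columns.
#' @return numeric vector of raw scores.
#' @export
maxent_raw <- function(model, X) {
  exp(maxent_eta(model, X) - model$logZ)
}

#' Logistic-scale suitability predictions
#'
#' `p = c r / (1 + c r)` with `r` the raw score and `c = exp(H)` the
#' entropy-linked constant, giving values in (0, 1) with a typical presence
#' near 0.5 under a featureless model.
#'
#' @param model a `maxent_model`.
#' @param newdata covariate matrix, or a `grid_stack` of covariate layers.
#' @return numeric vector, or a `grid_raster` when given a stack; NA cells
#'   propagate.
#' @export
maxent_predict_logistic <- function(model, newdata) {
  if (inherits(newdata, "grid_stack")) {
    miss <- setdiff(model$vars, names(newdata$layers))
    if (length(miss) > 0) {
      stop("missing covariate layers: ", paste(miss, collapse = ", "))
    }
    d <- grid_dim(newdata)
    X <- sapply(model$vars, function(v) as.vector(newdata$layers[[v]]))
    ok <- stats::complete.cases(X)
    p <- rep(NA_real_, nrow(X))
    if (any(ok)) {
      r <- maxent_raw(model, X[ok, , drop = FALSE])
      cr <- exp(model$entropy) * r
      p[ok] <- cr / (1 + cr)
    }
    return(grid_raster(matrix(p, d[1], d[2]), res = newdata$res,
                       xmin = newdata$xmin, ymax = newdata$ymax))
  }
  r <- maxent_raw(model, newdata)
  cr <- exp(model$entropy) * r
  cr / (1 + cr)
}

#' Rank-based ROC AUC of presence scores against background scores
#'
#' Ties receive half credit (midrank convention). Identical scores
#' everywhere give 0.5 with a warning.
#'
#' @param pres_scores,bg_scores numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(pres_scores, bg_scores) {
  np <- length(pres_scores); nb <- length(bg_scores)
  if (np < 1) stop("need at least one test presence")
  if (length(unique(c(pres_scores, bg_scores))) == 1) {
    warning("all scores identical: AUC = 0.5")
    return(0.5)
  }
  r <- rank(c(pres_scores, bg_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Fit replicate MaxEnt models with 75/25 presence resampling
#'
#' Each replicate holds out a random 25% of presences as the test set, fits
#' on the remaining 75%, and reports the held-out AUC against the
#' background.
#'
#' @param pres,bg covariate matrices as in [maxent_fit()].
#' @param config a [maxent_config()].
#' @param n_replicates number of replicates (default 10).
#' @param seed integer seed.
#' @return list: `models`, `auc` (per replicate), `mean_auc`,
#'   `train_fraction`.
#' @export
maxent_replicates <- function(pres, bg, config = maxent_config(),
                              n_replicates = 10, seed = 1) {
  pres <- as.matrix(pres); bg <- as.matrix(bg)
  m <- nrow(pres)
  with_seed(seed, {
    models <- list(); auc <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      n_train <- floor(0.75 * m)
      tr <- sample.int(m, n_train)
      fit <- maxent_fit(pres[tr, , drop = FALSE], bg, config)
      te <- setdiff(seq_len(m), tr)
      auc[r] <- roc_auc(maxent_raw(fit, pres[te, , drop = FALSE]),
                        maxent_raw(fit, bg))
      models[[r]] <- fit
    }
    list(models = models, auc = auc, mean_auc = mean(auc),
         train_fraction = 0.75)
  })
}

#' Variable-importance diagnostics for a fitted MaxEnt model
#'
#' `percent_contribution` attributes the training-gain increments
#' accumulated during optimization to the variable owning each updated
#' feature (negatives floored at zero) and normalizes to 100.
#' `permutation` shuffles one variable at a time across the combined
#' presence/background rows, measures the drop in training AUC, floors at
#' zero and normalizes to 100. `jackknife` refits with only / without each
#' variable and reports the training gains.
#'
#' @param model a `maxent_model`.
#' @param pres,bg the training covariate matrices.
#' @param mode one of `"percent_contribution"`, `"permutation"`,
#'   `"jackknife"`.
#' @param seed seed for the permutation shuffles.
#' @return data.frame, one row per variable.
#' @export
variable_importance <- function(model, pres, bg,
                                mode = c("percent_contribution",
                                         "permutation", "jackknife"),
                                seed = 1) {
  mode <- match.arg(mode)
  pres <- as.matrix(pres); bg <- as.matrix(bg)
  vars <- model$vars
  if (mode == "percent_contribution") {
    pos <- pmax(model$contrib, 0)
    tot <- sum(pos)
    pct <- if (tot > 0) 100 * pos / tot else rep(0, length(pos))
    return(data.frame(variable = vars, percent_contribution = as.numeric(pct),
                      row.names = NULL))
  }
  if (mode == "permutation") {
    if (length(vars) == 1) {
      return(data.frame(variable = vars, permutation_importance = 100))
    }
    base_auc <- roc_auc(maxent_raw(model, pres), maxent_raw(model, bg))
    drops <- with_seed(seed, vapply(vars, function(v) {
      pp <- pres; bb <- bg
      comb <- c(pp[, v], bb[, v])
      comb <- comb[sample.int(length(comb))]
      pp[, v] <- comb[seq_len(nrow(pp))]
      bb[, v] <- comb[-seq_len(nrow(pp))]
      max(0, base_auc - roc_auc(maxent_raw(model, pp), maxent_raw(model, bb)))
    }, 0))
    tot <- sum(drops)
    pct <- if (tot > 0) 100 * drops / tot else rep(0, length(drops))
    return(data.frame(variable = vars, permutation_importance = as.numeric(pct),
                      row.names = NULL))
  }
  # jackknife
  rows <- lapply(vars, function(v) {
    only <- maxent_fit(pres[, v, drop = FALSE], bg[, v, drop = FALSE],
                       model$config)
    without <- if (length(vars) > 1) {
      maxent_fit(pres[, setdiff(vars, v), drop = FALSE],
                 bg[, setdiff(vars, v), drop = FALSE], model$config)
    } else NULL
    data.frame(variable = v, gain_with_only = only$gain,
               gain_without = if (is.null(without)) NA_real_ else without$gain)
  })
  out <- do.call(rbind, rows)
  out$gain_full <- model$gain
  out
}

#' Grade a suitability raster into four classes
#'
#' `natural_breaks` reuses the Fisher-Jenks engine; `fixed_breaks` applies
#' supplied thresholds as half-open intervals (lower bound included).
#'
#' @param prob `grid_raster` of logistic suitability in (0, 1).
#' @param method `"natural_breaks"` or `"fixed_breaks"`.
#' @param breaks thresholds for `fixed_breaks`
#'   (default `c(0.16, 0.35, 0.5)`: non / low / medium / high suitability).
#' @param n_classes grade count for `natural_breaks`.
#' @return list: `grades` (`grid_raster` 1..k), `breaks`, `labels`.
#' @export
classify_suitability <- function(prob, method = c("natural_breaks",
                                                  "fixed_breaks"),
                                 breaks = c(0.16, 0.35, 0.5),
                                 n_classes = 4) {
  method <- match.arg(method)
  if (method == "natural_breaks") {
    jb <- jenks_breaks(as.vector(prob$values), n_classes)
    breaks <- jb$breaks
  }
  g <- classify_breaks(prob$values, breaks)
  labels <- c("non_suitable", "low_suitable", "medium_suitable",
              "high_suitable")[seq_len(length(breaks) + 1)]
  gr <- grid_raster(g, res = prob$res, xmin = prob$xmin, ymax = prob$ymax)
  attr(gr, "classes") <- labels
  list(grades = gr, breaks = breaks, labels = labels, method = method)
}

#' Per-class area of a grade raster
#'
#' `area(g) = pixel count(g) * resolution^2`.
#'
#' @param grades `grid_raster` of integer grades (NA = outside study area).
#' @param resolution_km pixel size in km.
#' @return data.frame `grade, label, n_pixels, area_km2`.
#' @export
area_by_class <- function(grades, resolution_km) {
  labels <- attr(grades, "classes")
  vals <- as.vector(grades$values)
  gs <- sort(unique(vals[!is.na(vals)]))
  counts <- vapply(gs, function(g) sum(vals == g, na.rm = TRUE), 0L)
  data.frame(grade = gs,
             label = if (!is.null(labels)) labels[gs] else as.character(gs),
             n_pixels = counts,
             area_km2 = counts * resolution_km^2)
}
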