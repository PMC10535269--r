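#' Synthetic study-area generator
#'
#' Builds a complete synthetic analogue of the study inputs: a patchy
#' five-class land-cover map, three-date 8-band scenes with per-class
#' Gaussian spectra (red-edge bands carry configurably larger inter-class
#' separation for the two tree classes), seasonal climate grids, a monthly
#' NDVI series, and occurrence/background points drawn from a known logistic
#' suitability surface over spatially autocorrelated bioclimatic covariates.
#' Everything is reproducible from one integer seed.
#'
#' @name synthdata
NULL

BAND_NAMES <- c("B1", "B2", "B3", "B4", "B5", "B6", "B7", "B8")
BAND_ROLES <- c(B1 = "Blue", B2 = "Green", B3 = "Red", B4 = "Near-infrared",
                B5 = "Red Edge 1", B6 = "Red Edge 2", B7 = "Violet",
                B8 = "Yellow")
CLASS_NAMES <- c("urban", "waterbody", "cropland", "other_forests",
                 "e_ulmoides")

# Evaluate expr with a private, restored RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed for a named stage, kept below 2^31.
sub_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  (as.double(seed) * 7919 + h * 131) %% 2147483647
}

#' Construct the ground-truth parameter set for the synthetic study area
#'
#' The five land-cover classes mirror a mixed agricultural/forest county:
#' urban, waterbody, cropland, other forests and the target plantation tree
#' (*E. ulmoides* analogue). Class spectra are per-date Gaussian means and
#' standard deviations over the 8 bands, plus a shared multiplicative
#' brightness factor per pixel (a rank-one inter-band correlation emulating
#' within-class canopy/illumination variability). The target-vs-forest mean
#' separation is largest in the red-edge bands (`red_edge_boost`) and on the
#' third (September) date, so red-edge added value and the optimal time
#' window exist by construction.
#'
#' @param nrow,ncol label-raster dimensions in pixels.
#' @param res pixel size in metres.
#' @param seed integer master seed; all generators derive sub-seeds from it.
#' @param n_patches number of Voronoi seed sites for the class map.
#' @param red_edge_boost multiplier on the target-vs-forest mean separation
#'   in bands B5/B6 (1 = default realism; 0 removes the red-edge advantage).
#' @param sd_scale multiplier on every class standard deviation and
#'   brightness-factor sd; values below 1 give a more separable scene.
#' @param suit_intercept,suit_weights intercept and named weights (over
#'   standardized BIO layers) of the true occurrence-generating logistic
#'   surface.
#' @param bioclim_sigma Gaussian smoothing radius (pixels) giving the
#'   bioclim layers their spatial autocorrelation.
#' @return a `synth_truth` list with label raster, class spectra, climate,
#'   NDVI-phenology and suitability parameters.
#' @export
synth_truth <- function(nrow = 120, ncol = 120, res = 16, seed = 1,
                        n_patches = 60, red_edge_boost = 1, sd_scale = 1,
                        suit_intercept = -10,
                        suit_weights = c(BIO17 = 8),
                        bioclim_sigma = 6) {
  stopifnot(nrow > 0, ncol > 0, res > 0, n_patches >= length(CLASS_NAMES))
  dates <- c("2021-05-09", "2021-06-28", "2021-09-09")
  # per-date scale of the target-vs-forest separation: September is the
  # configured optimal window, June the worst
  sep <- c(0.62, 0.45, 1.0)

  forest <- rbind(
    c(.042, .072, .055, .400, .140, .280, .037, .058),   # May
    c(.040, .070, .052, .430, .155, .310, .035, .056),   # June
    c(.040, .070, .050, .420, .150, .300, .035, .055))   # September
  # red-edge position shift: the target tree sits lower in B5, higher in
  # B6 than other forests, with a modest NIR and red offset; this keeps the
  # separation largely orthogonal to the shared brightness direction
  delta <- c(.002, .008, -.014, .045, -.028, .050, .002, .002)
  boost <- c(1, 1, 1, 1, red_edge_boost, red_edge_boost, 1, 1)
  ulmo <- forest + outer(sep, delta * boost)

  crop <- rbind(
    c(.050, .090, .070, .350, .160, .300, .040, .080),
    c(.100, .130, .160, .220, .180, .200, .080, .150),
    c(.050, .080, .060, .380, .170, .320, .040, .070))
  urban <- matrix(c(.16, .18, .20, .24, .21, .22, .14, .19),
                  nrow = 3, ncol = 8, byrow = TRUE)
  water <- matrix(c(.08, .06, .04, .02, .033, .028, .09, .05),
                  nrow = 3, ncol = 8, byrow = TRUE)

  mk <- function(mean, sd, gain_sd) {
    dimnames(mean) <- list(dates, BAND_NAMES)
    list(mean = mean,
         sd = matrix(sd * sd_scale, 3, 8, dimnames = dimnames(mean)),
         gain_sd = gain_sd * sd_scale)
  }
  spectra <- list(
    urban         = mk(urban, .025, .06),
    waterbody     = mk(water, .008, .03),
    cropland      = mk(crop, .020, .08),
    other_forests = mk(forest, .015, .08),
    e_ulmoides    = mk(ulmo, .015, .08))

  # monthly seasonal sinusoids: value(t) = mean + amplitude*cos(2*pi*(t-peak)/12)
  climate <- list(
    sol  = list(mean = 420, amplitude = 180, peak_month = 6.5, noise_sd = 15),
    temp = list(mean = 14, amplitude = 12, peak_month = 7, noise_sd = 0.5),
    prec = list(mean = 60, amplitude = 55, peak_month = 7, noise_sd = 8))

  # per-class NDVI phenology for the CASA stage (12-month sinusoid + noise)
  ndvi_pheno <- list(
    urban         = list(mean = 0.15, amplitude = 0.03, peak_month = 7, noise_sd = 0.02),
    waterbody     = list(mean = -0.10, amplitude = 0.02, peak_month = 7, noise_sd = 0.02),
    cropland      = list(mean = 0.45, amplitude = 0.25, peak_month = 7, noise_sd = 0.03),
    other_forests = list(mean = 0.55, amplitude = 0.25, peak_month = 7, noise_sd = 0.03),
    e_ulmoides    = list(mean = 0.50, amplitude = 0.28, peak_month = 7, noise_sd = 0.03))

  labels <- voronoi_labels(nrow, ncol, res, n_patches,
                           seed = sub_seed(seed, "labels"))

  structure(list(nrow = nrow, ncol = ncol, res = res, seed = seed,
                 dates = dates, classes = CLASS_NAMES, labels = labels,
                 spectra = spectra, climate = climate,
                 ndvi_pheno = ndvi_pheno,
                 suitability = list(intercept = suit_intercept,
                                    weights = suit_weights),
                 bioclim_sigma = bioclim_sigma),
            class = "synth_truth")
}

# Contiguous polygonal class patches: nearest-site Voronoi labelling with
# sites assigned to classes round-robin, so every class holds several patches.
voronoi_labels <- function(nrow, ncol, res, n_patches, seed) {
  with_seed(seed, {
    sx <- runif(n_patches, 0, ncol)
    sy <- runif(n_patches, 0, nrow)
    scls <- rep(seq_along(CLASS_NAMES), length.out = n_patches)[
      sample.int(n_patches)]
    cx <- matrix(rep(seq_len(ncol) - 0.5, each = nrow), nrow, ncol)
    cy <- matrix(rep(nrow - seq_len(nrow) + 0.5, times = ncol), nrow, ncol)
    best <- matrix(Inf, nrow, ncol)
    lab <- matrix(1L, nrow, ncol)
    for (k in seq_len(n_patches)) {
      d2 <- (cx - sx[k])^2 + (cy - (nrow - sy[k]))^2
      upd <- d2 < best
      best[upd] <- d2[upd]
      lab[upd] <- scls[k]
    }
    g <- grid_raster(lab, res = res, xmin = 0, ymax = nrow * res)
    attr(g, "classes") <- CLASS_NAMES
    g
  })
}

#' Generate one acquisition date's 8-band scene
#'
#' Pixel values are drawn per class from the configured Gaussian spectra:
#' `value = gain * mean + noise`, with `gain ~ N(1, gain_sd^2)` shared across
#' the 8 bands of a pixel and `noise` independent per band. The shared gain
#' induces the configured inter-band correlation.
#'
#' @param truth a [synth_truth()] object.
#' @param date one of `truth$dates`.
#' @return list with `scene` (a `grid_stack` of bands B1..B8, band roles in
#'   the `roles` attribute) and `labels` (the class raster).
#' @export
generate_scene <- function(truth, date) {
  stopifnot(inherits(truth, "synth_truth"))
  di <- match(date, truth$dates)
  if (is.na(di)) {
    stop(sprintf("unknown acquisition date '%s' (configured: %s)", date,
                 paste(truth$dates, collapse = ", ")))
  }
  lab <- truth$labels$values
  cls_present <- sort(unique(as.vector(lab)))
  missing <- setdiff(attr(truth$labels, "classes")[cls_present],
                     names(truth$spectra))
  if (length(missing) > 0) {
    stop("no spectral model configured for class: ",
         paste(missing, collapse = ", "))
  }
  with_seed(sub_seed(truth$seed, paste0("scene", di)), {
    n <- length(lab)
    gain <- rnorm(n, 1, 0)   # filled per class below
    bands <- lapply(BAND_NAMES, function(b) matrix(NA_real_, nrow(lab), ncol(lab)))
    names(bands) <- BAND_NAMES
    for (ci in cls_present) {
      cname <- attr(truth$labels, "classes")[ci]
      sp <- truth$spectra[[cname]]
      idx <- which(lab == ci)
      g <- rnorm(length(idx), 1, sp$gain_sd)
      for (b in seq_along(BAND_NAMES)) {
        mu <- sp$mean[di, b]; s <- sp$sd[di, b]
        bands[[b]][idx] <- g * mu + rnorm(length(idx), 0, s)
      }
    }
    scene <- grid_stack(bands, res = truth$res, xmin = 0,
                        ymax = nrow(lab) * truth$res)
    attr(scene, "roles") <- BAND_ROLES
    attr(scene, "date") <- date
    list(scene = scene, labels = truth$labels)
  })
}

#' Generate all configured dates as a multi-date scene set
#'
#' @param truth a [synth_truth()] object.
#' @return named list of `grid_stack`s keyed by date string.
#' @export
generate_scenes <- function(truth) {
  out <- lapply(truth$dates, function(d) generate_scene(truth, d)$scene)
  names(out) <- truth$dates
  out
}

#' Sample labelled ground points with a minimum-spacing rule
#'
#' Draws the requested number of points per class at pixel centres of the
#' label raster, enforcing a minimum distance between any two points (across
#' classes), then splits each class 3:1 into train/test
#' (`train = floor(3n/4)`).
#'
#' @param labels class `grid_raster` (with a `classes` attribute).
#' @param n_per_class named or positional integer vector of point counts.
#' @param min_distance minimum pairwise point distance in map units.
#' @param seed integer seed.
#' @return data.frame `x, y, class, partition` (class as factor,
#'   partition "train"/"test").
#' @export
sample_points <- function(labels, n_per_class, min_distance = 20, seed = 1) {
  classes <- attr(labels, "classes")
  if (is.null(classes)) classes <- as.character(sort(unique(as.vector(labels$values))))
  if (is.null(names(n_per_class))) {
    stopifnot(length(n_per_class) == length(classes))
    names(n_per_class) <- classes
  }
  with_seed(seed, {
    acc_x <- numeric(0); acc_y <- numeric(0)
    acc_cls <- character(0)
    co <- grid_coords(labels)
    labv <- as.vector(labels$values)   # column-major matches expand.grid order
    lab_at <- labels$values[cbind(co$row, co$col)]
    for (cname in names(n_per_class)) {
      ci <- match(cname, classes)
      elig <- which(lab_at == ci)
      elig <- elig[sample.int(length(elig))]
      need <- n_per_class[[cname]]
      got <- 0L
      for (e in elig) {
        if (got >= need) break
        px <- co$x[e]; py <- co$y[e]
        if (length(acc_x) == 0 ||
            all((acc_x - px)^2 + (acc_y - py)^2 >= min_distance^2)) {
          acc_x <- c(acc_x, px); acc_y <- c(acc_y, py)
          acc_cls <- c(acc_cls, cname)
          got <- got + 1L
        }
      }
      if (got < need) {
        stop(sprintf(
          "cannot place %d points of class '%s' at spacing >= %g (placed %d)",
          need, cname, min_distance, got))
      }
    }
    part <- character(length(acc_cls))
    for (cname in unique(acc_cls)) {
      idx <- which(acc_cls == cname)
      n <- length(idx)
      n_train <- floor(3 * n / 4)
      shuf <- idx[sample.int(n)]
      part[shuf[seq_len(n_train)]] <- "train"
      part[shuf[-seq_len(n_train)]] <- "test"
    }
    data.frame(x = acc_x, y = acc_y,
               class = factor(acc_cls, levels = classes),
               partition = part, stringsAsFactors = FALSE)
  })
}

#' Generate monthly climate grids (solar radiation, temperature, precipitation)
#'
#' Each variable follows its configured seasonal sinusoid plus independent
#' pixel noise; solar radiation and precipitation are clamped at zero.
#'
#' @param truth a [synth_truth()] object.
#' @param months integer vector of months (the annual CASA run needs all 12).
#' @return list with one element per month, each a `grid_stack` with layers
#'   `sol` (MJ m-2 month-1), `temp` (deg C) and `prec` (mm).
#' @export
generate_climate <- function(truth, months = 1:12) {
  stopifnot(all(months %in% 1:12))
  for (v in names(truth$climate)) {
    p <- truth$climate[[v]]
    if (v %in% c("sol", "prec") && p$amplitude > p$mean) {
      stop(sprintf("configured %s amplitude (%g) exceeds mean (%g): %s",
                   v, p$amplitude, p$mean,
                   "seasonal minimum would be negative"))
    }
  }
  nr <- truth$nrow; nc <- truth$ncol
  with_seed(sub_seed(truth$seed, "climate"), {
    out <- lapply(months, function(t) {
      layers <- lapply(names(truth$climate), function(v) {
        p <- truth$climate[[v]]
        m <- p$mean + p$amplitude * cos(2 * pi * (t - p$peak_month) / 12)
        val <- matrix(m + rnorm(nr * nc, 0, p$noise_sd), nr, nc)
        if (v %in% c("sol", "prec")) val[val < 0] <- 0
        val
      })
      names(layers) <- names(truth$climate)
      grid_stack(layers, res = truth$res, xmin = 0, ymax = nr * truth$res)
    })
    names(out) <- sprintf("month_%02d", months)
    out
  })
}

#' Generate a 12-month NDVI series from the per-class phenology curves
#'
#' @param truth a [synth_truth()] object.
#' @return `grid_stack` with layers `ndvi_01` .. `ndvi_12`.
#' @export
generate_ndvi_series <- function(truth) {
  lab <- truth$labels$values
  classes <- attr(truth$labels, "classes")
  with_seed(sub_seed(truth$seed, "ndvi"), {
    layers <- lapply(1:12, function(t) {
      out <- matrix(NA_real_, nrow(lab), ncol(lab))
      for (ci in seq_along(classes)) {
        p <- truth$ndvi_pheno[[classes[ci]]]
        idx <- which(lab == ci)
        m <- p$mean + p$amplitude * cos(2 * pi * (t - p$peak_month) / 12)
        out[idx] <- pmin(0.99, pmax(-0.99,
                         m + rnorm(length(idx), 0, p$noise_sd)))
      }
      out
    })
    names(layers) <- sprintf("ndvi_%02d", 1:12)
    grid_stack(layers, res = truth$res, xmin = 0,
               ymax = nrow(lab) * truth$res)
  })
}

# Separable Gaussian blur with edge renormalization.
smooth_gauss <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  conv1 <- function(m) {   # filter along rows (down each column)
    n <- nrow(m)
    pad <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
    out <- apply(pad, 2, function(col) stats::filter(col, k, sides = 2))
    out[(r + 1):(r + n), , drop = FALSE]
  }
  ones <- matrix(1, nrow(mat), ncol(mat))
  num <- t(conv1(t(conv1(mat))))
  den <- t(conv1(t(conv1(ones))))
  num / den
}

#' Generate occurrence points and 19 bioclimatic covariate layers
#'
#' Covariates BIO1..BIO19 are spatially autocorrelated fields
#' (Gaussian-filtered white noise, standardized, then mapped to plausible
#' bioclim units). Occurrence cells are sampled with probability
#' proportional to the configured logistic suitability surface over the
#' standardized driver layers; background cells uniformly.
#'
#' @param truth a [synth_truth()] object.
#' @param n_occurrences number of presence points (>= 10).
#' @param n_background number of background points.
#' @param seed integer seed.
#' @return list: `presence` and `background` data.frames (`x`, `y`),
#'   `bioclim` (19-layer `grid_stack`), `bioclim_std` (standardized fields),
#'   `suitability` (true-probability `grid_raster`), and `coefficients`.
#' @export
generate_sdm_inputs <- function(truth, n_occurrences = 120,
                                n_background = 2000, seed = truth$seed) {
  if (n_occurrences < 10) stop("need at least 10 occurrence points")
  nr <- truth$nrow; nc <- truth$ncol
  bio_names <- paste0("BIO", 1:19)
  w <- truth$suitability$weights
  if (!all(names(w) %in% bio_names)) {
    stop("suitability weights must be named over BIO1..BIO19")
  }
  # plausible unit mappings: temperature-like for BIO1-11, precipitation-like
  # for BIO12-19
  offsets <- c(14, 9, 30, 800, 28, -2, 30, 22, 2, 25, 1, 800, 180, 8, 70,
               450, 40, 400, 50)
  scales <- c(2, 1, 4, 80, 2, 2, 3, 2, 2, 2, 2, 120, 30, 3, 10, 70, 10, 60, 12)
  with_seed(seed, {
    std <- list(); raw <- list()
    for (i in 1:19) {
      f <- smooth_gauss(matrix(rnorm(nr * nc), nr, nc), truth$bioclim_sigma)
      s <- sd(as.vector(f))
      if (s < 1e-12) stop(sprintf("degenerate (constant) covariate BIO%d", i))
      z <- (f - mean(f)) / s
      std[[bio_names[i]]] <- z
      raw[[bio_names[i]]] <- offsets[i] + scales[i] * z
    }
    eta <- matrix(truth$suitability$intercept, nr, nc)
    for (v in names(w)) {
      if (sd(as.vector(std[[v]])) < 1e-12) {
        stop(sprintf("degenerate (constant) covariate %s requested as driver", v))
      }
      eta <- eta + w[[v]] * std[[v]]
    }
    suit <- 1 / (1 + exp(-eta))
    g <- grid_raster(suit, res = truth$res, xmin = 0, ymax = nr * truth$res)
    co <- grid_coords(g)
    cellv <- suit[cbind(co$row, co$col)]
    pres_idx <- sample.int(nrow(co), n_occurrences, replace = FALSE,
                           prob = cellv)
    bg_idx <- sample.int(nrow(co), min(n_background, nrow(co)),
                         replace = FALSE)
    list(presence = data.frame(x = co$x[pres_idx], y = co$y[pres_idx]),
         background = data.frame(x = co$x[bg_idx], y = co$y[bg_idx]),
         bioclim = grid_stack(raw, res = truth$res, xmin = 0,
                              ymax = nr * truth$res),
         bioclim_std = grid_stack(std, res = truth$res, xmin = 0,
                                  ymax = nr * truth$res),
         suitability = g,
         coefficients = list(intercept = truth$suitability$intercept,
                             weights = w))
  })
}

#' Population (configured) J-M distance between two classes over a band set
#'
#' Uses the configured class model exactly: mean vector `m`, covariance
#' `gain_sd^2 * m m' + diag(sd^2)` restricted to the requested bands, and
#' the closed-form Gaussian Bhattacharyya distance. This is the ground-truth
#' separability the generator was configured to produce, independent of any
#' sampled scene.
#'
#' @param truth a [synth_truth()] object.
#' @param date one of `truth$dates`.
#' @param class_a,class_b class names.
#' @param bands subset of B1..B8 (default all 8).
#' @return J-M distance in \[0, 2\].
#' @export
configured_jm <- function(truth, date, class_a, class_b,
                          bands = BAND_NAMES) {
  di <- match(date, truth$dates)
  stopifnot(!is.na(di), class_a %in% names(truth$spectra),
            class_b %in% names(truth$spectra))
  bi <- match(bands, BAND_NAMES)
  mom <- function(cl) {
    sp <- truth$spectra[[cl]]
    m <- sp$mean[di, bi]
    S <- sp$gain_sd^2 * tcrossprod(m) + diag(sp$sd[di, bi]^2,
                                             length(bi))
    list(m = m, S = S)
  }
  a <- mom(class_a); b <- mom(class_b)
  B <- bhattacharyya_mv(a$m, a$S, b$m, b$S)
  2 * (1 - exp(-B))
}
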