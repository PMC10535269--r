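#' Radiometric calibration: digital numbers to radiance
#'
#' `L = Gain * DN + bias`, applied per band. NA (nodata) pixels propagate.
#'
#' @param dn a `grid_stack` of digital numbers (or a single matrix).
#' @param gain,bias per-band calibration coefficients (recycled if scalar);
#'   all gains must be positive.
#' @return calibrated object of the same shape.
#' @export
calibrate_radiance <- function(dn, gain, bias) {
  if (inherits(dn, "grid_stack")) {
    nb <- length(dn$layers)
    gain <- rep_len(gain, nb); bias <- rep_len(bias, nb)
    if (length(gain) != nb) stop("gain/bias length does not match band count")
    if (any(gain <= 0)) stop("calibration gains must be > 0")
    out <- dn
    for (i in seq_len(nb)) out$layers[[i]] <- gain[i] * dn$layers[[i]] + bias[i]
    out
  } else {
    if (length(gain) != 1 || length(bias) != 1) {
      stop("band-count mismatch: matrix input takes scalar gain/bias")
    }
    if (gain <= 0) stop("calibration gains must be > 0")
    gain * dn + bias
  }
}

INDEX_DEFS <- list(
  NDVI    = c(num = "B4", den = "B3"),
  NDVI710 = c(num = "B5", den = "B3"),
  NDVI750 = c(num = "B6", den = "B3"))

#' Compute a normalized-difference vegetation index
#'
#' `NDVI = (B4 - B3)/(B4 + B3)`; the red-edge variants `NDVI710` and
#' `NDVI750` substitute B5 and B6 for B4. Pixels with a zero denominator
#' become NA and are counted in the `n_zero_denominator` attribute.
#'
#' @param scene `grid_stack` with bands B1..B8.
#' @param index one of `"NDVI"`, `"NDVI710"`, `"NDVI750"`.
#' @return index matrix in \[-1, 1\] (NA where undefined).
#' @export
compute_index <- function(scene, index) {
  if (!index %in% names(INDEX_DEFS)) {
    stop(sprintf("unknown index '%s' (available: %s)", index,
                 paste(names(INDEX_DEFS), collapse = ", ")))
  }
  def <- INDEX_DEFS[[index]]
  a <- scene$layers[[def[["num"]]]]
  b <- scene$layers[[def[["den"]]]]
  if (is.null(a) || is.null(b)) stop("required bands missing from scene")
  den <- a + b
  out <- (a - b) / den
  nz <- sum(den == 0, na.rm = TRUE)
  out[!is.na(den) & den == 0] <- NA_real_
  attr(out, "n_zero_denominator") <- nz
  out
}

#' Band-combination registry
#'
#' The eight classification models and the three separability screening
#' combinations. Models 1-8 pair band subsets with vegetation indices;
#' combinations 1-3 are the no-red-edge, all-band and all-band-plus-index
#' screening sets.
#'
#' @param which `"models"`, `"combinations"` or `"all"`.
#' @return named list of combinations, each `list(id, bands, indices)`.
#' @export
band_combinations <- function(which = c("models", "combinations", "all")) {
  which <- match.arg(which)
  b <- function(...) paste0("B", c(...))
  models <- list(
    model1 = list(id = "model1", bands = b(1:4, 7, 8), indices = character(0)),
    model2 = list(id = "model2", bands = b(1:4, 5, 7, 8), indices = character(0)),
    model3 = list(id = "model3", bands = b(1:4, 6, 7, 8), indices = character(0)),
    model4 = list(id = "model4", bands = b(1:8), indices = character(0)),
    model5 = list(id = "model5", bands = b(1:4, 7, 8), indices = "NDVI"),
    model6 = list(id = "model6", bands = b(1:4, 5, 7, 8),
                  indices = c("NDVI", "NDVI710")),
    model7 = list(id = "model7", bands = b(1:4, 6, 7, 8),
                  indices = c("NDVI", "NDVI750")),
    model8 = list(id = "model8", bands = b(1:8),
                  indices = c("NDVI", "NDVI710", "NDVI750")))
  combos <- list(
    combination1 = list(id = "combination1", bands = b(1:4, 7, 8),
                        indices = character(0)),
    combination2 = list(id = "combination2", bands = b(1:8),
                        indices = character(0)),
    combination3 = list(id = "combination3", bands = b(1:8),
                        indices = c("NDVI", "NDVI710", "NDVI750")))
  switch(which, models = models, combinations = combos,
         all = c(models, combos))
}

#' Write / read the combination registry as YAML
#' @param registry list from [band_combinations()].
#' @param path YAML file path.
#' @return `path` (write) or the registry (read).
#' @export
write_registry <- function(registry, path) {
  yaml::write_yaml(registry, path)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) yaml::read_yaml(path)

#' Extract a per-sample feature table for one band combination
#'
#' One row per sample point; columns are the combination's bands in B-number
#' order followed by its indices (NDVI, NDVI710, NDVI750 order). Values come
#' from the pixel containing each point (nearest pixel, no interpolation).
#' Points outside the raster are kept as all-NA rows and listed in the
#' `excluded` element rather than silently dropped.
#'
#' @param scene `grid_stack` with bands B1..B8.
#' @param samples data.frame with `x`, `y` (and usually `class`,
#'   `partition`).
#' @param combo a registry entry (`list(id, bands, indices)`).
#' @return list: `features` (matrix), `samples` (the input), `excluded`
#'   (integer row indices that fell outside the raster), `combo_id`.
#' @export
build_feature_table <- function(scene, samples, combo) {
  stopifnot(all(combo$bands %in% names(scene$layers)))
  cols <- c(combo$bands, combo$indices)
  feats <- matrix(NA_real_, nrow = nrow(samples), ncol = length(cols),
                  dimnames = list(NULL, cols))
  if (nrow(samples) > 0) {
    bandvals <- grid_extract(scene, samples$x, samples$y)
    feats[, combo$bands] <- bandvals[, combo$bands, drop = FALSE]
    for (ix in combo$indices) {
      def <- INDEX_DEFS[[ix]]
      num <- bandvals[, def[["num"]]]; den0 <- bandvals[, def[["den"]]]
      s <- num + den0
      v <- (num - den0) / s
      v[!is.na(s) & s == 0] <- NA_real_
      feats[, ix] <- v
    }
  }
  rc <- grid_cell_at(scene, samples$x, samples$y)
  excluded <- which(is.na(rc$row))
  list(features = feats, samples = samples, excluded = excluded,
       combo_id = combo$id)
}
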