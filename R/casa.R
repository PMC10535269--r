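#' CASA light-use-efficiency NPP model
#'
#' Monthly net primary productivity as the product of absorbed
#' photosynthetically active radiation and an actual light-use efficiency:
#' `NPP = APAR * Te1 * Te2 * We * eps_max`, with
#' `APAR = 0.5 * SOL * FPAR(NDVI)`. The stress-term formulations follow the
#' widely used regional CASA parameterization: an NDVI/simple-ratio
#' linear-stretch FPAR blend, a two-term temperature stress around a
#' per-pixel optimal temperature, and a water stress driven by the ratio of
#' estimated to potential evapotranspiration. All stress functions are
#' exported individually so alternates can be swapped in.
#'
#' @name casa
NULL

#' FPAR from NDVI (linear-stretch blend)
#'
#' Averages (with weight `alpha`) the NDVI linear stretch and the simple
#' ratio `SR = (1+NDVI)/(1-NDVI)` linear stretch, each mapping the
#' vegetation-type range (`ndvi_min`, `ndvi_max`) onto \[0.001, 0.95\];
#' the result is clamped to the same interval.
#'
#' @param ndvi NDVI values in \[-1, 1\] (matrix or vector).
#' @param ndvi_min,ndvi_max vegetation-type NDVI range (min < max).
#' @param alpha blend weight of the NDVI stretch (default 0.5).
#' @return FPAR, same shape as `ndvi`, in \[0.001, 0.95\].
#' @export
fpar <- function(ndvi, ndvi_min, ndvi_max, alpha = 0.5) {
  if (ndvi_min >= ndvi_max) stop("degenerate stretch: ndvi_min >= ndvi_max")
  lo <- 0.001; hi <- 0.95
  stretch <- function(v, vmin, vmax) {
    pmax(pmin((v - vmin) * (hi - lo) / (vmax - vmin) + lo, hi), lo)
  }
  sr <- (1 + ndvi) / (1 - ndvi)
  sr_min <- (1 + ndvi_min) / (1 - ndvi_min)
  sr_max <- (1 + ndvi_max) / (1 - ndvi_max)
  f <- alpha * stretch(ndvi, ndvi_min, ndvi_max) +
    (1 - alpha) * stretch(sr, sr_min, sr_max)
  pmax(pmin(f, hi), lo)
}

#' Absorbed photosynthetically active radiation
#'
#' `APAR = 0.5 * SOL * FPAR`; 0.5 is the PAR fraction of total solar
#' radiation.
#' @param sol total solar radiation, MJ m-2 month-1 (non-negative).
#' @param fpar_val FPAR from [fpar()].
#' @return APAR, MJ m-2 month-1.
#' @export
apar <- function(sol, fpar_val) {
  if (any(sol < 0, na.rm = TRUE)) stop("negative solar radiation input")
  if (!all(dim(as.matrix(sol)) == dim(as.matrix(fpar_val)))) {
    stop("sol and fpar shapes differ")
  }
  0.5 * sol * fpar_val
}

#' Two-term temperature stress
#'
#' `Te1 = 0.8 + 0.02 T_opt - 0.0005 T_opt^2` (clamped at 0) captures the
#' reduced efficiency of vegetation adapted to extreme optima; `Te2`
#' penalizes departure of the month's temperature from the optimum through
#' two logistic shoulders and is bounded by 1.1814.
#'
#' @param temp monthly mean temperature, deg C.
#' @param t_opt optimal growth temperature, deg C (pixel- or type-level).
#' @return list with `te1` and `te2`, shaped like `temp`.
#' @export
temperature_stress <- function(temp, t_opt) {
  if (any(!is.finite(t_opt))) stop("t_opt must be finite")
  te1 <- pmax(0.8 + 0.02 * t_opt - 0.0005 * t_opt^2, 0)
  te2 <- 1.1814 / ((1 + exp(0.2 * (t_opt - 10 - temp))) *
                     (1 + exp(0.3 * (-t_opt - 10 + temp))))
  if (length(te1) == 1 && length(te2) > 1) {
    te1 <- if (is.null(dim(te2))) rep(te1, length(te2)) else
      array(te1, dim = dim(te2))
  }
  list(te1 = te1, te2 = pmax(te2, 0))
}

#' Thornthwaite potential evapotranspiration (monthly, mm)
#'
#' `PET = 16 (10 T / I)^a` for T > 0 (0 otherwise), with `I` the annual heat
#' index `sum((T_m/5)^1.514)` over months with positive mean temperature.
#'
#' @param temp monthly mean temperature, deg C.
#' @param heat_index annual heat index `I` (see [annual_heat_index()]).
#' @return potential evapotranspiration, mm.
#' @export
thornthwaite_pet <- function(temp, heat_index) {
  a <- 6.75e-7 * heat_index^3 - 7.71e-5 * heat_index^2 +
    1.792e-2 * heat_index + 0.49239
  out <- ifelse(temp > 0 & heat_index > 0,
                16 * (10 * pmax(temp, 0) / pmax(heat_index, 1e-9))^a, 0)
  if (is.matrix(temp)) out <- matrix(out, nrow(temp), ncol(temp))
  out
}

#' Annual heat index for the Thornthwaite formula
#' @param temp_monthly list (or 3-d array) of 12 monthly temperature grids.
#' @return heat index `I`, same shape as one month.
#' @export
annual_heat_index <- function(temp_monthly) {
  acc <- 0
  for (t in seq_along(temp_monthly)) {
    Tm <- pmax(temp_monthly[[t]], 0)
    acc <- acc + (Tm / 5)^1.514
  }
  acc
}

#' Regional estimated evapotranspiration (Zhou-Zhang form)
#'
#' `EET = P Rn (P^2 + Rn^2 + P Rn) / ((P + Rn)(P^2 + Rn^2))`, with the net
#' radiation surrogate `Rn = sqrt(PET0 * P) * (0.369 + 0.598 sqrt(PET0/P))`.
#' Zero precipitation gives EET = 0.
#'
#' @param prec monthly precipitation, mm.
#' @param pet0 Thornthwaite potential evapotranspiration, mm.
#' @return estimated evapotranspiration, mm.
#' @export
regional_eet <- function(prec, pet0) {
  P <- pmax(prec, 0)
  Rn <- ifelse(P > 0, sqrt(pet0 * P) * (0.369 + 0.598 * sqrt(pet0 / pmax(P, 1e-9))), 0)
  den <- (P + Rn) * (P^2 + Rn^2)
  eet <- ifelse(den > 0, P * Rn * (P^2 + Rn^2 + P * Rn) / den, 0)
  if (is.matrix(prec)) eet <- matrix(eet, nrow(prec), ncol(prec))
  eet
}

#' Water stress from monthly precipitation and temperature
#'
#' `We = 0.5 + 0.5 * EET/PET`, clamped to \[0.5, 1\], with
#' `PET = (EET + PET0)/2`; pixels with PET = 0 get the dry floor 0.5 (their
#' count is reported in the `n_pet_zero` attribute).
#'
#' @param prec monthly precipitation, mm.
#' @param temp monthly mean temperature, deg C.
#' @param heat_index annual heat index from [annual_heat_index()].
#' @return We, same shape as `prec`.
#' @export
water_stress <- function(prec, temp, heat_index) {
  pet0 <- thornthwaite_pet(temp, heat_index)
  eet <- regional_eet(prec, pet0)
  pet <- (eet + pet0) / 2
  we <- water_stress_from_ratio(ifelse(pet > 0, eet / pet, 0))
  attr(we, "n_pet_zero") <- sum(pet <= 0, na.rm = TRUE)
  we
}

#' Water stress from a precomputed EET/PET ratio
#' @param ratio EET/PET in \[0, 1\].
#' @return `0.5 + 0.5 * ratio`, clamped to \[0.5, 1\].
#' @export
water_stress_from_ratio <- function(ratio) {
  pmax(pmin(0.5 + 0.5 * ratio, 1), 0.5)
}

#' Optimal temperature: the month of maximum NDVI
#'
#' The standard CASA convention: each pixel's optimal temperature is the
#' monthly mean temperature of the month in which its NDVI peaks.
#'
#' @param ndvi_series `grid_stack` of 12 monthly NDVI layers.
#' @param climate list of 12 monthly climate stacks (layer `temp`).
#' @return matrix of optimal temperatures.
#' @export
optimal_temperature <- function(ndvi_series, climate) {
  d <- grid_dim(ndvi_series)
  best_ndvi <- matrix(-Inf, d[1], d[2])
  t_opt <- matrix(NA_real_, d[1], d[2])
  for (t in 1:12) {
    nd <- ndvi_series$layers[[t]]
    upd <- nd > best_ndvi
    best_ndvi[upd] <- nd[upd]
    t_opt[upd] <- climate[[t]]$layers$temp[upd]
  }
  t_opt
}

#' Automatic NDVI-range configuration per vegetation type
#'
#' The per-type stretch limits (`ndvi_min`, `ndvi_max`) are the 5th and 95th
#' percentiles of that type's NDVI values across the 12-month series.
#'
#' @param ndvi_series `grid_stack` of 12 monthly NDVI layers.
#' @param veg_map `grid_raster` of vegetation-type codes (with a `classes`
#'   attribute naming them).
#' @param probs the two percentile levels.
#' @return data.frame `type, ndvi_min, ndvi_max`.
#' @export
auto_ndvi_range <- function(ndvi_series, veg_map, probs = c(0.05, 0.95)) {
  classes <- attr(veg_map, "classes")
  if (is.null(classes)) classes <- as.character(sort(unique(as.vector(veg_map$values))))
  rows <- lapply(seq_along(classes), function(ci) {
    idx <- which(veg_map$values == ci)
    vals <- unlist(lapply(ndvi_series$layers, function(l) l[idx]))
    q <- stats::quantile(vals, probs, na.rm = TRUE, names = FALSE)
    data.frame(type = classes[ci], ndvi_min = q[1], ndvi_max = q[2])
  })
  do.call(rbind, rows)
}

#' Default maximum light-use efficiencies per land-cover type (g C/MJ)
#'
#' Literature-standard regional-CASA values; configuration, not ground
#' truth. Deciduous/mixed forest classes use the deciduous broadleaf value,
#' cropland the crop value, and non-vegetated classes a nominal floor.
#'
#' @return named numeric vector.
#' @export
default_epsilon_max <- function() {
  c(urban = 0.389, waterbody = 0.389, cropland = 0.542,
    other_forests = 0.692, e_ulmoides = 0.692)
}

#' NPP from precomputed components
#'
#' The bare product `NPP = APAR * Te1 * Te2 * We * eps_max`
#' (g C m-2 month-1); any zero stress term zeroes the pixel.
#' @param apar_val APAR, MJ m-2 month-1.
#' @param te1,te2,we stress terms.
#' @param eps_max maximum light-use efficiency, g C MJ-1.
#' @return NPP, same shape as the inputs.
#' @export
npp_from_components <- function(apar_val, te1, te2, we, eps_max) {
  apar_val * te1 * te2 * we * eps_max
}

#' Monthly NPP for one month
#'
#' @param ndvi NDVI matrix for the month.
#' @param sol,temp,prec climate matrices for the month.
#' @param t_opt optimal-temperature matrix (see [optimal_temperature()]).
#' @param heat_index annual heat index matrix.
#' @param eps_max matrix (or scalar) of maximum light-use efficiency.
#' @param ndvi_min,ndvi_max FPAR stretch limits (matrices or scalars).
#' @return NPP matrix, g C m-2 month-1.
#' @export
npp_monthly <- function(ndvi, sol, temp, prec, t_opt, heat_index, eps_max,
                        ndvi_min, ndvi_max) {
  fp <- fpar_pixelwise(ndvi, ndvi_min, ndvi_max)
  ap <- apar(sol, fp)
  ts <- temperature_stress(temp, t_opt)
  we <- water_stress(prec, temp, heat_index)
  attr(we, "n_pet_zero") <- NULL
  npp_from_components(ap, ts$te1, ts$te2, we, eps_max)
}

# fpar() with possibly pixel-varying stretch limits
fpar_pixelwise <- function(ndvi, ndvi_min, ndvi_max) {
  if (length(ndvi_min) == 1 && length(ndvi_max) == 1) {
    return(fpar(ndvi, ndvi_min, ndvi_max))
  }
  if (any(ndvi_min >= ndvi_max)) stop("degenerate stretch: ndvi_min >= ndvi_max")
  lo <- 0.001; hi <- 0.95
  st <- function(v, vmin, vmax) {
    pmax(pmin((v - vmin) * (hi - lo) / (vmax - vmin) + lo, hi), lo)
  }
  sr <- (1 + ndvi) / (1 - ndvi)
  srmin <- (1 + ndvi_min) / (1 - ndvi_min)
  srmax <- (1 + ndvi_max) / (1 - ndvi_max)
  pmax(pmin(0.5 * st(ndvi, ndvi_min, ndvi_max) +
              0.5 * st(sr, srmin, srmax), hi), lo)
}

#' Annual CASA run over a 12-month series
#'
#' @param ndvi_series `grid_stack` of 12 monthly NDVI layers.
#' @param climate list of 12 monthly climate stacks (`sol`, `temp`, `prec`).
#' @param veg_map vegetation-type `grid_raster` (classes attribute).
#' @param eps_max_lookup named vector of per-type eps_max
#'   (default [default_epsilon_max()]).
#' @return list: `annual` (`grid_raster`, g C m-2 a-1), `monthly` (list of
#'   12 matrices), `params` (NDVI ranges and eps_max used).
#' @export
casa_annual <- function(ndvi_series, climate, veg_map,
                        eps_max_lookup = default_epsilon_max()) {
  if (length(climate) != 12 || length(ndvi_series$layers) != 12) {
    stop("annual aggregation requires all 12 months")
  }
  classes <- attr(veg_map, "classes")
  ranges <- auto_ndvi_range(ndvi_series, veg_map)
  d <- grid_dim(ndvi_series)
  eps <- matrix(NA_real_, d[1], d[2])
  nmin <- matrix(NA_real_, d[1], d[2])
  nmax <- matrix(NA_real_, d[1], d[2])
  for (ci in seq_along(classes)) {
    idx <- which(veg_map$values == ci)
    eps[idx] <- eps_max_lookup[[classes[ci]]]
    nmin[idx] <- ranges$ndvi_min[ranges$type == classes[ci]]
    nmax[idx] <- ranges$ndvi_max[ranges$type == classes[ci]]
  }
  temps <- lapply(climate, function(m) m$layers$temp)
  hi <- annual_heat_index(temps)
  t_opt <- optimal_temperature(ndvi_series, climate)
  monthly <- vector("list", 12)
  annual <- matrix(0, d[1], d[2])
  for (t in 1:12) {
    monthly[[t]] <- npp_monthly(
      ndvi_series$layers[[t]], climate[[t]]$layers$sol,
      climate[[t]]$layers$temp, climate[[t]]$layers$prec,
      t_opt, hi, eps, nmin, nmax)
    annual <- annual + monthly[[t]]
  }
  list(annual = grid_raster(annual, res = ndvi_series$res,
                            xmin = ndvi_series$xmin, ymax = ndvi_series$ymax),
       monthly = monthly,
       params = list(ranges = ranges, eps_max = eps_max_lookup))
}

#' Grade an annual NPP raster with natural breaks
#'
#' @param annual `grid_raster` of annual NPP.
#' @param n_classes number of grades (default 4: low / medium / high /
#'   very high, ascending).
#' @return list: `grades` (`grid_raster` of 1..k), `breaks`, `labels`.
#' @export
classify_npp <- function(annual, n_classes = 4) {
  jb <- jenks_breaks(as.vector(annual$values), n_classes)
  g <- classify_breaks(annual$values, jb$breaks)
  labels <- c("low", "medium", "high", "very_high")[seq_len(n_classes)]
  gr <- grid_raster(g, res = annual$res, xmin = annual$xmin,
                    ymax = annual$ymax)
  attr(gr, "classes") <- labels
  list(grades = gr, breaks = jb$breaks, labels = labels,
       class_ranges = jb$class_ranges)
}

#' Total annual carbon over a class mask
#'
#' `total (t C a-1) = sum over masked pixels of NPP * pixel_area * 1e-6`.
#'
#' @param annual `grid_raster` of annual NPP, g C m-2 a-1.
#' @param mask logical matrix (TRUE = include), aligned with `annual`.
#' @param pixel_area pixel area in m^2 (default `res^2`).
#' @return total carbon, tonnes per year.
#' @export
total_carbon <- function(annual, mask, pixel_area = annual$res^2) {
  stopifnot(identical(dim(mask), dim(annual$values)))
  if (!any(mask, na.rm = TRUE)) {
    warning("empty mask: total carbon is 0")
    return(0)
  }
  sum(annual$values[which(mask)], na.rm = TRUE) * pixel_area * 1e-6
}

#' Point-sample validation of an NPP estimate against a reference raster
#'
#' Draws `n_points` random valid pixels, extracts both rasters there, and
#' reports RMSE, the Pearson correlation r and r^2 (both correlation forms
#' are reported since published usage conflates them).
#'
#' @param est,ref co-registered `grid_raster`s.
#' @param n_points number of validation points (default 30).
#' @param seed integer seed.
#' @return list: `rmse`, `r`, `r2`, `points` (sampled coordinates and
#'   values).
#' @export
validate_npp <- function(est, ref, n_points = 30, seed = 1) {
  stopifnot(identical(dim(est$values), dim(ref$values)))
  ok <- which(is.finite(est$values) & is.finite(ref$values))
  if (length(ok) < n_points) stop("fewer valid pixels than requested points")
  with_seed(seed, {
    pick <- sample(ok, n_points)
    yp <- est$values[pick]; yt <- ref$values[pick]
    rmse <- sqrt(mean((yt - yp)^2))
    if (stats::sd(yt) == 0 || stats::sd(yp) == 0) {
      stop("correlation undefined: zero variance in sampled values")
    }
    r <- stats::cor(yt, yp)
    arr <- arrayInd(pick, dim(est$values))
    pts <- data.frame(row = arr[, 1], col = arr[, 2],
                      x = est$xmin + (arr[, 2] - 0.5) * est$res,
                      y = est$ymax - (arr[, 1] - 0.5) * est$res,
                      est = yp, ref = yt)
    list(rmse = rmse, r = r, r2 = r^2, points = pts, seed = seed)
  })
}

#' Inverse-distance interpolation of station records onto a grid
#'
#' For climate supplied as points rather than grids. Power-2 weighting;
#' a station coincident with a pixel centre takes its exact value.
#'
#' @param stations data.frame `x, y, value`.
#' @param template `grid_raster` defining the output grid.
#' @param power IDW exponent (default 2).
#' @return `grid_raster` of interpolated values.
#' @export
idw_interpolate <- function(stations, template, power = 2) {
  co <- grid_coords(template)
  out <- numeric(nrow(co))
  for (i in seq_len(nrow(co))) {
    d2 <- (stations$x - co$x[i])^2 + (stations$y - co$y[i])^2
    if (any(d2 == 0)) {
      out[i] <- stations$value[which.min(d2)]
    } else {
      w <- 1 / d2^(power / 2)
      out[i] <- sum(w * stations$value) / sum(w)
    }
  }
  d <- grid_dim(template)
  grid_raster(matrix(out, d[1], d[2]), res = template$res,
              xmin = template$xmin, ymax = template$ymax)
}
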