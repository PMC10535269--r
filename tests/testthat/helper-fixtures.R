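# Shared fixtures, all built in code.

# Five-class reference confusion matrix (rows = mapped, cols = reference)
# with known marginals; the urban, waterbody and target rows and the urban,
# waterbody, cropland and target columns are internally consistent, the
# remaining margins are deliberately not reproducible from the cells (the
# fixture mirrors a published table with typographic errors in two rows).
reference_confusion <- function() {
  cls <- c("urban", "waterbody", "cropland", "other_forests", "e_ulmoides")
  m <- matrix(c(
    1053,   6,  15,    0,    0,
      16, 378,   0,    0,    0,
       8,   0, 418,    9,   10,
       0,   0,  22, 1276,  130,
       0,   0,   0,  250, 1610),
    nrow = 5, byrow = TRUE, dimnames = list(cls, cls))
  new_confusion_matrix(m)
}

# Small synthetic study area for fast tests.
small_truth <- function(seed = 1, ...) {
  synth_truth(nrow = 60, ncol = 60, seed = seed, ...)
}

# Survey-design sample counts per class.
survey_counts <- function() {
  c(urban = 45, waterbody = 28, cropland = 43, other_forests = 53,
    e_ulmoides = 39)
}

# Numerical-integration oracle for the J-M distance of two 1-D Gaussians:
# J = 2 (1 - BC) with BC the Bhattacharyya coefficient integral.
jm_numeric_1d <- function(mu1, s1, mu2, s2) {
  bc <- stats::integrate(function(x) {
    sqrt(stats::dnorm(x, mu1, s1) * stats::dnorm(x, mu2, s2))
  }, -Inf, Inf, rel.tol = 1e-12)$value
  2 * (1 - bc)   # J = 2(1 - BC); BC = exp(-B)
}

# Exhaustive-search oracle for optimal k-class 1-D partitions: enumerates
# every split of the sorted values and returns the minimal within-class SSD.
jenks_exhaustive_ssd <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  ssd <- function(v) sum((v - mean(v))^2)
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (j in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, j], n)
    tot <- 0
    for (g in seq_len(k)) {
      tot <- tot + ssd(xs[(bounds[g] + 1):bounds[g + 1]])
    }
    best <- min(best, tot)
  }
  best
}
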