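#' Fisher-Jenks natural breaks (exact dynamic program)
#'
#' Partitions sorted values into `k` classes minimizing the within-class sum
#' of squared deviations, via the O(k n^2) Fisher dynamic program with
#' prefix-sum class costs (exact, not the heuristic Jenks-Caspall
#' iteration). Inputs longer than `max_n` are first thinned to `max_n`
#' order statistics — the standard practice for raster-scale inputs — and
#' the resulting breaks are then applicable to the full data.
#'
#' @param x numeric vector (non-finite values dropped).
#' @param k number of classes (>= 2); `x` must contain at least `k`
#'   distinct values.
#' @param max_n size above which the input is thinned to evenly spaced
#'   order statistics before the exact program runs (default 2000).
#' @return list: `breaks` (k-1 upper class boundaries, placed halfway
#'   between the adjacent data values), `ssd` (optimal within-class sum of
#'   squares of the solved sequence), `class_ranges` (k x 2 matrix of
#'   min/max value per class).
#' @export
jenks_breaks <- function(x, k = 4, max_n = 2000) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < k) {
    stop(sprintf("need at least %d distinct finite values for %d classes", k, k))
  }
  xs <- sort(x)
  if (length(xs) > max_n) {
    probs <- (seq_len(max_n) - 0.5) / max_n
    xs <- as.numeric(stats::quantile(xs, probs, names = FALSE, type = 7))
    if (length(unique(xs)) < k) {
      stop(sprintf("need at least %d distinct finite values for %d classes",
                   k, k))
    }
  }
  n <- length(xs)
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  cs0 <- c(0, cs); cs20 <- c(0, cs2)
  # D[m, j] = optimal cost of splitting xs[1..j] into m classes
  D <- matrix(Inf, k, n)
  idx <- matrix(0L, k, n)   # start index of the last class
  D[1, ] <- cs2 - cs^2 / seq_len(n)
  idx[1, ] <- 1L
  for (m in 2:k) {
    for (j in m:n) {
      i <- m:j                      # candidate starts of the last class
      s <- cs[j] - cs0[i]
      s2 <- cs2[j] - cs20[i]
      cost <- D[m - 1, i - 1] + s2 - s^2 / (j - i + 1)
      bi <- which.min(cost)
      D[m, j] <- cost[bi]
      idx[m, j] <- i[bi]
    }
  }
  starts <- integer(k)
  j <- n
  for (m in k:1) { starts[m] <- idx[m, j]; j <- starts[m] - 1L }
  ends <- c(starts[-1] - 1L, n)
  ranges <- cbind(min = xs[starts], max = xs[ends])
  breaks <- (xs[ends[-k]] + xs[starts[-1]]) / 2
  list(breaks = breaks, ssd = D[k, n], class_ranges = ranges)
}

#' Assign values to classes given break points
#'
#' Half-open intervals: class g covers `[breaks[g-1], breaks[g])`, with the
#' outer classes unbounded below/above.
#' @param x numeric vector or matrix.
#' @param breaks increasing break values (length k-1 for k classes).
#' @return integer classes 1..k, same shape as `x`.
#' @export
classify_breaks <- function(x, breaks) {
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("breaks must be strictly increasing")
  }
  out <- findInterval(x, breaks) + 1L
  out[!is.finite(x)] <- NA_integer_
  if (is.matrix(x)) out <- matrix(out, nrow(x), ncol(x))
  out
}
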