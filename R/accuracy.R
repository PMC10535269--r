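#' Build a confusion matrix (rows = mapped class, columns = reference class)
#'
#' Cell (r, c) accumulates the segment weights of segments mapped as class r
#' whose reference class is c. With unit weights (the default) this is the
#' ordinary count matrix; supplying per-segment areas gives area-weighted
#' metrics.
#'
#' @param reference,mapped equal-length label vectors.
#' @param weights optional positive per-segment weights (areas); default 1.
#' @param classes class ordering (default: union of labels in order of
#'   appearance in `reference` then `mapped`).
#' @return object of class `confusion_matrix`: list with `counts` (k x k),
#'   `classes`, `n` (total weight).
#' @export
confusion_matrix <- function(reference, mapped, weights = NULL,
                             classes = NULL) {
  reference <- as.character(reference); mapped <- as.character(mapped)
  if (length(reference) != length(mapped)) {
    stop("reference and mapped label vectors differ in length")
  }
  if (is.null(classes)) classes <- unique(c(reference, mapped))
  if (!all(reference %in% classes) || !all(mapped %in% classes)) {
    stop("label outside the declared class set")
  }
  if (is.null(weights)) weights <- rep(1, length(reference))
  if (length(weights) != length(reference) || any(weights <= 0)) {
    stop("weights must be positive and match the label length")
  }
  k <- length(classes)
  m <- matrix(0, k, k, dimnames = list(mapped = classes,
                                       reference = classes))
  for (i in seq_along(reference)) {
    m[mapped[i], reference[i]] <- m[mapped[i], reference[i]] + weights[i]
  }
  new_confusion_matrix(m)
}

#' Wrap an existing count matrix as a confusion matrix
#'
#' For re-entering published tables: rows are the mapped class, columns the
#' reference class.
#'
#' @param counts k x k non-negative matrix with identical row/column names.
#' @return a `confusion_matrix`.
#' @export
new_confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0))
  if (is.null(rownames(counts))) {
    rownames(counts) <- colnames(counts) <- paste0("class", seq_len(nrow(counts)))
  }
  stopifnot(identical(rownames(counts), colnames(counts)))
  structure(list(counts = counts, classes = rownames(counts),
                 n = sum(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = mapped, cols = reference\n")
  print(x$counts)
  invisible(x)
}

#' Overall accuracy (percent)
#' @param cm a `confusion_matrix`.
#' @return `100 * sum(diagonal) / total`.
#' @export
overall_accuracy <- function(cm) {
  if (cm$n <= 0) stop("undefined metric: empty confusion matrix")
  100 * sum(diag(cm$counts)) / cm$n
}

#' Producer's accuracy (recall) for one class, percent
#' @param cm a `confusion_matrix`.
#' @param class class label.
#' @return `100 * diagonal / reference-column total`.
#' @export
producer_accuracy <- function(cm, class) {
  j <- match(class, cm$classes)
  if (is.na(j)) stop("unknown class: ", class)
  tot <- sum(cm$counts[, j])
  if (tot <= 0) stop(sprintf("undefined metric: no reference segments of '%s'", class))
  100 * cm$counts[j, j] / tot
}

#' User's accuracy (precision) for one class, percent
#' @inheritParams producer_accuracy
#' @return `100 * diagonal / mapped-row total`.
#' @export
user_accuracy <- function(cm, class) {
  j <- match(class, cm$classes)
  if (is.na(j)) stop("unknown class: ", class)
  tot <- sum(cm$counts[j, ])
  if (tot <= 0) stop(sprintf("undefined metric: no mapped segments of '%s'", class))
  100 * cm$counts[j, j] / tot
}

#' Per-class F1 score (0-1 scale)
#'
#' Harmonic mean of precision (user's accuracy) and recall (producer's
#' accuracy). Returns 0 by convention when both are zero.
#' @inheritParams producer_accuracy
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(cm, class) {
  p <- user_accuracy(cm, class) / 100
  r <- producer_accuracy(cm, class) / 100
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Cohen's kappa coefficient
#'
#' Chance-corrected agreement: `(p0 - pe)/(1 - pe)` with `pe` the expected
#' agreement from the row/column marginals.
#' @param cm a `confusion_matrix`.
#' @return kappa in \[-1, 1\].
#' @export
kappa_coefficient <- function(cm) {
  if (cm$n <= 0) stop("undefined metric: empty confusion matrix")
  p0 <- sum(diag(cm$counts)) / cm$n
  pe <- sum(rowSums(cm$counts) * colSums(cm$counts)) / cm$n^2
  if (abs(1 - pe) < .Machine$double.eps) {
    stop("undefined metric: degenerate single-class matrix (pe = 1)")
  }
  (p0 - pe) / (1 - pe)
}

#' Full accuracy summary of a confusion matrix
#'
#' @param cm a `confusion_matrix`.
#' @param digits decimals for the rounded columns (percent metrics use
#'   half-up rounding to match conventional reporting).
#' @return list with `oa`, `kappa` and a per-class data.frame of PA/UA/F1.
#' @export
accuracy_summary <- function(cm, digits = 2) {
  half_up <- function(x, d) floor(x * 10^d + 0.5) / 10^d
  per <- data.frame(
    class = cm$classes,
    pa = vapply(cm$classes, function(cl) producer_accuracy(cm, cl), 0),
    ua = vapply(cm$classes, function(cl) user_accuracy(cm, cl), 0),
    f1 = vapply(cm$classes, function(cl) f1_score(cm, cl), 0),
    row.names = NULL)
  per$pa_rounded <- half_up(per$pa, digits)
  per$ua_rounded <- half_up(per$ua, digits)
  per$f1_rounded <- half_up(per$f1, digits)
  list(oa = overall_accuracy(cm), kappa = kappa_coefficient(cm),
       per_class = per)
}

#' Serialize a confusion matrix with margins to CSV
#'
#' Layout mirrors the conventional published table: cell counts, row totals
#' with UA, column totals with PA, and overall accuracy.
#' @param cm a `confusion_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  k <- length(cm$classes)
  s <- accuracy_summary(cm)
  body <- cbind(cm$counts, Total = rowSums(cm$counts),
                UA = s$per_class$ua_rounded, F1 = s$per_class$f1_rounded)
  tot <- c(colSums(cm$counts), cm$n, NA, NA)
  pa <- c(s$per_class$pa_rounded, NA, NA, NA)
  out <- rbind(body, Total = tot, `PA (%)` = pa)
  utils::write.csv(out, path, na = "")
  cat(sprintf("OA (%%),%0.2f\nKappa,%0.4f\n", s$oa, s$kappa),
      file = path, append = TRUE)
  invisible(path)
}
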