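#' Bhattacharyya distance between two univariate Gaussians
#'
#' `B = 1/8 * (mu_i - mu_j)^2 * 2/(s_i^2 + s_j^2) + 1/2 * log((s_i^2 + s_j^2)/(2 s_i s_j))`
#'
#' The first term penalizes mean separation relative to the pooled variance,
#' the second variance mismatch; `B = 0` iff the distributions are identical.
#'
#' @param mu_i,mu_j class means.
#' @param sigma_i,sigma_j class standard deviations (> 0).
#' @return non-negative Bhattacharyya distance.
#' @export
bhattacharyya_1d <- function(mu_i, sigma_i, mu_j, sigma_j) {
  if (any(sigma_i <= 0) || any(sigma_j <= 0)) {
    stop("degenerate distribution: standard deviations must be > 0")
  }
  v <- sigma_i^2 + sigma_j^2
  (mu_i - mu_j)^2 / (4 * v) + 0.5 * log(v / (2 * sigma_i * sigma_j))
}

#' Multivariate Gaussian Bhattacharyya distance
#'
#' `B = 1/8 d' S^-1 d + 1/2 log(det(S) / sqrt(det(S_i) det(S_j)))` with
#' `S = (S_i + S_j)/2` the pooled covariance and `d` the mean difference.
#' A ridge of `reg * trace/d` is added to each covariance diagonal before
#' inversion to guard against singular small-sample covariances.
#'
#' @param mu_i,mu_j mean vectors.
#' @param S_i,S_j covariance matrices.
#' @param reg relative ridge regularization (default 1e-8).
#' @return non-negative Bhattacharyya distance.
#' @export
bhattacharyya_mv <- function(mu_i, S_i, mu_j, S_j, reg = 1e-8) {
  d <- length(mu_i)
  stopifnot(length(mu_j) == d, all(dim(S_i) == d), all(dim(S_j) == d))
  ridge <- function(S) S + diag(reg * sum(diag(S)) / d, d)
  S_i <- ridge(S_i); S_j <- ridge(S_j)
  S <- (S_i + S_j) / 2
  dm <- mu_i - mu_j
  ld <- function(M) determinant(M, logarithm = TRUE)$modulus
  as.numeric(dm %*% solve(S, dm)) / 8 +
    0.5 * as.numeric(ld(S) - 0.5 * (ld(S_i) + ld(S_j)))
}

#' Per-class Gaussian feature summary
#'
#' @param features numeric matrix, one row per sample.
#' @param labels class labels aligned with rows.
#' @return named list of summaries (`mu`, `cov`, `sd`, `n`) per class.
#' @export
class_summaries <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  out <- list()
  for (cl in unique(labels)) {
    x <- features[labels == cl, , drop = FALSE]
    if (nrow(x) < 2) {
      stop(sprintf("class '%s' has fewer than 2 samples", cl))
    }
    out[[cl]] <- list(mu = colMeans(x), cov = stats::cov(x),
                      sd = apply(x, 2, stats::sd), n = nrow(x),
                      features = colnames(features))
  }
  out
}

#' Jeffries-Matusita distance between two class summaries
#'
#' `J = 2 (1 - exp(-B))`, bounded in \[0, 2\]; values of 1.8 and above are
#' conventionally read as excellent separability. `multivariate` mode uses
#' the full Gaussian Bhattacharyya with pooled covariance; `univariate-mean`
#' averages the per-feature 1-D Bhattacharyya distances before the transform
#' (a diagnostic mode ignoring feature correlation).
#'
#' @param summary_i,summary_j entries from [class_summaries()].
#' @param mode `"multivariate"` (default) or `"univariate-mean"`.
#' @return J-M distance in \[0, 2\].
#' @export
jm_distance <- function(summary_i, summary_j,
                        mode = c("multivariate", "univariate-mean")) {
  mode <- match.arg(mode)
  if (!identical(summary_i$features, summary_j$features)) {
    stop("feature-set mismatch between class summaries")
  }
  B <- if (mode == "multivariate") {
    bhattacharyya_mv(summary_i$mu, summary_i$cov, summary_j$mu, summary_j$cov)
  } else {
    mean(bhattacharyya_1d(summary_i$mu, summary_i$sd,
                          summary_j$mu, summary_j$sd))
  }
  jm_from_b(B)
}

#' Transform a Bhattacharyya distance to the J-M scale
#' @param B non-negative Bhattacharyya distance.
#' @return `2 * (1 - exp(-B))`.
#' @export
jm_from_b <- function(B) 2 * (1 - exp(-B))

#' Separability report over dates, band combinations and class pairs
#'
#' For every date and registry combination, fits Gaussian class summaries to
#' the extracted feature table and computes the J-M distance between the
#' target class and every other class. Cells with a J-M of at least 1.8 are
#' flagged as optimal separability.
#'
#' @param scenes named list of `grid_stack` scenes keyed by date.
#' @param samples data.frame from [sample_points()].
#' @param combos list of band combinations (see [band_combinations()]).
#' @param target_class class name of interest.
#' @param mode passed to [jm_distance()].
#' @return data.frame `date, combination, class_a, class_b, jm, optimal_flag`.
#' @export
separability_report <- function(scenes, samples, combos,
                                target_class = "e_ulmoides",
                                mode = "multivariate") {
  rows <- list()
  others <- setdiff(levels(samples$class), target_class)
  for (date in names(scenes)) {
    for (cb in combos) {
      ft <- build_feature_table(scenes[[date]], samples, cb)
      keep <- stats::complete.cases(ft$features)
      sm <- class_summaries(ft$features[keep, , drop = FALSE],
                            samples$class[keep])
      for (oc in others) {
        if (is.null(sm[[target_class]]) || is.null(sm[[oc]])) {
          rows[[length(rows) + 1]] <- data.frame(
            date = date, combination = cb$id, class_a = target_class,
            class_b = oc, jm = NA_real_, optimal_flag = NA,
            note = "class absent on this date")
          next
        }
        j <- jm_distance(sm[[target_class]], sm[[oc]], mode = mode)
        rows[[length(rows) + 1]] <- data.frame(
          date = date, combination = cb$id, class_a = target_class,
          class_b = oc, jm = j, optimal_flag = j >= 1.8, note = "")
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the optimal acquisition window from a separability report
#'
#' Returns the date maximizing the J-M distance for the designated hardest
#' class pair (by default the largest full-feature combination present).
#' Ties go to the earliest date and are recorded in the `tie` attribute.
#'
#' @param report output of [separability_report()].
#' @param class_b the confusable class defining the hardest pair.
#' @param combination registry id to read (default: last one in the report).
#' @return the selected date string; attributes `jm` and `tie`.
#' @export
select_optimal_window <- function(report, class_b = "other_forests",
                                  combination = NULL) {
  if (nrow(report) == 0) stop("empty separability report")
  if (is.null(combination)) combination <- utils::tail(report$combination, 1)
  sub <- report[report$combination == combination &
                  report$class_b == class_b & !is.na(report$jm), ]
  if (nrow(sub) == 0) stop("no report entries for the requested pair")
  dates <- sub$date[order(sub$date)]
  jms <- sub$jm[order(sub$date)]
  best <- which(jms == max(jms))
  sel <- dates[best[1]]
  attr(sel, "jm") <- max(jms)
  attr(sel, "tie") <- length(best) > 1
  sel
}
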