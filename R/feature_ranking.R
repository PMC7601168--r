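# Fisher linear-discriminant feature ranking. Each texture feature receives a
# scalar Mahalanobis separation between the standard and anomalous classes;
# large values mean little overlap, and the top-ranked features feed the KNN
# classifier.

#' Pooled covariance of two classes
#'
#' Sample-size-weighted pool `C = (n1 C1 + n2 C2) / (n1 + n2)` of the per-class
#' (population-form) covariance matrices.
#'
#' @param C1,C2 Covariance matrices (or scalars) of identical shape.
#' @param n1,n2 Positive class sample counts.
#' @return The pooled covariance, same shape as `C1`.
#' @export
pooled_covariance <- function(C1, C2, n1, n2) {
  C1 <- as.matrix(C1); C2 <- as.matrix(C2)
  if (!identical(dim(C1), dim(C2))) stop("covariance shapes differ")
  if (n1 <= 0 || n2 <= 0) stop("class counts must be positive")
  (n1 * C1 + n2 * C2) / (n1 + n2)
}

# population covariance (divisor n, matching the pooled form above)
pop_cov <- function(x) {
  x <- as.matrix(x)
  xc <- sweep(x, 2, colMeans(x))
  crossprod(xc) / nrow(x)
}

#' Fisher separation of one feature between two classes
#'
#' The univariate Mahalanobis separation
#' `delta2 = (mu1 - mu2)^2 / C_pooled`, with the pooled variance from
#' [pooled_covariance()] on the population per-class variances. It is
#' invariant to shifting and (positively) rescaling the feature. A pooled
#' variance of zero yields 0 when the means agree and `Inf` (with a warning)
#' when they differ — a degenerate perfectly-separating feature.
#'
#' @param x1,x2 Numeric samples of the feature in each class (each length
#'   >= 2).
#' @return The separation score (non-negative, possibly `Inf`).
#' @export
fisher_separation <- function(x1, x2) {
  if (length(x1) < 2 || length(x2) < 2) stop("each class needs >= 2 samples")
  mu1 <- mean(x1); mu2 <- mean(x2)
  C <- pooled_covariance(mean((x1 - mu1)^2), mean((x2 - mu2)^2),
                         length(x1), length(x2))[1, 1]
  if (C == 0) {
    if (mu1 == mu2) return(0)
    warning("zero pooled variance with unequal means: infinite separation")
    return(Inf)
  }
  (mu1 - mu2)^2 / C
}

#' Multivariate Fisher discriminant model
#'
#' Fits the two-class linear discriminant: coefficient vector
#' `beta = C^-1 (mu1 - mu2)` with `C` the pooled (population) covariance, and
#' Mahalanobis separation `delta2 = beta' (mu1 - mu2)`. On a single feature
#' `delta2` reduces to [fisher_separation()]; the model is exported mainly so
#' that reduction can be verified and the discriminant score `z = beta' x`
#' inspected.
#'
#' @param X1,X2 Per-class numeric matrices (rows = samples).
#' @return List with `mu1`, `mu2`, `C1`, `C2`, `n1`, `n2`, `C`, `beta`,
#'   `delta2`, and `score(x)` computing `z` for new rows.
#' @export
lda_model <- function(X1, X2) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (nrow(X1) < 2 || nrow(X2) < 2) stop("each class needs >= 2 samples")
  mu1 <- colMeans(X1); mu2 <- colMeans(X2)
  C1 <- pop_cov(X1); C2 <- pop_cov(X2)
  C <- pooled_covariance(C1, C2, nrow(X1), nrow(X2))
  beta <- solve(C, mu1 - mu2)
  delta2 <- drop(crossprod(beta, mu1 - mu2))
  list(mu1 = mu1, mu2 = mu2, C1 = C1, C2 = C2,
       n1 = nrow(X1), n2 = nrow(X2), C = C, beta = beta, delta2 = delta2,
       score = function(x) {
         X <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
         drop(X %*% beta)
       })
}

#' Rank features by class separation
#'
#' Scores every feature with [fisher_separation()] between the `standard`
#' and `anomalous` classes of a feature table and sorts descending. Ties are
#' broken by the original feature order (column order of the table, i.e.
#' f1 first). Precomputed scores can be ranked directly by passing a named
#' numeric vector.
#'
#' @param table A feature table from [extract_features()] (needs a `label`
#'   column), or a named numeric vector of precomputed scores.
#' @param features Which feature columns to rank (default: all Haralick
#'   columns present).
#' @return A `feature_ranking` data frame: `rank`, `feature`, `score`,
#'   score-descending.
#' @export
rank_features <- function(table, features = NULL) {
  if (is.numeric(table) && !is.null(names(table))) {
    return(rank_scores(table))
  }
  if (is.null(features)) {
    features <- intersect(c(haralick_feature_names, haralick_extra_names),
                          names(table))
  }
  lab <- table$label
  if (length(unique(lab)) < 2) {
    stop("feature ranking needs both classes present")
  }
  a <- lab == "anomalous"
  scores <- vapply(features, function(f) {
    fisher_separation(table[[f]][a], table[[f]][!a])
  }, numeric(1))
  rank_scores(scores)
}

rank_scores <- function(scores) {
  ord <- order(-scores, seq_along(scores))
  out <- data.frame(rank = seq_along(scores),
                    feature = names(scores)[ord],
                    score = unname(scores[ord]),
                    stringsAsFactors = FALSE)
  class(out) <- c("feature_ranking", class(out))
  out
}

#' Select the top-ranked features
#'
#' @param ranking A `feature_ranking` from [rank_features()].
#' @param k Number of features to keep, `1 <= k <= nrow(ranking)`;
#'   default 8, the best-performing depth of the feature-addition sweep.
#' @return Character vector of the top `k` feature names, in rank order.
#' @export
select_top <- function(ranking, k = 8L) {
  if (k < 1 || k > nrow(ranking)) stop("`k` out of range")
  ranking$feature[seq_len(k)]
}

#' Write a ranking to CSV
#' @param ranking A `feature_ranking`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking_csv <- function(ranking, path) {
  out <- ranking
  out$feature_name <- feature_display_names(out$feature)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
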