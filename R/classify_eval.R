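# KNN classification of super-pixels on the selected texture features, the
# grouped cross-validation protocol (train on the other images of the test
# image's group), and the confusion-matrix metrics.

#' Fit a k-nearest-neighbour model
#'
#' Stores the training vectors after z-score standardisation (mean/scale
#' estimated on the training data only — the ten texture features span
#' wildly different scales, so unscaled Euclidean distance would be dominated
#' by a single feature). Features with zero training variance are dropped
#' with a warning.
#'
#' @param table Feature table with a `label` column.
#' @param features Feature columns to use.
#' @param k Neighbour count, `1 <= k <= nrow(table)`; default 1.
#' @return A `knn_model` list: `X` (standardised matrix), `labels`, `k`,
#'   `center`, `scale`, `features`, `metric`.
#' @export
knn_fit <- function(table, features = haralick_feature_names, k = 1L) {
  if (nrow(table) == 0) stop("empty training table")
  if (k < 1 || k > nrow(table)) stop("`k` must be in [1, nrow(table)]")
  X <- as.matrix(table[, features, drop = FALSE])
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  drop_f <- scl == 0 | !is.finite(scl)
  if (any(drop_f)) {
    warning("dropping zero-variance feature(s): ",
            paste(features[drop_f], collapse = ", "))
    features <- features[!drop_f]
    if (length(features) == 0) stop("no usable features left")
    X <- X[, !drop_f, drop = FALSE]
    ctr <- ctr[!drop_f]; scl <- scl[!drop_f]
  }
  X <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  structure(list(X = X, labels = table$label, k = as.integer(k),
                 center = ctr, scale = scl, features = features,
                 metric = "euclidean"),
            class = "knn_model")
}

#' Predict classes with a fitted KNN model
#'
#' Majority vote among the `k` nearest training vectors under Euclidean
#' distance in the standardised feature space. Vote ties are broken toward
#' `anomalous`: missing a lesion is clinically costlier than flagging a
#' normal region.
#'
#' @param model A `knn_model` from [knn_fit()].
#' @param query Numeric vector (one case) or matrix/data frame of cases with
#'   the model's features.
#' @return Character vector of predicted labels.
#' @export
knn_predict <- function(model, query) {
  if (is.data.frame(query)) {
    query <- as.matrix(query[, model$features, drop = FALSE])
  } else if (is.null(dim(query))) {
    if (length(query) != length(model$features)) {
      stop("query dimension does not match model features")
    }
    query <- matrix(query, nrow = 1)
  }
  if (ncol(query) != length(model$features)) {
    stop("query dimension does not match model features")
  }
  Q <- sweep(sweep(query, 2, model$center), 2, model$scale, `/`)
  # squared distances, training x query
  d2 <- outer(rowSums(model$X^2), rowSums(Q^2), `+`) - 2 * model$X %*% t(Q)
  apply(d2, 2, function(d) {
    nb <- order(d)[seq_len(model$k)]
    votes <- sum(model$labels[nb] == "anomalous")
    if (2 * votes >= model$k) "anomalous" else "standard"
  })
}

#' Confusion counts and metrics
#'
#' Computes TP/FP/TN/FN with `anomalous` as the positive class, and
#' sensitivity `TP / (TP + FN)`, specificity `TN / (TN + FP)` and accuracy
#' `(TP + TN) / (TP + TN + FP + FN)`. Metrics with zero denominators are
#' undefined and returned as `NA`.
#'
#' @param truth,prediction Character vectors of labels.
#' @return A `confusion` list: `TP`, `FP`, `TN`, `FN` and the three metrics.
#' @export
confusion_counts <- function(truth, prediction) {
  stopifnot(length(truth) == length(prediction))
  tp <- sum(truth == "anomalous" & prediction == "anomalous")
  fp <- sum(truth == "standard" & prediction == "anomalous")
  tn <- sum(truth == "standard" & prediction == "standard")
  fn <- sum(truth == "anomalous" & prediction == "standard")
  c(list(TP = tp, FP = fp, TN = tn, FN = fn),
    classification_metrics(tp, fp, tn, fn))
}

#' @rdname confusion_counts
#' @param TP,FP,TN,FN Non-negative confusion counts.
#' @export
classification_metrics <- function(TP, FP, TN, FN) {
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  list(sensitivity = safe_div(TP, TP + FN),
       specificity = safe_div(TN, TN + FP),
       accuracy = safe_div(TP + TN, TP + TN + FP + FN))
}

#' Grouped cross-validation of the super-pixel classifier
#'
#' Within each group, one fold per image: the classifier is trained on the
#' group's other images and tested on the held-out image, so every image
#' passes through the testing phase exactly once and a test image's
#' super-pixels never appear in its own training set. Per-fold metrics are
#' aggregated as mean and standard deviation across folds (undefined
#' per-fold metrics are excluded from the aggregate), and pooled
#' (micro-averaged) metrics over the summed confusion counts are also
#' reported.
#'
#' @param table Combined feature table with `image_id`, `group_id`, `label`.
#' @param features Feature columns used for classification.
#' @param k Neighbour count (default 1).
#' @param global_training Train on all images outside the test image
#'   regardless of group (default `FALSE`: train within the test image's own
#'   group).
#' @return A `fold_report`: `folds` data frame (one row per fold with counts
#'   and metrics), `summary` (mean/sd per metric), `pooled` (micro-averaged
#'   metrics), and `predictions` (per-super-pixel truth/prediction).
#' @export
grouped_cv <- function(table, features = haralick_feature_names, k = 1L,
                       global_training = FALSE) {
  imgs <- unique(table[, c("image_id", "group_id")])
  grp_sizes <- table(imgs$group_id)
  if (any(grp_sizes < 2)) {
    stop("every group needs >= 2 images for grouped cross-validation")
  }
  fold_rows <- list()
  preds <- list()
  for (i in seq_len(nrow(imgs))) {
    img <- imgs$image_id[i]; grp <- imgs$group_id[i]
    test <- table[table$image_id == img, , drop = FALSE]
    train <- if (global_training) {
      table[table$image_id != img, , drop = FALSE]
    } else {
      table[table$group_id == grp & table$image_id != img, , drop = FALSE]
    }
    if (length(unique(train$label)) < 2) {
      warning(sprintf("fold %s: training data single-class; skipped", img))
      next
    }
    model <- suppressWarnings(knn_fit(train, features, k = min(k, nrow(train))))
    pred <- knn_predict(model, test)
    cc <- confusion_counts(test$label, pred)
    fold_rows[[length(fold_rows) + 1L]] <- data.frame(
      group_id = grp, image_id = img,
      TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN,
      sensitivity = cc$sensitivity, specificity = cc$specificity,
      accuracy = cc$accuracy, stringsAsFactors = FALSE)
    preds[[length(preds) + 1L]] <- data.frame(
      image_id = img, window_row = test$window_row,
      window_col = test$window_col, truth = test$label, prediction = pred,
      stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, fold_rows)
  metrics <- c("sensitivity", "specificity", "accuracy")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(folds[[m]], na.rm = TRUE), 0),
    sd = vapply(metrics, function(m) stats::sd(folds[[m]], na.rm = TRUE), 0),
    row.names = NULL)
  pooled <- classification_metrics(sum(folds$TP), sum(folds$FP),
                                   sum(folds$TN), sum(folds$FN))
  structure(list(folds = folds, summary = summary, pooled = pooled,
                 predictions = do.call(rbind, preds),
                 features = features, k = k),
            class = "fold_report")
}

#' @export
print.fold_report <- function(x, ...) {
  cat(sprintf("<fold_report: %d folds, k = %d, %d features>\n",
              nrow(x$folds), x$k, length(x$features)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %5.1f%% +/- %.1f%%\n",
                s$metric[i], 100 * s$mean[i], 100 * s$sd[i]))
  }
  invisible(x)
}

#' Serialize a fold report
#' @param report A `fold_report`.
#' @param path Output path (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(folds = report$folds, summary = report$summary,
           pooled = report$pooled, features = report$features, k = report$k),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.csv(report$folds, path, row.names = FALSE)
  }
  invisible(path)
}
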