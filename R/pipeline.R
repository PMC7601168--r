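# End-to-end orchestration: grayscale -> Deriche-Canny -> circular Hough ->
# device removal -> quadtree -> labelling -> co-occurrence features ->
# Fisher ranking -> grouped-CV KNN.

#' Default pipeline configuration
#'
#' One flat list of key-value pairs covering every tunable stage decision.
#' Keys are namespaced by stage (`edge.*`, `cht.*`, `quadtree.*`, `glcm.*`,
#' `rank.*`, `knn.*`).
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    edge.alpha = 1.0,
    edge.low_quantile = 0.70,
    edge.high_quantile = 0.90,
    cht.r_min_frac = 0.30,
    cht.r_max_frac = 0.48,
    cht.r_step = 2,
    cht.score_floor = 0.35,
    quadtree.leaf_size = 64,
    glcm.offset_dr = 0,
    glcm.offset_dc = 1,
    glcm.symmetric = TRUE,
    glcm.extended = FALSE,
    rank.top_k = 8,
    knn.k = 1,
    knn.global_training = FALSE
  )
}

#' Read / write a flat `key = value` configuration file
#'
#' Unknown keys are rejected; values are coerced to the type of the default.
#'
#' @param path File path.
#' @return For `read_config`, a full configuration list (defaults overlaid
#'   with the file's entries).
#' @export
read_config <- function(path) {
  cfg <- default_config()
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (is.null(cfg[[key]])) stop("unknown config key: ", key)
    cfg[[key]] <- if (is.logical(cfg[[key]])) as.logical(val) else as.numeric(val)
  }
  cfg
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, as.character, "")), path)
  invisible(path)
}

#' Preprocess one image: edges, device removal, labelled super-pixel grid
#'
#' Runs the device-presence branch: Deriche gradient, Canny edge map,
#' circular Hough transform; if a circle clears the score floor the image
#' (and mask) are cropped to the aperture, otherwise they pass through
#' unchanged. The result is divided into super-pixels and labelled against
#' the mask when one is supplied.
#'
#' @param image A [gray_image()].
#' @param mask Optional `label_mask` aligned with `image`.
#' @param config Configuration list (see [default_config()]).
#' @return List with `image` (possibly cropped), `mask` (aligned), `grid`
#'   (labelled when a mask was given), `circle` (accepted hit or `NULL`) and
#'   `hits` (all Hough hits).
#' @export
preprocess_image <- function(image, mask = NULL, config = default_config()) {
  grad <- deriche_gradient(image, alpha = config$edge.alpha)
  edges <- canny_edges(grad, quantiles = c(config$edge.low_quantile,
                                           config$edge.high_quantile))
  side <- min(dim(image))
  hits <- hough_circles(edges,
                        r_min = config$cht.r_min_frac * side,
                        r_max = config$cht.r_max_frac * side,
                        r_step = config$cht.r_step)
  out <- remove_device(image, hits, score_floor = config$cht.score_floor)
  circle <- attr(out, "circle")
  if (!is.null(mask) && !is.null(circle)) mask <- crop_mask_like(mask, out)
  grid <- quadtree_divide(out, leaf_size = config$quadtree.leaf_size)
  if (!is.null(mask)) grid <- label_superpixels(grid, mask)
  list(image = out, mask = mask, grid = grid, circle = circle, hits = hits)
}

#' Build the combined feature table of a manifest
#'
#' Preprocesses every manifest entry and extracts per-super-pixel texture
#' features. Entries whose mask is missing are skipped with a warning.
#'
#' @param manifest Data frame from [read_manifest()] (or a manifest path).
#' @param config Configuration list.
#' @param verbose Log the device-present / device-absent decision per image.
#' @return Combined feature table (one row per valid labelled super-pixel).
#' @export
manifest_features <- function(manifest, config = default_config(),
                              verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  tables <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    if (!file.exists(row$mask_path)) {
      warning("mask missing for ", row$image_id, "; image skipped")
      next
    }
    image <- load_image(row$image_path)
    mask <- load_mask(row$mask_path, image)
    pre <- preprocess_image(image, mask, config)
    if (verbose) {
      message(sprintf("%s: %s", row$image_id,
                      if (is.null(pre$circle)) "device absent (pass-through)"
                      else sprintf("device circle r=%.0f at (%.0f, %.0f), score %.2f",
                                   pre$circle$radius, pre$circle$center_row,
                                   pre$circle$center_col, pre$circle$score)))
    }
    tables[[length(tables) + 1L]] <- extract_features(
      pre$image, pre$grid, image_id = row$image_id, group_id = row$group_id,
      offset = c(config$glcm.offset_dr, config$glcm.offset_dc),
      symmetric = config$glcm.symmetric, extended = config$glcm.extended)
  }
  if (length(tables) == 0L) {
    warning("no usable images in manifest")
    return(NULL)
  }
  do.call(rbind, tables)
}

#' Train and evaluate over a manifest
#'
#' Full training phase: feature extraction over all images, Fisher-LDA
#' feature ranking, then grouped cross-validation — either at the configured
#' top-`k` feature depth only, or sweeping depths `1..n` to show how
#' performance evolves as ranked features are added.
#'
#' @param manifest Data frame or manifest path.
#' @param config Configuration list.
#' @param sweep Evaluate every feature-depth `1..n` (default `FALSE`: only
#'   `rank.top_k`).
#' @param verbose Passed to [manifest_features()].
#' @return List with `table`, `ranking`, `reports` (named by feature depth)
#'   and `config`.
#' @export
run_training <- function(manifest, config = default_config(), sweep = FALSE,
                         verbose = FALSE) {
  table <- manifest_features(manifest, config, verbose = verbose)
  ranking <- rank_features(table)
  depths <- if (sweep) seq_len(nrow(ranking)) else config$rank.top_k
  reports <- lapply(depths, function(k) {
    grouped_cv(table, features = select_top(ranking, k), k = config$knn.k,
               global_training = config$knn.global_training)
  })
  names(reports) <- paste0("top", depths)
  list(table = table, ranking = ranking, reports = reports, config = config)
}

#' Classify one test image against a training feature table
#'
#' Testing phase: the test image is preprocessed and its super-pixels
#' classified by a KNN model fitted on the supplied training table with the
#' supplied feature subset; per-super-pixel predictions and confusion
#' metrics against the image's own mask are returned.
#'
#' @param image A [gray_image()] (or image path).
#' @param mask A `label_mask` (or mask path).
#' @param train_table Feature table to train on.
#' @param features Feature subset (e.g. from [select_top()]).
#' @param config Configuration list.
#' @return List with `predictions` data frame, `confusion`, `grid`, and the
#'   preprocessed `image`.
#' @export
run_test <- function(image, mask, train_table,
                     features = haralick_feature_names,
                     config = default_config()) {
  if (is.character(image)) image <- load_image(image)
  if (is.character(mask)) mask <- load_mask(mask, image)
  pre <- preprocess_image(image, mask, config)
  test_tab <- extract_features(
    pre$image, pre$grid, image_id = "test", group_id = 0L,
    offset = c(config$glcm.offset_dr, config$glcm.offset_dc),
    symmetric = config$glcm.symmetric, extended = config$glcm.extended)
  model <- knn_fit(train_table, features, k = config$knn.k)
  pred <- knn_predict(model, test_tab)
  cc <- confusion_counts(test_tab$label, pred)
  list(predictions = data.frame(window_row = test_tab$window_row,
                                window_col = test_tab$window_col,
                                truth = test_tab$label, prediction = pred,
                                stringsAsFactors = FALSE),
       confusion = cc, grid = pre$grid, image = pre$image)
}

#' Render a label/prediction overlay as an RGB PNG
#'
#' Anomalous windows are tinted red (truth) or outlined by tint
#' (predictions when given), mirroring the review overlay a clinician would
#' inspect before biopsy.
#'
#' @param image A [gray_image()].
#' @param grid A labelled `superpixel_grid`.
#' @param predictions Optional predictions data frame (`window_row`,
#'   `window_col`, `prediction`).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
render_overlay <- function(image, grid, predictions = NULL, path) {
  g <- unclass(image) / 255
  rgb <- array(rep(g, 3), c(dim(g), 3))
  tint <- function(wr, wc, channel) {
    for (i in seq_along(wr)) {
      rs <- (wr[i] - 1L) * grid$leaf_size + seq_len(grid$leaf_size)
      cs <- (wc[i] - 1L) * grid$leaf_size + seq_len(grid$leaf_size)
      rs <- rs[rs <= nrow(g)]; cs <- cs[cs <= ncol(g)]
      rgb[rs, cs, channel] <<- 0.5 * rgb[rs, cs, channel] + 0.5
    }
  }
  wdf <- grid$windows
  anom <- wdf[wdf$label == "anomalous", ]
  tint(anom$grid_row, anom$grid_col, 1L)
  if (!is.null(predictions)) {
    p <- predictions[predictions$prediction == "anomalous", ]
    tint(p$window_row, p$window_col, 3L)
  }
  png::writePNG(rgb, path)
  invisible(path)
}
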