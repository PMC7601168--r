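# Gray-level co-occurrence matrix at full 8-bit depth (256 x 256, no
# requantisation) and the ten Haralick texture features used to describe each
# super-pixel. Keeping all 256 levels preserves the subtle textural
# differences between lesional and normal mucosa that coarser quantisation
# would average away.

#' Gray-level co-occurrence matrix of a window
#'
#' Counts co-occurring intensity pairs `(I(r, c), I(r + dr, c + dc))` over
#' all in-bounds positions and normalises to a joint probability matrix
#' `p(i, j)` over the full 256 gray levels. With `symmetric = TRUE`
#' (the conventional choice, and the default) each pair is also counted in
#' reverse order, making `p` symmetric and the row/column marginals equal.
#'
#' @param window A [gray_image()] (any size compatible with `offset`).
#' @param offset Integer displacement `c(dr, dc)`; the default `c(0, 1)` is
#'   0 degrees at distance 1. Other angles (45/90/135 degrees) are supported
#'   via e.g. `c(-1, 1)`, `c(1, 0)`, `c(1, 1)`.
#' @param symmetric Count each pair in both orders (default `TRUE`).
#' @return A `coocc_matrix`: list with `p` (256 x 256), `Ng`, `offset`,
#'   marginals `px`, `py`, diagonal sums `p_sum` (indices `0..510` of
#'   `i + j`), cross sums `p_diff` (indices `0..255` of `|i - j|`), and
#'   moments `mu_x`, `mu_y`, `sd_x`, `sd_y`.
#' @export
cooccurrence <- function(window, offset = c(0L, 1L), symmetric = TRUE) {
  m <- unclass(window)
  dr <- as.integer(offset[1]); dc <- as.integer(offset[2])
  h <- nrow(m); w <- ncol(m)
  rs <- seq_len(h - abs(dr))
  cs <- seq_len(w - abs(dc))
  if (length(rs) == 0L || length(cs) == 0L) {
    stop("window too small for the requested offset")
  }
  if (dr >= 0) { r1 <- rs; r2 <- rs + dr } else { r1 <- rs - dr; r2 <- rs }
  if (dc >= 0) { c1 <- cs; c2 <- cs + dc } else { c1 <- cs - dc; c2 <- cs }
  i <- as.vector(m[r1, c1, drop = FALSE])
  j <- as.vector(m[r2, c2, drop = FALSE])
  counts <- tabulate(i * 256L + j + 1L, nbins = 256L * 256L)
  p <- matrix(counts, 256L, 256L, byrow = TRUE)  # row = i, col = j
  if (symmetric) p <- p + t(p)
  p <- p / sum(p)
  coocc_from_p(p, offset)
}

# Derive marginals, diagonal/cross sums and moments from a normalised p.
coocc_from_p <- function(p, offset = c(0L, 1L)) {
  Ng <- nrow(p)
  lev <- 0:(Ng - 1)
  px <- rowSums(p)
  py <- colSums(p)
  mu_x <- sum(lev * px)
  mu_y <- sum(lev * py)
  sd_x <- sqrt(sum((lev - mu_x)^2 * px))
  sd_y <- sqrt(sum((lev - mu_y)^2 * py))
  idx_sum <- outer(lev, lev, `+`)          # i + j in 0..2Ng-2
  idx_diff <- abs(outer(lev, lev, `-`))    # |i - j| in 0..Ng-1
  grp_sum <- function(idx, n) {
    out <- numeric(n)
    agg <- rowsum(as.vector(p), as.vector(idx))
    out[as.integer(rownames(agg)) + 1] <- agg[, 1]
    out
  }
  p_sum_full <- grp_sum(idx_sum, 2 * Ng - 1)
  p_diff_full <- grp_sum(idx_diff, Ng)
  structure(list(p = p, Ng = Ng, offset = offset,
                 px = px, py = py,
                 p_sum = p_sum_full, p_diff = p_diff_full,
                 mu_x = mu_x, mu_y = mu_y, sd_x = sd_x, sd_y = sd_y),
            class = "coocc_matrix")
}

#' @export
print.coocc_matrix <- function(x, ...) {
  cat(sprintf("<coocc_matrix %d x %d, offset (%d, %d), %d nonzero entries>\n",
              x$Ng, x$Ng, x$offset[1], x$offset[2], sum(x$p > 0)))
  invisible(x)
}

haralick_feature_names <- c(
  "asm", "contrast", "correlation", "variance", "idm",
  "sum_average", "sum_variance", "sum_entropy", "entropy", "diff_variance"
)

haralick_extra_names <- c("diff_entropy", "info_correlation")

#' Display names for the texture features
#' @param features Character vector of internal feature names.
#' @return Character vector of human-readable names.
#' @export
feature_display_names <- function(features = haralick_feature_names) {
  map <- c(
    asm = "Angular second moment", contrast = "Contrast",
    correlation = "Correlation", variance = "Variance",
    idm = "Inverse difference moment", sum_average = "Sum average",
    sum_variance = "Sum variance", sum_entropy = "Sum entropy",
    entropy = "Entropy", diff_variance = "Difference variance",
    diff_entropy = "Difference entropy",
    info_correlation = "Measure of co-relation"
  )
  unname(map[features])
}

#' Haralick texture features of a co-occurrence matrix
#'
#' Computes the ten features: angular second moment (energy), contrast,
#' correlation, variance (sum of squares), inverse difference moment, sum
#' average, sum variance, sum entropy, entropy and difference variance. With
#' `extended = TRUE`, difference entropy and the first information measure of
#' correlation are appended. Natural logarithms are used with the convention
#' `0 * log 0 = 0`. For a constant window the gray-level standard deviations
#' vanish and correlation is undefined; it is reported as 0 and the result
#' carries attribute `degenerate = TRUE`.
#'
#' All formulas follow Haralick's standard definitions: contrast weights
#' `p_diff` by `n^2` over `|i - j| = n`; the inverse difference moment weight
#' is `1 / (1 + (i - j)^2)`; the correlation denominator is `sd_x * sd_y`;
#' sum variance is taken about the sum entropy; sum entropy carries the minus
#' sign so that it is non-negative; variance is taken about the marginal mean
#' (the two marginal means coincide under symmetric accumulation).
#'
#' @param m A `coocc_matrix` from [cooccurrence()].
#' @param extended Also compute difference entropy and the information
#'   measure of correlation (default `FALSE`).
#' @return Named numeric vector of features.
#' @export
haralick <- function(m, extended = FALSE) {
  stopifnot(inherits(m, "coocc_matrix"))
  p <- m$p
  Ng <- m$Ng
  lev <- 0:(Ng - 1)
  k_sum <- 0:(2 * Ng - 2)
  k_diff <- 0:(Ng - 1)
  xlogx <- function(v) ifelse(v > 0, v * log(v), 0)

  f1 <- sum(p^2)
  f2 <- sum(k_diff^2 * m$p_diff)
  degenerate <- (m$sd_x * m$sd_y) == 0
  f3 <- if (degenerate) 0 else {
    (sum(outer(lev, lev) * p) - m$mu_x * m$mu_y) / (m$sd_x * m$sd_y)
  }
  f4 <- sum((lev - m$mu_x)^2 * m$px)          # == sum_ij (i - mu)^2 p(i,j)
  f5 <- sum(p / (1 + outer(lev, lev, `-`)^2))
  f6 <- sum(k_sum * m$p_sum)
  f8 <- -sum(xlogx(m$p_sum))
  f7 <- sum((k_sum - f8)^2 * m$p_sum)
  f9 <- -sum(xlogx(p))
  mu_d <- sum(k_diff * m$p_diff)
  f10 <- sum((k_diff - mu_d)^2 * m$p_diff)
  out <- c(asm = f1, contrast = f2, correlation = f3, variance = f4, idm = f5,
           sum_average = f6, sum_variance = f7, sum_entropy = f8,
           entropy = f9, diff_variance = f10)
  if (extended) {
    f11 <- -sum(xlogx(m$p_diff))
    hxy <- f9
    hx <- -sum(xlogx(m$px))
    hy <- -sum(xlogx(m$py))
    hxy1 <- -sum(xlogx_pair(p, outer(m$px, m$py)))
    denom <- max(hx, hy)
    f12 <- if (denom > 0) (hxy - hxy1) / denom else 0
    out <- c(out, diff_entropy = f11, info_correlation = f12)
  }
  attr(out, "degenerate") <- degenerate
  out
}

# sum of p * log(q) terms with 0 * log 0 := 0 (only where p > 0)
xlogx_pair <- function(p, q) {
  v <- numeric(length(p))
  ok <- p > 0 & q > 0
  v[ok] <- p[ok] * log(q[ok])
  v
}

#' Per-super-pixel feature table of an image
#'
#' Runs [cooccurrence()] and [haralick()] on every valid labelled window of
#' the grid and assembles one row per window, tagged with the image and
#' cross-validation group identifiers.
#'
#' @param image A [gray_image()].
#' @param grid A labelled `superpixel_grid`.
#' @param image_id,group_id Identifiers carried into the table.
#' @param offset,symmetric,extended Passed to [cooccurrence()]/[haralick()].
#' @return Data frame with columns `image_id`, `group_id`, `window_row`,
#'   `window_col`, `label` and one column per feature.
#' @export
extract_features <- function(image, grid, image_id = "img", group_id = 1L,
                             offset = c(0L, 1L), symmetric = TRUE,
                             extended = FALSE) {
  wdf <- grid$windows
  use <- which(wdf$valid & wdf$label != "unlabeled")
  feat_names <- c(haralick_feature_names, if (extended) haralick_extra_names)
  if (length(use) == 0L) {
    warning("no valid labelled windows; returning empty feature table")
    empty <- as.data.frame(setNames(rep(list(numeric(0)), length(feat_names)),
                                    feat_names))
    return(cbind(data.frame(image_id = character(0), group_id = integer(0),
                            window_row = integer(0), window_col = integer(0),
                            label = character(0)), empty))
  }
  rows <- lapply(use, function(i) {
    win <- window_pixels(image, grid, i)
    haralick(cooccurrence(win, offset, symmetric), extended = extended)
  })
  fmat <- do.call(rbind, rows)
  out <- data.frame(image_id = image_id, group_id = group_id,
                    window_row = wdf$grid_row[use],
                    window_col = wdf$grid_col[use],
                    label = as.character(wdf$label[use]),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(fmat))
}
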