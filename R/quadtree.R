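# Fixed-depth quadtree division into equal-size square super-pixels, and the
# all-pixels labelling rule that makes a super-pixel "anomalous" only when it
# lies entirely inside the delineated lesion (so a flagged super-pixel is a
# safe biopsy target).

#' Divide an image into equal-size super-pixel windows
#'
#' The image is zero-padded bottom/right to the next multiple of `leaf_size`
#' per side, then subdivided to fixed depth. Because every level of a
#' quadtree halves each side, subdividing a padded image down to
#' `leaf_size` leaves is exactly the uniform `leaf_size`-tiling, which is how
#' the grid is computed; the equivalence is exercised against a literal
#' recursive-subdivision oracle in the test suite. Windows are enumerated
#' row-major. Windows that overlap the padding, or the exterior fill left by
#' [remove_device()] (attribute `fill_mask`), are flagged `valid = FALSE` so
#' their artificial black texture never enters training or testing.
#'
#' @param image A [gray_image()], possibly carrying a `fill_mask` attribute.
#' @param leaf_size Super-pixel side in pixels; a power of two >= 2
#'   (each subdivision level halves sides, which requires even sizes
#'   throughout). Default 64.
#' @return A `superpixel_grid`: list with `leaf_size`, `grid_rows`,
#'   `grid_cols`, original `img_rows`/`img_cols`, padded sizes, and a
#'   `windows` data frame (`index`, `row0`, `col0` 1-based window starts,
#'   `valid`, `label`).
#' @export
quadtree_divide <- function(image, leaf_size = 64L) {
  leaf_size <- as.integer(leaf_size)
  if (leaf_size < 2L || bitwAnd(leaf_size, leaf_size - 1L) != 0L) {
    stop("`leaf_size` must be a power of two >= 2")
  }
  h <- nrow(image); w <- ncol(image)
  ph <- as.integer(ceiling(h / leaf_size)) * leaf_size
  pw <- as.integer(ceiling(w / leaf_size)) * leaf_size
  if (leaf_size > ph || leaf_size > pw) stop("`leaf_size` exceeds padded image")
  gr <- ph %/% leaf_size
  gc <- pw %/% leaf_size
  wr <- rep(seq_len(gr), each = gc)   # row-major enumeration
  wc <- rep(seq_len(gc), times = gr)
  row0 <- (wr - 1L) * leaf_size + 1L
  col0 <- (wc - 1L) * leaf_size + 1L
  valid <- (row0 + leaf_size - 1L) <= h & (col0 + leaf_size - 1L) <= w
  fill <- attr(image, "fill_mask")
  if (!is.null(fill) && any(valid)) {
    sat <- sat_table(fill)
    v <- which(valid)   # windows fully inside the image, safe to index
    n_fill <- sat_window_sum(sat, row0[v], col0[v], leaf_size)
    valid[v] <- n_fill == 0
  }
  grid <- list(
    leaf_size = leaf_size, grid_rows = gr, grid_cols = gc,
    img_rows = h, img_cols = w, padded_rows = ph, padded_cols = pw,
    windows = data.frame(
      index = seq_along(row0), grid_row = wr, grid_col = wc,
      row0 = row0, col0 = col0, valid = valid,
      label = factor(rep("unlabeled", length(row0)),
                     levels = c("standard", "anomalous", "unlabeled")),
      stringsAsFactors = FALSE
    )
  )
  class(grid) <- "superpixel_grid"
  grid
}

#' @export
print.superpixel_grid <- function(x, ...) {
  cat(sprintf("<superpixel_grid %d x %d windows of %d px (%d valid)>\n",
              x$grid_rows, x$grid_cols, x$leaf_size, sum(x$windows$valid)))
  invisible(x)
}

# Summed-area table with a zero guard row/column, for O(1) window sums.
sat_table <- function(m) {
  s <- apply(apply(m * 1, 2, cumsum), 1, cumsum)  # transposed after second pass
  s <- t(s)
  rbind(0, cbind(0, s))
}

sat_window_sum <- function(sat, row0, col0, size) {
  r1 <- row0; r2 <- row0 + size; c1 <- col0; c2 <- col0 + size
  sat[cbind(r2, c2)] - sat[cbind(r1, c2)] - sat[cbind(r2, c1)] + sat[cbind(r1, c1)]
}

#' Label super-pixels from a ground-truth mask
#'
#' A valid window is labelled `anomalous` only if *every* one of its pixels is
#' inside the anomalous mask region; a window containing any standard pixel
#' is `standard`. This conservative rule ensures any flagged super-pixel lies
#' wholly within the lesion. Invalid windows stay `unlabeled`.
#'
#' @param grid A `superpixel_grid` from [quadtree_divide()].
#' @param mask A `label_mask` covering the grid's image.
#' @return The grid with `windows$label` filled in.
#' @export
label_superpixels <- function(grid, mask) {
  stopifnot(inherits(grid, "superpixel_grid"))
  if (nrow(mask) < grid$img_rows || ncol(mask) < grid$img_cols) {
    stop("mask does not cover the grid's image")
  }
  wdf <- grid$windows
  sat <- sat_table(unclass(mask))
  lab <- rep("unlabeled", nrow(wdf))
  v <- wdf$valid
  n_anom <- sat_window_sum(sat, wdf$row0[v], wdf$col0[v], grid$leaf_size)
  full <- grid$leaf_size^2
  lab[v] <- ifelse(n_anom == full, "anomalous", "standard")
  grid$windows$label <- factor(lab, levels = levels(wdf$label))
  grid
}

#' Extract the pixel block of one window
#' @param image Source [gray_image()].
#' @param grid The `superpixel_grid`.
#' @param index Window index (row-major).
#' @return A [gray_image()] of size `leaf_size` x `leaf_size`.
#' @export
window_pixels <- function(image, grid, index) {
  w <- grid$windows[index, ]
  s <- grid$leaf_size
  block <- matrix(0L, s, s)
  rs <- w$row0:min(nrow(image), w$row0 + s - 1L)
  cs <- w$col0:min(ncol(image), w$col0 + s - 1L)
  block[seq_along(rs), seq_along(cs)] <- unclass(image)[rs, cs]
  gray_image(block)
}

#' Serialize a grid to CSV
#' @param grid A `superpixel_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  utils::write.csv(grid$windows, path, row.names = FALSE)
  invisible(path)
}
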