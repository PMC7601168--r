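# Circular Hough transform for locating the imaging device's circular
# aperture, and extraction of the oral-cavity region inside it.

#' Detect circles in an edge map by Hough voting
#'
#' For each candidate radius every edge pixel votes for circle centres at
#' that distance and the accumulator peak (votes pooled over a 3x3
#' neighbourhood, so discretisation does not split a peak) becomes a
#' candidate. When the edge map carries gradient fields (as maps from
#' [canny_edges()] do), each pixel votes only along its gradient direction —
#' the centre of a circular rim lies on the gradient ray — which both
#' sharpens the accumulator and suppresses votes from oriented clutter.
#'
#' Each candidate is then scored by the fraction of its circumference
#' (divided into ~7-pixel arc cells) supported by at least 3 nearby edge
#' pixels, counting only pixels whose gradient is radially aligned (within
#' 20 degrees) when directions are available. A genuine rim traces every arc
#' cell with radially-oriented edges and scores near 1; a half circle scores
#' near 0.5; texture speckle, whose gradient directions are isotropic,
#' scores far lower.
#'
#' @param edges Binary edge map from [canny_edges()] (or any 0/1 matrix).
#' @param r_min,r_max Radius search range in pixels.
#' @param r_step Radius step in pixels (default 2).
#' @param min_score Hits scoring below this are dropped (default 0.1).
#' @param gx,gy Optional gradient fields; default taken from the edge map's
#'   attributes when present.
#' @return A data frame of hits sorted by decreasing score, with columns
#'   `center_row`, `center_col`, `radius`, `score`; zero rows when nothing
#'   qualifies.
#' @export
hough_circles <- function(edges, r_min, r_max, r_step = 2, min_score = 0.1,
                          gx = attr(edges, "gx"), gy = attr(edges, "gy")) {
  h <- nrow(edges); w <- ncol(edges)
  if (!(r_min > 0 && r_min <= r_max && r_max <= min(h, w) / 2 + r_step)) {
    stop("invalid radius range: need 0 < r_min <= r_max <= min(dim)/2 + r_step")
  }
  pts <- which(unclass(edges) != 0)
  empty <- data.frame(center_row = numeric(0), center_col = numeric(0),
                      radius = numeric(0), score = numeric(0))
  if (length(pts) == 0) return(empty)
  pr <- (pts - 1L) %% h + 1L
  pc <- (pts - 1L) %/% h + 1L
  directed <- !is.null(gx) && !is.null(gy)
  if (directed) {
    mg <- sqrt(gx[pts]^2 + gy[pts]^2)
    mg[mg == 0] <- 1
    ur <- gy[pts] / mg   # unit gradient, row component
    uc <- gx[pts] / mg
    grad_ang <- atan2(ur, uc)
  }
  radii <- seq(r_min, r_max, by = r_step)
  band <- max(1.5, r_step / 2)
  hits <- vector("list", length(radii))
  for (i in seq_along(radii)) {
    r <- radii[i]
    if (directed) {
      # two votes per pixel: centre may lie up- or down-gradient
      cr <- round(c(pr - r * ur, pr + r * ur))
      cc <- round(c(pc - r * uc, pc + r * uc))
      ok <- cr >= 1 & cr <= h & cc >= 1 & cc <= w
      acc <- tabulate((cc[ok] - 1L) * h + cr[ok], nbins = h * w)
    } else {
      n_t <- max(16L, as.integer(ceiling(2 * pi * r)))
      theta <- seq(0, 2 * pi, length.out = n_t + 1L)[-(n_t + 1L)]
      dr <- round(r * sin(theta))
      dc <- round(r * cos(theta))
      acc <- numeric(h * w)
      chunk <- max(1L, as.integer(2e7 / length(pr)))
      for (t0 in seq(1L, n_t, by = chunk)) {
        ts <- t0:min(n_t, t0 + chunk - 1L)
        cr <- rep(pr, times = length(ts)) - rep(dr[ts], each = length(pr))
        cc <- rep(pc, times = length(ts)) - rep(dc[ts], each = length(pr))
        ok <- cr >= 1 & cr <= h & cc >= 1 & cc <= w
        acc <- acc + tabulate((cc[ok] - 1L) * h + cr[ok], nbins = h * w)
      }
    }
    pooled <- box3_sum(matrix(acc, h, w))
    peak <- which.max(pooled)
    py <- (peak - 1) %% h + 1
    px <- (peak - 1) %/% h + 1
    dist <- sqrt((pr - py)^2 + (pc - px)^2)
    on <- abs(dist - r) <= band
    if (directed) {
      radial <- atan2(pr - py, pc - px)
      dev <- abs((grad_ang - radial) %% pi)
      dev <- pmin(dev, pi - dev)
      on <- on & dev <= (20 * pi / 180)
    }
    n_bins <- max(24L, as.integer(2 * pi * r / 7))
    bins <- floor((atan2(pr[on] - py, pc[on] - px) + pi) / (2 * pi) *
                    n_bins) %% n_bins
    score <- sum(tabulate(bins + 1L, nbins = n_bins) >= 3L) / n_bins
    hits[[i]] <- data.frame(center_row = py, center_col = px,
                            radius = r, score = score)
  }
  out <- do.call(rbind, hits)
  out <- out[out$score >= min_score, , drop = FALSE]
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# 3x3 box sum with zero boundary, via shifted adds.
box3_sum <- function(m) {
  out <- matrix(0, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) out <- out + shift_mat(m, dr, dc)
  out
}

#' Blank and crop the image to a detected circular aperture
#'
#' When the best hit reaches `score_floor`, pixels outside the circle are set
#' to 0 and the image is cropped to the circle's bounding square (parts of the
#' square falling outside the frame are zero-filled). The exterior-fill
#' support is recorded in the attribute `fill_mask` so that downstream
#' quadtree windows touching it can be excluded. When no hit qualifies the
#' image is returned unchanged — absence of the device is a valid outcome,
#' not an error.
#'
#' @param image A [gray_image()].
#' @param hits Data frame from [hough_circles()] (may have zero rows).
#' @param score_floor Minimum score for accepting the best hit (default 0.35).
#' @return A [gray_image()]; cropped with `fill_mask` and `crop` attributes
#'   when a circle was accepted, otherwise the input.
#' @export
remove_device <- function(image, hits, score_floor = 0.35) {
  if (is.null(hits) || nrow(hits) == 0 || max(hits$score) < score_floor) {
    return(image)
  }
  best <- hits[which.max(hits$score), ]
  h <- nrow(image); w <- ncol(image)
  r <- best$radius
  side <- 2L * as.integer(r) + 1L
  out <- matrix(0L, side, side)
  fill <- matrix(TRUE, side, side)
  # crop window in source coordinates
  r0 <- as.integer(round(best$center_row)) - as.integer(r)
  c0 <- as.integer(round(best$center_col)) - as.integer(r)
  rs <- max(1L, r0):min(h, r0 + side - 1L)
  cs <- max(1L, c0):min(w, c0 + side - 1L)
  out[rs - r0 + 1L, cs - c0 + 1L] <- unclass(image)[rs, cs]
  ctr <- as.integer(r) + 1L
  dist2 <- outer((seq_len(side) - ctr)^2, (seq_len(side) - ctr)^2, `+`)
  inside <- dist2 <= r^2
  out[!inside] <- 0L
  fill[rs - r0 + 1L, cs - c0 + 1L] <- FALSE
  fill <- fill | !inside
  res <- gray_image(out)
  attr(res, "fill_mask") <- fill
  attr(res, "circle") <- best
  attr(res, "crop") <- list(row0 = r0, col0 = c0, side = side)
  res
}

#' Apply the crop of a device-removed image to its mask
#'
#' @param mask A `label_mask` aligned with the original image.
#' @param cropped The output of [remove_device()] (carrying a `crop`
#'   attribute); if none, `mask` is returned unchanged.
#' @return A `label_mask` aligned with `cropped`.
#' @export
crop_mask_like <- function(mask, cropped) {
  cr <- attr(cropped, "crop")
  if (is.null(cr)) return(mask)
  out <- matrix(0L, cr$side, cr$side)
  rs <- max(1L, cr$row0):min(nrow(mask), cr$row0 + cr$side - 1L)
  cs <- max(1L, cr$col0):min(ncol(mask), cr$col0 + cr$side - 1L)
  out[rs - cr$row0 + 1L, cs - cr$col0 + 1L] <- unclass(mask)[rs, cs]
  out[attr(cropped, "fill_mask")] <- 0L
  label_mask(out, cropped)
}
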