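# Deriche recursive edge detector.
#
# Smoothing kernel  s(x) = k (1 + a|x|) exp(-a|x|),  k chosen so sum(s) = 1.
# Derivative kernel d(x) = -c x exp(-a|x|),          c = (1 - e)^2 / e, e = exp(-a).
# Both are realised exactly as 2nd-order recursive (IIR) filters: a causal and
# an anticausal pass sharing the poles b1 = 2e, b2 = -e^2. The derivative is
# antisymmetric, hence zero-mean; an increasing intensity ramp yields a
# positive response.

deriche_coeffs <- function(alpha) {
  e <- exp(-alpha)
  k <- (1 - e)^2 / (1 + 2 * alpha * e - e^2)
  cc <- (1 - e)^2 / e
  list(
    e = e, k = k, c = cc,
    b1 = 2 * e, b2 = -e^2,
    # smoothing numerators: causal (a1 + a2 z^-1), anticausal (a3 z + a4 z^2)
    s = c(a1 = k, a2 = k * e * (alpha - 1), a3 = k * e * (alpha + 1), a4 = -k * e^2),
    # derivative numerators
    d = c(a1 = 0, a2 = -cc * e, a3 = cc * e, a4 = 0)
  )
}

# Sampled kernels, used by tests as the direct-convolution oracle and here
# only to size the reflect pad.
deriche_smooth_kernel <- function(alpha, half) {
  co <- deriche_coeffs(alpha)
  x <- -half:half
  co$k * (1 + alpha * abs(x)) * exp(-alpha * abs(x))
}

deriche_deriv_kernel <- function(alpha, half) {
  co <- deriche_coeffs(alpha)
  x <- -half:half
  -co$c * x * exp(-alpha * abs(x))
}

# Apply the causal+anticausal recursion along the columns of `m` (i.e. filter
# each row as a signal), with reflect padding absorbing the zero initial
# conditions. Vectorised across rows: each recursion step is a column
# operation.
deriche_filter_cols <- function(m, co, num) {
  n <- ncol(m)
  pad <- min(n - 1L, as.integer(ceiling(30 / -log(co$e))) + 2L)
  if (pad > 0L) {
    left <- m[, (pad + 1L):2L, drop = FALSE]   # reflect, edge not repeated
    right <- m[, (n - 1L):(n - pad), drop = FALSE]
    m <- cbind(left, m, right)
  }
  N <- ncol(m)
  b1 <- co$b1; b2 <- co$b2
  a1 <- num[["a1"]]; a2 <- num[["a2"]]; a3 <- num[["a3"]]; a4 <- num[["a4"]]
  yc <- matrix(0, nrow(m), N)
  yc[, 1] <- a1 * m[, 1]
  yc[, 2] <- a1 * m[, 2] + a2 * m[, 1] + b1 * yc[, 1]
  for (j in 3:N) {
    yc[, j] <- a1 * m[, j] + a2 * m[, j - 1] + b1 * yc[, j - 1] + b2 * yc[, j - 2]
  }
  ya <- matrix(0, nrow(m), N)
  ya[, N - 1] <- a3 * m[, N]
  for (j in (N - 2):1) {
    ya[, j] <- a3 * m[, j + 1] + a4 * m[, j + 2] + b1 * ya[, j + 1] + b2 * ya[, j + 2]
  }
  y <- yc + ya
  y[, (pad + 1L):(pad + n), drop = FALSE]
}

#' Deriche gradient of an image
#'
#' Computes the horizontal and vertical gradient responses of the Deriche
#' recursive filter: a separable combination of an exponential smoothing
#' kernel (normalised to unit sum) along one axis and an antisymmetric
#' (zero-mean) derivative kernel along the other. Both 1-D passes are exact
#' second-order recursive filters, so the cost is independent of the
#' effective kernel width `1/alpha`. Borders are handled by reflect padding.
#'
#' @param image A [gray_image()] or numeric matrix.
#' @param alpha Positive smoothing coefficient; smaller values smooth more.
#' @return A list with matrices `gx` (derivative along columns, i.e. response
#'   to vertical edges) and `gy` (derivative along rows).
#' @export
deriche_gradient <- function(image, alpha = 1.0) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("`alpha` must be a positive scalar")
  }
  m <- unclass(image)
  storage.mode(m) <- "double"
  co <- deriche_coeffs(alpha)
  # gx: derivative across columns, smoothing down rows
  gx <- deriche_filter_cols(m, co, co$d)
  gx <- t(deriche_filter_cols(t(gx), co, co$s))
  # gy: derivative down rows, smoothing across columns
  gy <- t(deriche_filter_cols(t(m), co, co$d))
  gy <- deriche_filter_cols(gy, co, co$s)
  list(gx = gx, gy = gy, alpha = alpha)
}

#' Canny edge map from gradient fields
#'
#' Gradient magnitude, non-maximum suppression along the gradient direction
#' (against magnitudes interpolated between the bracketing 8-neighbours),
#' then hysteresis linking: weak edge pixels
#' (magnitude >= `low`) are kept only if 8-connected to a strong pixel
#' (magnitude >= `high`). When `low`/`high` are `NULL` they are taken as
#' quantiles of the nonzero gradient magnitude (`quantiles`, default
#' 70th/90th percentile), which is robust across scenes of very different
#' contrast.
#'
#' @param gx,gy Gradient matrices from [deriche_gradient()] (or a list with
#'   elements `gx`, `gy` passed as the first argument).
#' @param low,high Hysteresis thresholds in gradient-magnitude units;
#'   `low <= high` required.
#' @param quantiles Length-2 vector of probabilities used when `low`/`high`
#'   are not given.
#' @return A binary integer matrix of class `edge_map` (1 = edge), with the
#'   thresholds used stored in attribute `params`.
#' @export
canny_edges <- function(gx, gy = NULL, low = NULL, high = NULL,
                        quantiles = c(0.70, 0.90)) {
  if (is.list(gx) && is.null(gy)) {
    gy <- gx$gy
    gx <- gx$gx
  }
  stopifnot(identical(dim(gx), dim(gy)))
  mag <- sqrt(gx^2 + gy^2)
  nz <- mag[mag > 0]
  if (is.null(low) || is.null(high)) {
    if (length(nz) == 0) {
      q <- c(0, 0)
    } else {
      q <- stats::quantile(nz, quantiles, names = FALSE)
    }
    if (is.null(low)) low <- q[1]
    if (is.null(high)) high <- q[2]
  }
  if (low > high) stop("`low` must not exceed `high`")
  thin <- nonmax_suppress(mag, gx, gy)
  edges <- hysteresis_link(thin, low, high)
  # carry the gradient fields so circle detection can vote and score along
  # the gradient direction
  structure(edges, class = c("edge_map", class(edges)),
            params = list(low = low, high = high), gx = gx, gy = gy)
}

shift_mat <- function(m, dr, dc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Keep a pixel iff its magnitude is a local maximum along the gradient
# direction, comparing against the magnitude linearly interpolated between
# the two 8-neighbours bracketing the true gradient ray (not a quantised
# sector direction: hard 4-sector comparison systematically over-suppresses
# oblique ridges and fragments circular rims, the very structures the Hough
# stage needs). The asymmetric tie-break (> backward, >= forward) thins the
# exact 2-pixel plateau an ideal step edge produces under the antisymmetric
# derivative (d(0) = 0).
nonmax_suppress <- function(mag, gx, gy) {
  ax <- abs(gx); ay <- abs(gy)
  sx <- ifelse(gx >= 0, 1L, -1L)
  sy <- ifelse(gy >= 0, 1L, -1L)
  axge <- ax >= ay
  w <- ifelse(axge, ay / pmax(ax, 1e-300), ax / pmax(ay, 1e-300))
  N <- function(a, b) shift_mat(mag, -a, -b)   # value at (r + a, c + b)
  pick <- function(mats, masks) {
    out <- matrix(0, nrow(mag), ncol(mag))
    for (i in seq_along(mats)) out <- out + mats[[i]] * masks[[i]]
    out
  }
  sgn <- list(pp = sy > 0 & sx > 0, pm = sy > 0 & sx < 0,
              mp = sy < 0 & sx > 0, mm = sy < 0 & sx < 0)
  diag_f <- pick(list(N(1, 1), N(1, -1), N(-1, 1), N(-1, -1)), sgn)
  diag_b <- pick(list(N(-1, -1), N(-1, 1), N(1, -1), N(1, 1)), sgn)
  col_f <- pick(list(N(0, 1), N(0, -1)), list(sx > 0, sx < 0))
  col_b <- pick(list(N(0, -1), N(0, 1)), list(sx > 0, sx < 0))
  row_f <- pick(list(N(1, 0), N(-1, 0)), list(sy > 0, sy < 0))
  row_b <- pick(list(N(-1, 0), N(1, 0)), list(sy > 0, sy < 0))
  fwd <- ifelse(axge, (1 - w) * col_f, (1 - w) * row_f) + w * diag_f
  bwd <- ifelse(axge, (1 - w) * col_b, (1 - w) * row_b) + w * diag_b
  keep <- mag > bwd & mag >= fwd
  keep[c(1, nrow(mag)), ] <- FALSE
  keep[, c(1, ncol(mag))] <- FALSE
  out <- mag
  out[!keep] <- 0
  out
}

# Breadth-first growth of the strong set through the weak set under
# 8-connectivity, on a 1-pixel pad so neighbour index arithmetic never wraps.
hysteresis_link <- function(thin, low, high) {
  h <- nrow(thin); w <- ncol(thin)
  weak <- thin >= low & thin > 0
  strong <- thin >= high & weak
  if (!any(strong)) return(matrix(0L, h, w))
  hp <- h + 2L
  W <- matrix(FALSE, hp, w + 2L)
  W[2:(h + 1L), 2:(w + 1L)] <- weak
  vis <- matrix(FALSE, hp, w + 2L)
  idx <- which(strong)
  frontier <- ((idx - 1L) %/% h + 1L) * hp + ((idx - 1L) %% h + 2L)
  vis[frontier] <- TRUE
  offs <- c(-1L, 1L, -hp, hp, -hp - 1L, -hp + 1L, hp - 1L, hp + 1L)
  while (length(frontier)) {
    nb <- unique(as.vector(outer(frontier, offs, `+`)))
    nb <- nb[W[nb] & !vis[nb]]
    vis[nb] <- TRUE
    frontier <- nb
  }
  matrix(as.integer(vis[2:(h + 1L), 2:(w + 1L)]), h, w)
}
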