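# Independent oracles used across the suite. Each reimplements an operation
# by the most literal route available (enumeration, direct convolution,
# brute force) so the package code is checked against a different
# computational path.

# literal pair-enumeration co-occurrence counter (double loop over positions)
naive_cooccurrence <- function(window, offset = c(0L, 1L), symmetric = TRUE) {
  m <- unclass(window)
  p <- matrix(0, 256, 256)
  dr <- offset[1]; dc <- offset[2]
  for (r in seq_len(nrow(m))) {
    for (c in seq_len(ncol(m))) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nrow(m) && c2 >= 1 && c2 <= ncol(m)) {
        i <- m[r, c] + 1L; j <- m[r2, c2] + 1L
        p[i, j] <- p[i, j] + 1
        if (symmetric) p[j, i] <- p[j, i] + 1
      }
    }
  }
  p / sum(p)
}

# literal summation of the ten texture features from a normalised p matrix,
# following the definitions term by term (loop over gray level i)
naive_haralick <- function(p) {
  Ng <- nrow(p)
  lev <- 0:(Ng - 1)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum(lev * px); mu_y <- sum(lev * py)
  sd_x <- sqrt(sum((lev - mu_x)^2 * px))
  sd_y <- sqrt(sum((lev - mu_y)^2 * py))
  p_sum <- numeric(2 * Ng - 1)   # index k+1 holds P(i+j = k)
  p_diff <- numeric(Ng)          # index k+1 holds P(|i-j| = k)
  f1 <- 0; f5 <- 0; f9 <- 0; f4 <- 0; cor_num <- 0
  for (ii in seq_len(Ng)) {
    i <- ii - 1
    row <- p[ii, ]
    f1 <- f1 + sum(row^2)
    f5 <- f5 + sum(row / (1 + (i - lev)^2))
    nz <- row > 0
    f9 <- f9 - sum(row[nz] * log(row[nz]))
    f4 <- f4 + sum((i - mu_x)^2 * row)
    cor_num <- cor_num + sum(i * lev * row)
    for (jj in seq_len(Ng)) {
      if (row[jj] > 0) {
        p_sum[i + jj] <- p_sum[i + jj] + row[jj]        # i + (jj-1) + 1
        p_diff[abs(i - jj + 1) + 1] <- p_diff[abs(i - jj + 1) + 1] + row[jj]
      }
    }
  }
  k_sum <- 0:(2 * Ng - 2); k_diff <- 0:(Ng - 1)
  f2 <- sum(k_diff^2 * p_diff)
  f3 <- if (sd_x * sd_y == 0) 0 else (cor_num - mu_x * mu_y) / (sd_x * sd_y)
  f6 <- sum(k_sum * p_sum)
  nzs <- p_sum > 0
  f8 <- -sum(p_sum[nzs] * log(p_sum[nzs]))
  f7 <- sum((k_sum - f8)^2 * p_sum)
  mu_d <- sum(k_diff * p_diff)
  f10 <- sum((k_diff - mu_d)^2 * p_diff)
  c(asm = f1, contrast = f2, correlation = f3, variance = f4, idm = f5,
    sum_average = f6, sum_variance = f7, sum_entropy = f8, entropy = f9,
    diff_variance = f10)
}

# literal recursive quadtree subdivision down to leaf_size (square input,
# side = leaf_size * 2^d), returning row-major window starts
recursive_quadtree_windows <- function(side, leaf_size, row0 = 1L, col0 = 1L) {
  if (side == leaf_size) {
    return(data.frame(row0 = row0, col0 = col0))
  }
  half <- side %/% 2L
  out <- rbind(
    recursive_quadtree_windows(half, leaf_size, row0, col0),
    recursive_quadtree_windows(half, leaf_size, row0, col0 + half),
    recursive_quadtree_windows(half, leaf_size, row0 + half, col0),
    recursive_quadtree_windows(half, leaf_size, row0 + half, col0 + half)
  )
  out[order(out$row0, out$col0), ]
}

# brute-force circle search: for every centre and radius on the small
# instance, count edge pixels within the band and return the best triple
brute_hough <- function(edges, radii, band = 1.5) {
  pts <- which(edges != 0)
  h <- nrow(edges); w <- ncol(edges)
  pr <- (pts - 1) %% h + 1; pc <- (pts - 1) %/% h + 1
  best <- c(score = -1, row = NA, col = NA, r = NA)
  for (r in radii) {
    for (cy in seq_len(h)) {
      for (cx in seq_len(w)) {
        d <- sqrt((pr - cy)^2 + (pc - cx)^2)
        s <- sum(abs(d - r) <= band) / (2 * pi * r)
        if (s > best["score"]) best <- c(score = s, row = cy, col = cx, r = r)
      }
    }
  }
  best
}

# planted thin ring edge map
ring_edges <- function(size, cy, cx, r, width = 0.5) {
  d <- sqrt(outer((seq_len(size) - cy)^2, (seq_len(size) - cx)^2, `+`))
  matrix(as.integer(abs(d - r) < width), size, size)
}

# a flat disk image for edge tests
disk_image <- function(size, cy, cx, r, inside = 220L, outside = 30L) {
  d <- sqrt(outer((seq_len(size) - cy)^2, (seq_len(size) - cx)^2, `+`))
  m <- matrix(outside, size, size)
  m[d <= r] <- inside
  gray_image(m)
}
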