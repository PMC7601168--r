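# Seeded generator of autofluorescence-like scenes with ground truth. Normal
# mucosa fluoresces bright with a smooth, low-contrast texture; lesional
# tissue absorbs the excitation light and appears darker with markedly higher
# local contrast. The generator reproduces exactly those two statistics
# (mean intensity and distance-1 local variance) — the ones the co-occurrence
# features respond to — plus an optional bright-rimmed circular device
# aperture surrounded by a near-black border.

#' Specification of a synthetic scene
#'
#' @param seed Integer seed; a scene is bit-reproducible from its spec.
#' @param size Image side in pixels (clinical frames are 1792; the test suite
#'   works at 256).
#' @param bg_mean Background (normal mucosa) mean intensity, default 180.
#' @param bg_sd Background intensity standard deviation, default 5.
#' @param bg_smooth Background smoothing scale in pixels (Gaussian sigma),
#'   default 4 — adjacent-pixel differences stay small, i.e. low contrast.
#' @param anomaly_mean Lesion mean intensity, default 60 (darker than
#'   background, as absorbing tissue must be).
#' @param anomaly_sd Lesion pixel noise standard deviation, default
#'   `4 * bg_sd` (the lesion's local variance multiplier; the noise is left
#'   unsmoothed so the contrast shows at displacement 1).
#' @param area_fraction Target fraction of pixels covered by lesion blobs,
#'   in (0, 0.5); default 0.25. The realised fraction deviates slightly where
#'   blobs overlap each other or the frame border.
#' @param n_blobs Number of lesion blobs, default 2. The first (primary)
#'   blob takes 60 percent of the target area and, when large enough to
#'   contain a full super-pixel window, is placed roughly window-centred —
#'   emulating clinical lesions, which span several windows at the native
#'   1792-pixel scale — so the all-pixels labelling rule yields at least one
#'   anomalous super-pixel. Remaining blobs are placed uniformly.
#' @param blob_deform Amplitude of the smooth radial deformation of each
#'   blob boundary (fraction of the blob radius), default 0.08; blobs are
#'   irregular closed shapes rather than perfect disks.
#' @param device_circle Optional list with `center_frac` (length-2, default
#'   `c(0.5, 0.5)`), `radius_frac` (default 0.4) and `fill` (exterior
#'   intensity 0-10, default 2) describing the device aperture.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(seed = 1L, size = 1792L, bg_mean = 180, bg_sd = 5,
                       bg_smooth = 4, anomaly_mean = 60, anomaly_sd = 4 * bg_sd,
                       area_fraction = 0.25, n_blobs = 2L, blob_deform = 0.08,
                       device_circle = NULL) {
  if (!(area_fraction > 0 && area_fraction < 0.5)) {
    stop("`area_fraction` must lie in (0, 0.5)")
  }
  if (n_blobs < 1) stop("`n_blobs` must be >= 1")
  if (anomaly_mean >= bg_mean) {
    stop("lesions absorb fluorescence: `anomaly_mean` must be < `bg_mean`")
  }
  if (!is.null(device_circle)) {
    device_circle <- utils::modifyList(
      list(center_frac = c(0.5, 0.5), radius_frac = 0.4, fill = 2),
      device_circle)
    stopifnot(device_circle$fill >= 0, device_circle$fill <= 10)
  }
  structure(list(seed = as.integer(seed), size = as.integer(size),
                 bg_mean = bg_mean, bg_sd = bg_sd, bg_smooth = bg_smooth,
                 anomaly_mean = anomaly_mean, anomaly_sd = anomaly_sd,
                 area_fraction = area_fraction, n_blobs = as.integer(n_blobs),
                 blob_deform = blob_deform, device_circle = device_circle),
            class = "scene_spec")
}

# run `expr` under a fixed seed, leaving the caller's RNG state untouched
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

smooth_field <- function(n, sigma) {
  f <- matrix(stats::rnorm(n * n), n, n)
  f <- EBImage::imageData(EBImage::gblur(EBImage::Image(f), sigma = sigma))
  (f - mean(f)) / stats::sd(f)
}

# Support of the lesion blobs: irregular disks with a smooth (low-order
# Fourier) radial deformation. The primary blob takes 60% of the target area;
# when its radius can contain a full 64-pixel window it is centred near a
# window centre (small jitter), guaranteeing at least one fully-lesional
# super-pixel under the all-pixels labelling rule.
blob_support <- function(n, n_blobs, area_fraction, deform) {
  target <- area_fraction * n * n
  shares <- if (n_blobs == 1) 1 else c(0.6, rep(0.4 / (n_blobs - 1), n_blobs - 1))
  radii <- sqrt(shares * target / pi)
  support <- matrix(FALSE, n, n)
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  for (b in seq_len(n_blobs)) {
    r0 <- radii[b]
    # window-centred placement for a primary blob large enough to hold a
    # 64 px tile (circumradius 32*sqrt(2) plus jitter and deformation slack)
    tile <- 64
    min_r <- r0 * (1 - deform)
    centres <- seq(tile / 2, n - tile / 2, by = tile)
    centres <- centres[centres - r0 >= 1 & centres + r0 <= n]
    if (b == 1L && min_r > tile / 2 * sqrt(2) + 5 && length(centres) > 0) {
      cy <- sample(centres, 1) + stats::runif(1, -3, 3)
      cx <- sample(centres, 1) + stats::runif(1, -3, 3)
    } else {
      lo <- min(r0 + 1, n / 2); hi <- max(n - r0, n / 2)
      cy <- stats::runif(1, lo, hi)
      cx <- stats::runif(1, lo, hi)
    }
    theta <- atan2(rows - cy, cols - cx)
    z <- 0
    for (k in 2:5) {
      z <- z + stats::rnorm(1) * cos(k * theta) + stats::rnorm(1) * sin(k * theta)
    }
    zmax <- max(abs(z))
    if (zmax > 0) z <- z / zmax
    rt <- r0 * (1 + deform * z)
    support <- support | ((rows - cy)^2 + (cols - cx)^2 <= rt^2)
  }
  support
}

#' Generate a synthetic autofluorescence scene
#'
#' Background: Gaussian-smoothed white noise rescaled to the spec's mean and
#' standard deviation — bright and locally smooth, like fluorescing normal
#' mucosa. Lesion support: `n_blobs` irregular (smoothly deformed) disks
#' sized to the target `area_fraction`. Inside the support, pixels are
#' replaced by darker, high-variance (unsmoothed) noise. If a device circle
#' is requested, the exterior is filled near-black with a bright rim at the
#' aperture boundary (giving the edge detector something to find), and the
#' ground-truth mask is blanked outside the aperture.
#'
#' @param spec A [scene_spec()].
#' @return List with `image` ([gray_image()]), `mask` (`label_mask`), and
#'   `circle` (ground-truth `center_row`, `center_col`, `radius`, or `NULL`).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    n <- spec$size
    bg <- spec$bg_mean + spec$bg_sd * smooth_field(n, spec$bg_smooth)
    support <- blob_support(n, spec$n_blobs, spec$area_fraction,
                            spec$blob_deform)
    img <- bg
    n_in <- sum(support)
    if (n_in > 0) {
      img[support] <- spec$anomaly_mean + spec$anomaly_sd * stats::rnorm(n_in)
    }
    img <- pmin(pmax(round(img), 0), 255)   # matrix first: dims preserved
    mask_raster <- support * 1L
    circle <- NULL
    dc <- spec$device_circle
    if (!is.null(dc)) {
      cr <- round(dc$center_frac[1] * n)
      cc <- round(dc$center_frac[2] * n)
      r <- dc$radius_frac * n
      d <- sqrt(outer((seq_len(n) - cr)^2, (seq_len(n) - cc)^2, `+`))
      img[d > r] <- dc$fill
      img[d >= r - 2 & d <= r] <- 255L   # bright rim ending at the aperture
                                         # boundary, so the strongest edge sits
                                         # at the true radius
      mask_raster[d > r] <- 0L
      circle <- list(center_row = cr, center_col = cc, radius = r)
    }
    image <- gray_image(img)
    list(image = image, mask = label_mask(mask_raster, image), circle = circle)
  })
}

#' Generate a ground-truthed benchmark dataset on disk
#'
#' Writes `n_images` scene/mask PNG pairs plus a `manifest.csv`
#' (`image_path`, `mask_path`, `group_id`, `image_id`) assigning images to
#' `n_groups` equal-sized cross-validation groups — the format consumed by
#' the preprocessing and training commands. Each image's scene seed is
#' derived deterministically from `seed`, so regeneration with the same
#' arguments is bit-identical.
#'
#' @param n_images Number of scenes (default 10), divisible by `n_groups`.
#' @param n_groups Number of cross-validation groups (default 2).
#' @param seed Master seed.
#' @param dir Output directory (created if needed).
#' @param size Scene side in pixels (default 256).
#' @param ... Further arguments to [scene_spec()] (e.g. `device_circle`).
#' @return The manifest data frame (absolute paths), invisibly; attribute
#'   `path` holds the manifest location.
#' @export
generate_benchmark <- function(n_images = 10L, n_groups = 2L, seed = 1L,
                               dir = tempfile("benchmark"), size = 256L, ...) {
  if (n_images %% n_groups != 0) {
    stop("`n_images` must be divisible by `n_groups`")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    sseed <- (as.double(seed) * 1009 + i * 9973) %% 2147483629 + 1
    sc <- generate_scene(scene_spec(seed = sseed, size = size, ...))
    img_name <- sprintf("scene_%02d.png", i)
    msk_name <- sprintf("scene_%02d_mask.png", i)
    save_image(sc$image, file.path(dir, img_name))
    save_mask(sc$mask, file.path(dir, msk_name))
    rows[[i]] <- data.frame(image_path = img_name, mask_path = msk_name,
                            group_id = ((i - 1L) %/% (n_images %/% n_groups)) + 1L,
                            image_id = sprintf("scene_%02d", i),
                            stringsAsFactors = FALSE)
  }
  man <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  out <- read_manifest(path)
  attr(out, "path") <- path
  invisible(out)
}
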