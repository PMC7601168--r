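# Coordinate convention used package-wide: matrices are row-major with the
# origin at the top-left; indices are 1-based (R idiom). Pixel (r, c) is
# image[r, c].

#' Construct a grayscale image
#'
#' A `gray_image` is an integer matrix of 8-bit intensities in \[0, 255\],
#' rows running top to bottom. It is the raster type consumed by every
#' downstream stage of the pipeline.
#'
#' @param pixels Numeric or integer matrix with all values in \[0, 255\].
#' @return An integer matrix of class `gray_image`.
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("image must be at least 1x1")
  if (anyNA(pixels)) stop("image contains missing values")
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("intensities must lie in [0, 255]")
  }
  storage.mode(pixels) <- "integer"
  class(pixels) <- c("gray_image", class(pixels))
  pixels
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, range [%d, %d]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

is_gray_image <- function(x) inherits(x, "gray_image")

#' Convert an RGB array to grayscale
#'
#' Uses the Rec. 601 luminance weights (0.299, 0.587, 0.114) and rounds to the
#' nearest integer. Any fixed convention would do for this pipeline; Rec. 601
#' is the common default for 8-bit still images.
#'
#' @param rgb Numeric array `h x w x 3` with channel values in \[0, 255\].
#' @return A [gray_image()].
#' @export
rgb_to_gray <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] >= 3L)
  g <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  gray_image(round(g))
}

#' Read an image file as an 8-bit grayscale raster
#'
#' Reads a PNG or TIFF file; RGB(A) inputs are reduced to one channel with
#' [rgb_to_gray()]. The decoders return intensities scaled to \[0, 1\]; they
#' are mapped back to the 8-bit scale, and files whose sample precision
#' exceeds 8 bits are rejected.
#'
#' @param path Path to a PNG or TIFF file.
#' @return A [gray_image()].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  raw <- read_raster(path)
  px <- raw * 255
  if (max(abs(px - round(px))) > 1e-6) {
    stop("image is not 8-bit: ", path)
  }
  px <- round(px)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] == 2L) px <- px[, , 1, drop = TRUE]   # gray + alpha
    else px <- rgb_to_gray(px)
  }
  gray_image(as.matrix(px))
}

read_raster <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", lower)) {
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format (expected PNG or TIFF): ", path)
  }
}

#' Write a grayscale image as PNG
#'
#' Lossless 8-bit single-channel output; `load_image(save_image(x))` is
#' pixel-identical to `x`.
#'
#' @param image A [gray_image()].
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  stopifnot(is_gray_image(image))
  png::writePNG(unclass(image) / 255, path)
  invisible(path)
}

#' Read a ground-truth label mask
#'
#' Masks mark anomalous (lesional) pixels. Any nonzero pixel maps to label 1
#' so that both 1-valued and 255-valued mask files are accepted. The mask must
#' have the same geometry as its paired image.
#'
#' @param path Path to a single-channel PNG/TIFF mask.
#' @param image The paired [gray_image()].
#' @return A `label_mask`: integer matrix over \{0, 1\}, same shape as `image`.
#' @export
load_mask <- function(path, image) {
  stopifnot(is_gray_image(image))
  raw <- read_raster(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1, drop = TRUE]
  label_mask(raw, image)
}

#' Construct a label mask from a raster
#'
#' @param raster Matrix; nonzero entries become label 1 (anomalous).
#' @param image The paired [gray_image()] (geometry check).
#' @return Integer matrix over \{0, 1\} of class `label_mask`.
#' @export
label_mask <- function(raster, image) {
  raster <- as.matrix(raster)
  if (!identical(dim(raster), dim(unclass(image)))) {
    stop(sprintf("mask geometry %dx%d does not match image %dx%d",
                 nrow(raster), ncol(raster), nrow(image), ncol(image)))
  }
  m <- matrix(as.integer(raster != 0), nrow(raster), ncol(raster))
  class(m) <- c("label_mask", class(m))
  m
}

#' Write a label mask as PNG (0 / 255)
#' @param mask A `label_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) {
  png::writePNG(unclass(mask) * 1.0, path)
  invisible(path)
}

#' Read a batch manifest
#'
#' A manifest is a CSV with columns `image_path`, `mask_path`, `group_id`
#' (and optionally `image_id`) driving batch preprocessing, training and
#' cross-validation. Relative paths are resolved against the manifest's
#' directory.
#'
#' @param path Path to the manifest CSV.
#' @return A data frame with absolute `image_path`/`mask_path` columns.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_path", "mask_path", "group_id")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols)) {
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  for (col in need) man[[col]] <- as.character(man[[col]])
  if (is.null(man$image_id)) {
    man$image_id <- sub("\\.[^.]*$", "", basename(man$image_path))
  }
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  man$image_path <- fix(man$image_path)
  man$mask_path <- fix(man$mask_path)
  man
}
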