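# Tissue detection, grid patch extraction with tissue-fraction filtering,
# and naive reference colour normalisation. Images are plain RGB arrays
# (H, W, 3) with intensities in [0, 1]; stained tissue is darker than the
# bright glass background, so tissue = below-threshold pixels of the blurred
# grayscale image.

img_gray <- function(image) {
  if (length(dim(image)) == 3) (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  else image
}

#' Detect tissue by blurred-grayscale thresholding
#'
#' Converts to grayscale, applies a Gaussian blur, and thresholds: pixels
#' darker than the threshold are tissue. With `threshold = "auto"` the Otsu
#' threshold of the blurred image is used; a (near-)constant image falls
#' back to the fixed threshold 0.8, under which pure background (white)
#' yields an all-false mask.
#'
#' @param image RGB array `(H, W, 3)` or grayscale matrix, values in `[0,1]`.
#' @param blur_sigma Gaussian blur radius in pixels.
#' @param threshold `"auto"` (Otsu) or a numeric cutoff in `(0, 1)`.
#' @return an `hm_tissue_mask`: logical `mask` (TRUE = tissue) and
#'   `source_shape`.
#' @export
detect_tissue <- function(image, blur_sigma = 2, threshold = "auto") {
  if (length(image) == 0) stop("empty image")
  g <- img_gray(image)
  g <- pmin(pmax(g, 0), 1)
  b <- if (blur_sigma > 0) blur_band(g, blur_sigma) else g
  if (identical(threshold, "auto")) {
    thr <- if (diff(range(b)) < 1e-6) 0.8
           else EBImage::otsu(EBImage::Image(b), range = c(0, 1))
  } else {
    thr <- as.numeric(threshold)
  }
  structure(list(mask = b < thr, source_shape = dim(g), threshold = thr),
            class = "hm_tissue_mask")
}

#' Extract non-overlapping grid patches with a tissue filter
#'
#' Tiles the image from the top-left corner into `patch_size`-sided,
#' half-open, non-overlapping tiles (trailing partial tiles are discarded)
#' and keeps a tile when the tissue fraction within its footprint is at
#' least `min_tissue_frac`. The 20% default mirrors common practice of
#' discarding near-empty tiles.
#'
#' @param image RGB array `(H, W, 3)` in `[0, 1]`.
#' @param mask an [detect_tissue()] result (or logical matrix of the same
#'   height/width).
#' @param patch_size tile side in pixels.
#' @param min_tissue_frac minimum tissue fraction to keep a tile.
#' @return list of `list(img, grid_row, grid_col)` with 0-based grid
#'   indices; empty when the image is smaller than one tile.
#' @export
extract_patches <- function(image, mask, patch_size, min_tissue_frac = 0.2) {
  stopifnot(patch_size >= 1, min_tissue_frac >= 0, min_tissue_frac <= 1)
  m <- if (inherits(mask, "hm_tissue_mask")) mask$mask else mask
  d <- dim(image)
  stopifnot(all(dim(m) == d[1:2]))
  nr <- d[1] %/% patch_size
  nc <- d[2] %/% patch_size
  out <- list()
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      ri <- ((r - 1) * patch_size + 1):(r * patch_size)
      ci <- ((cc - 1) * patch_size + 1):(cc * patch_size)
      if (mean(m[ri, ci]) >= min_tissue_frac) {
        img <- if (length(d) == 3) image[ri, ci, , drop = FALSE]
               else image[ri, ci, drop = FALSE]
        out[[length(out) + 1L]] <- list(img = img, grid_row = r - 1L,
                                        grid_col = cc - 1L)
      }
    }
  }
  out
}

#' Per-channel statistics of a reference image
#'
#' @param image RGB array `(H, W, 3)` in `[0, 1]`.
#' @param space `"rgb"` (default, the naive variant) or `"lab"`.
#' @return an `hm_reference_stats` list: `mean`, `sd` (length 3) and `space`.
#' @export
reference_stats <- function(image, space = c("rgb", "lab")) {
  space <- match.arg(space)
  x <- image_channels(image, space)
  structure(list(mean = colMeans(x), sd = apply(x, 2, stats::sd), space = space),
            class = "hm_reference_stats")
}

image_channels <- function(image, space) {
  stopifnot(length(dim(image)) == 3)
  x <- matrix(image, ncol = 3)
  if (space == "lab") x <- grDevices::convertColor(x, "sRGB", "Lab")
  x
}

channels_image <- function(x, dims, space) {
  if (space == "lab") x <- grDevices::convertColor(x, "Lab", "sRGB")
  array(x, dim = dims)
}

#' Reference-based colour normalisation
#'
#' Reinhard-style per-channel standardisation: each channel is shifted and
#' scaled so its mean and standard deviation match the reference statistics,
#' then the result is clipped to `[0, 1]`. A zero-variance channel is passed
#' through shifted to the reference mean.
#'
#' @param image RGB array `(H, W, 3)` in `[0, 1]`.
#' @param ref a [reference_stats()] object.
#' @return the normalised RGB array.
#' @export
color_normalize <- function(image, ref) {
  stopifnot(inherits(ref, "hm_reference_stats"))
  x <- image_channels(image, ref$space)
  for (ch in 1:3) {
    mu <- mean(x[, ch]); s <- stats::sd(x[, ch])
    x[, ch] <- if (s > 1e-12) (x[, ch] - mu) / s * ref$sd[ch] + ref$mean[ch]
               else x[, ch] - mu + ref$mean[ch]
  }
  pmin(pmax(channels_image(x, dim(image), ref$space), 0), 1)
}

#' Read / write plain RGB images (PNG or TIFF by extension)
#'
#' @param path image path ending in `.png`, `.tif` or `.tiff`.
#' @return `(H, W, 3)` array in `[0, 1]` (grayscale images are returned as
#'   matrices).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else stop("unsupported image format: ", ext)
}

#' @rdname read_image
#' @param image array to write.
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(image, path)
  else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("writing TIFF requires the 'tiff' package")
    tiff::writeTIFF(image, path)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}
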