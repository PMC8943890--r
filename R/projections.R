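#' Maximum intensity projection
#'
#' Collapses a Z-stack (or hyperspectral stack) to a 2D image holding, at
#' each pixel, the maximum value over all planes (channels) at that pixel
#' location. Exact per-pixel maximum, no interpolation.
#'
#' @param stack a [z_stack()], [hyper_stack()] or 3D array (treated as
#'   (plane, row, col) unless it is a `hyper_stack`).
#' @return an intensity [image2d()].
#' @export
max_projection <- function(stack) {
  image2d(Reduce(pmax, stack_planes(stack)), "intensity")
}

#' Average intensity projection
#'
#' Per-pixel arithmetic mean along the stacking axis, the standard way to
#' localise cells from a hyperspectral sweep before masking.
#'
#' @inheritParams max_projection
#' @return an intensity [image2d()].
#' @export
average_projection <- function(stack) {
  planes <- stack_planes(stack)
  image2d(Reduce(`+`, planes) / length(planes), "intensity")
}

stack_planes <- function(stack) {
  if (inherits(stack, "hyper_stack")) {
    arr <- stack$intensities
    lapply(seq_len(dim(arr)[3]),
           function(k) matrix(arr[, , k], dim(arr)[1], dim(arr)[2]))
  } else {
    arr <- if (inherits(stack, "z_stack")) stack$intensities else
      as_array3d(stack)
    lapply(seq_len(dim(arr)[1]),
           function(p) matrix(arr[p, , ], dim(arr)[2], dim(arr)[3]))
  }
}

#' Threshold an image into a binary mask
#'
#' Produces the background-removal mask used before ratiometric imaging:
#' pixels strictly above the threshold become 1, all others 0. With
#' `threshold = "otsu"` the threshold is chosen by Otsu's between-class
#' variance maximisation on a 256-bin histogram (the ImageJ default
#' automatic threshold).
#'
#' @param image matrix or [image2d()] of finite values.
#' @param threshold numeric cutoff, or `"otsu"`.
#' @return a mask [image2d()].
#' @export
threshold_mask <- function(image, threshold = "otsu") {
  m <- as_matrix2d(image)
  if (any(!is.finite(m))) stop("threshold_mask needs a finite image")
  if (identical(threshold, "otsu")) {
    rng <- range(m)
    if (rng[1] == rng[2]) {
      stop("Otsu thresholding is undefined for a constant image; ",
           "supply a numeric threshold")
    }
    u <- (m - rng[1]) / (rng[2] - rng[1])
    threshold <- rng[1] +
      EBImage::otsu(u, range = c(0, 1), levels = 256) * (rng[2] - rng[1])
  }
  image2d((m > threshold) + 0, "mask")
}

#' Ratiometric image with background masking
#'
#' Builds the CH2/CH3-style ratio image: the numerator is divided by the
#' denominator pixelwise and multiplied by a binary mask. Pixels whose
#' denominator is not positive are set to 0 regardless of the mask
#' (background semantics, keeping downstream area arithmetic well defined).
#' Ratio values are stored unclipped; `display_max` (default 0.8, the
#' conventional CH2/CH3 display ceiling) is recorded as rendering metadata
#' only.
#'
#' @param numerator,denominator matrices or [image2d()]s of equal shape.
#' @param mask binary mask of the same shape.
#' @param display_max upper display limit recorded as an attribute.
#' @return a ratio [image2d()] with attribute `display_max`.
#' @export
ratio_image <- function(numerator, denominator, mask, display_max = 0.8) {
  num <- as_matrix2d(numerator)
  den <- as_matrix2d(denominator)
  msk <- as_matrix2d(mask)
  if (!all(dim(num) == dim(den)) || !all(dim(num) == dim(msk))) {
    stop("numerator, denominator and mask must have identical shapes")
  }
  if (!all(msk %in% c(0, 1))) stop("mask must be binary")
  out <- num / den
  out[den <= 0] <- 0
  out <- out * msk
  out <- image2d(out, "ratio")
  attr(out, "display_max") <- display_max
  out
}

#' Write a ratio image as an 8-bit rainbow-LUT PNG
#'
#' Renders a ratio image for display: values are clipped to
#' `[0, display_max]` and mapped through a rainbow RGB lookup table. The
#' underlying data are not modified.
#'
#' @param ratio a ratio [image2d()] (attribute `display_max` used if
#'   `display_max` is missing).
#' @param path output PNG path.
#' @param display_max display ceiling.
#' @return `path`, invisibly.
#' @export
write_ratio_png <- function(ratio, path,
                            display_max = attr(ratio, "display_max") %||%
                              0.8) {
  m <- as_matrix2d(ratio)
  u <- pmin(pmax(m / display_max, 0), 1)
  lut <- t(col2rgb(rev(rainbow(256, end = 0.7)))) / 255
  idx <- pmin(floor(u * 255) + 1L, 256L)
  rgb <- array(0, c(nrow(m), ncol(m), 3))
  for (ch in 1:3) rgb[, , ch] <- matrix(lut[idx, ch], nrow(m), ncol(m))
  png::writePNG(rgb, path)
  invisible(path)
}
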