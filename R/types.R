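#' Wavenumber axis of a hyperspectral stack
#'
#' Validates and wraps the ordered Raman-shift axis attached to a
#' hyperspectral SRS stack. Acquisition retunes the pump laser in fixed
#' wavelength steps, so the axis must be strictly increasing and close to
#' uniformly spaced: the maximum deviation of any channel spacing from the
#' mean spacing must be below 10%. The channel index (not the wavenumber
#' value) drives the phasor Fourier kernel, which is only meaningful under
#' this near-uniformity.
#'
#' @param values numeric vector of Raman shifts in cm^-1, one per stack page.
#' @return an object of class `wavenumber_axis` with fields `values` and
#'   `n_channels`.
#' @examples
#' ax <- wavenumber_axis(seq(2800, 3050, length.out = 40))
#' ax$n_channels
#' @export
wavenumber_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L || any(!is.finite(values))) {
    stop("wavenumber axis must contain at least one finite value")
  }
  if (length(values) > 1L) {
    d <- diff(values)
    if (any(d <= 0)) {
      stop("wavenumber axis must be strictly monotonically increasing")
    }
    if (length(d) > 1L && max(abs(d - mean(d))) / mean(d) >= 0.1) {
      stop("wavenumber axis spacing deviates more than 10% from uniform")
    }
  }
  structure(list(values = values, n_channels = length(values)),
            class = "wavenumber_axis")
}

#' @export
print.wavenumber_axis <- function(x, ...) {
  cat(sprintf("<wavenumber_axis> %d channels, %.1f-%.1f cm^-1\n",
              x$n_channels, min(x$values), max(x$values)))
  invisible(x)
}

#' Hyperspectral SRS image stack
#'
#' A 3D block of SRS intensities indexed `(row, col, channel)` with the
#' channel dimension last, plus its [wavenumber_axis()]. Intensities are
#' arbitrary (instrument) units and must be finite; noisy data may contain
#' negative values, which downstream operations tolerate.
#'
#' @param intensities numeric 3D array indexed (row, col, channel).
#' @param axis a [wavenumber_axis()] whose length equals `dim(intensities)[3]`.
#' @param pixel_size optional pixel pitch in micrometres.
#' @return an object of class `hyper_stack`.
#' @examples
#' ax <- wavenumber_axis(c(2850, 2900, 2950))
#' hs <- hyper_stack(array(1, c(4, 4, 3)), ax)
#' @export
hyper_stack <- function(intensities, axis, pixel_size = NULL) {
  if (!inherits(axis, "wavenumber_axis")) axis <- wavenumber_axis(axis)
  intensities <- as_array3d(intensities)
  if (dim(intensities)[3] != axis$n_channels) {
    stop(sprintf(
      "channel dimension (%d) does not match axis length (%d)",
      dim(intensities)[3], axis$n_channels))
  }
  if (any(!is.finite(intensities))) {
    stop("stack intensities must all be finite")
  }
  structure(list(intensities = intensities, axis = axis,
                 pixel_size = pixel_size),
            class = "hyper_stack")
}

#' @export
print.hyper_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<hyper_stack> %d x %d pixels, %d channels (%.1f-%.1f cm^-1)\n",
              d[1], d[2], d[3], min(x$axis$values), max(x$axis$values)))
  invisible(x)
}

#' Single-frequency Z-stack
#'
#' A stack of images acquired at one wavenumber while stepping the focal
#' plane, indexed `(plane, row, col)`.
#'
#' @param intensities numeric 3D array indexed (plane, row, col).
#' @param z_step focal step between planes in micrometres (> 0); acquisitions
#'   typically step in 1 um increments.
#' @param wavenumber optional acquisition wavenumber in cm^-1.
#' @return an object of class `z_stack`.
#' @export
z_stack <- function(intensities, z_step = 1, wavenumber = NULL) {
  intensities <- as_array3d(intensities)
  if (dim(intensities)[1] < 1L) stop("z_stack needs at least one plane")
  if (!is.numeric(z_step) || length(z_step) != 1L || z_step <= 0) {
    stop("z_step must be a single positive number")
  }
  structure(list(intensities = intensities, z_step = z_step,
                 wavenumber = wavenumber),
            class = "z_stack")
}

#' @export
print.z_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<z_stack> %d planes of %d x %d pixels, z-step %g um\n",
              d[1], d[2], d[3], x$z_step))
  invisible(x)
}

#' Tagged 2D image
#'
#' A real-valued 2D grid carrying a semantic tag. Mask images may contain
#' only 0/1; label images only non-negative integers.
#'
#' @param values numeric matrix.
#' @param meaning one of `"intensity"`, `"ratio"`, `"mask"`, `"label"`.
#' @return the matrix with class `image2d` and attribute `meaning`.
#' @export
image2d <- function(values,
                    meaning = c("intensity", "ratio", "mask", "label")) {
  meaning <- match.arg(meaning)
  if (!is.matrix(values)) stop("image2d values must be a matrix")
  if (meaning == "mask" && !all(values %in% c(0, 1))) {
    stop("mask images may contain only 0 and 1")
  }
  if (meaning == "label" &&
      (any(values < 0) || any(values != round(values)))) {
    stop("label images may contain only non-negative integers")
  }
  structure(values, meaning = meaning, class = c("image2d", "matrix"))
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d:%s> %d x %d\n", attr(x, "meaning"),
              nrow(x), ncol(x)))
  invisible(x)
}

image_meaning <- function(x) attr(x, "meaning") %||% "intensity"

## strip image2d down to a plain matrix for arithmetic
as_matrix2d <- function(x) {
  if (inherits(x, "image2d")) {
    attr(x, "meaning") <- NULL
    class(x) <- "matrix"
  }
  if (!is.matrix(x)) stop("expected a matrix or image2d")
  x
}

as_array3d <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("expected a 3D array")
  }
  storage.mode(x) <- "double"
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## run code under a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
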