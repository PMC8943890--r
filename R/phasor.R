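#' Spectral phasor transform of a hyperspectral stack
#'
#' Maps each pixel's SRS spectrum to its normalised discrete-Fourier
#' first-harmonic coordinates. For a pixel spectrum \eqn{I_k}
#' (\eqn{k = 0, \dots, N-1} the channel index) with total \eqn{T = \sum_k
#' I_k}, the harmonic-\eqn{n} phasor is
#' \deqn{G = \sum_k I_k \cos(2\pi n k / N) / T, \quad
#'       S = \sum_k I_k \sin(2\pi n k / N) / T.}
#' Raw intensities are used directly: no smoothing, normalisation or other
#' post-processing. The channel index, not the wavenumber value, drives the
#' Fourier kernel; this assumes the near-uniform axis spacing enforced by
#' [wavenumber_axis()]. With the `+sin` convention used here a
#' delta spectrum concentrated in the first channel maps to (1, 0) on the
#' unit circle, so ROI coordinates are portable across datasets.
#'
#' Pixels whose spectral sum is not positive (noise-dominated background)
#' are marked invalid and carry G = S = 0; they are excluded from phasor
#' histograms and ROI membership rather than being clamped, so they cannot
#' contaminate compartment clusters. For any non-negative spectrum the
#' phasor lies in the unit disk, \eqn{G^2 + S^2 \le 1}.
#'
#' @param stack a [hyper_stack()] (or 3D array (row, col, channel)) with at
#'   least 2 channels.
#' @param harmonic Fourier harmonic `n`, `1 <= n < N` (default 1).
#' @param intensity_threshold optional minimum per-pixel mean intensity;
#'   pixels at or below it are marked invalid. Default `NULL` applies no
#'   pre-threshold.
#' @return an object of class `phasor_field`: matrices `G` and `S`, a
#'   validity mask `valid`, and `harmonic`.
#' @examples
#' ax <- wavenumber_axis(seq(2800, 2818, length.out = 4))
#' st <- hyper_stack(array(c(1, 2, 3, 4), c(1, 1, 4)), ax)
#' pf <- phasor_transform(st)
#' c(pf$G, pf$S)  # -0.2, -0.2
#' @export
phasor_transform <- function(stack, harmonic = 1L,
                             intensity_threshold = NULL) {
  arr <- if (inherits(stack, "hyper_stack")) stack$intensities else
    as_array3d(stack)
  n_ch <- dim(arr)[3]
  if (n_ch < 2L) stop("phasor transform needs at least 2 channels")
  harmonic <- as.integer(harmonic)
  if (harmonic < 1L || harmonic >= n_ch) {
    stop(sprintf("harmonic must satisfy 1 <= n < %d channels", n_ch))
  }
  nr <- dim(arr)[1]
  nc <- dim(arr)[2]
  m <- matrix(arr, nrow = nr * nc, ncol = n_ch)
  k <- seq_len(n_ch) - 1
  ang <- 2 * pi * harmonic * k / n_ch
  tot <- rowSums(m)
  valid <- tot > 0
  if (!is.null(intensity_threshold)) {
    valid <- valid & (tot / n_ch > intensity_threshold)
  }
  G <- S <- numeric(nr * nc)
  if (any(valid)) {
    G[valid] <- (m[valid, , drop = FALSE] %*% cos(ang)) / tot[valid]
    S[valid] <- (m[valid, , drop = FALSE] %*% sin(ang)) / tot[valid]
  } else {
    warning("no valid pixels: every spectral sum is non-positive")
  }
  structure(list(G = matrix(G, nr, nc), S = matrix(S, nr, nc),
                 valid = image2d(matrix(valid + 0, nr, nc), "mask"),
                 harmonic = harmonic),
            class = "phasor_field")
}

#' @export
print.phasor_field <- function(x, ...) {
  cat(sprintf("<phasor_field> %d x %d pixels, harmonic %d, %d valid\n",
              nrow(x$G), ncol(x$G), x$harmonic, sum(x$valid)))
  invisible(x)
}

#' 2D phasor histogram
#'
#' Bins the (G, S) coordinates of all valid pixels on a regular grid over
#' \eqn{[-1, 1) \times [-1, 1)} (half-open bins, last bin right-closed).
#' Coordinates outside the square (possible only for spectra with negative
#' noise excursions) are clamped into the edge bins so that the histogram
#' total always equals the number of valid pixels.
#'
#' @param field a `phasor_field`.
#' @param n_bins bins per axis (>= 2).
#' @return an `n_bins` x `n_bins` count matrix (rows index G, columns S)
#'   with attribute `breaks`.
#' @export
phasor_histogram <- function(field, n_bins = 128L) {
  stopifnot(inherits(field, "phasor_field"))
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  ok <- as_matrix2d(field$valid) > 0
  counts <- matrix(0L, n_bins, n_bins)
  if (any(ok)) {
    bin <- function(x) pmin(pmax(floor((x + 1) / 2 * n_bins) + 1L, 1L),
                            n_bins)
    ij <- cbind(bin(field$G[ok]), bin(field$S[ok]))
    tab <- table(factor(ij[, 1], levels = seq_len(n_bins)),
                 factor(ij[, 2], levels = seq_len(n_bins)))
    counts <- matrix(as.integer(tab), n_bins, n_bins)
  }
  attr(counts, "breaks") <- seq(-1, 1, length.out = n_bins + 1L)
  counts
}
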