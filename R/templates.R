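#' Spectral template for a cellular compartment
#'
#' A compartment's CH-stretch SRS spectrum is modelled as a constant
#' baseline (solvent and non-resonant background) plus a sum of Gaussian or
#' Lorentzian bands. All amplitudes and the baseline are non-negative, so an
#' evaluated template is non-negative on any axis.
#'
#' @param peaks data frame (or list coercible to one) with columns `center`
#'   (cm^-1), `amplitude` (>= 0), `width` (> 0, Gaussian sigma or Lorentzian
#'   half-width at half-maximum) and optionally `shape`
#'   (`"gaussian"`/`"lorentzian"`, default Gaussian).
#' @param baseline constant offset (>= 0).
#' @return an object of class `spectral_template`.
#' @examples
#' tpl <- spectral_template(
#'   data.frame(center = c(2851, 2930), amplitude = c(1, 0.4), width = 13))
#' eval_template(tpl, c(2851, 2930))
#' @export
spectral_template <- function(peaks = NULL, baseline = 0) {
  if (is.null(peaks)) {
    peaks <- data.frame(center = numeric(), amplitude = numeric(),
                        width = numeric(), shape = character())
  }
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) && is.null(peaks$shape)) peaks$shape <- "gaussian"
  if (nrow(peaks)) {
    stopifnot(all(c("center", "amplitude", "width") %in% names(peaks)))
    if (any(peaks$amplitude < 0)) stop("peak amplitudes must be >= 0")
    if (any(peaks$width <= 0)) stop("peak widths must be > 0")
    if (!all(peaks$shape %in% c("gaussian", "lorentzian"))) {
      stop("peak shape must be 'gaussian' or 'lorentzian'")
    }
  }
  if (baseline < 0) stop("baseline must be >= 0")
  structure(list(peaks = peaks, baseline = baseline),
            class = "spectral_template")
}

#' Evaluate a spectral template on a wavenumber grid
#'
#' @param template a [spectral_template()].
#' @param wavenumbers numeric vector of Raman shifts (cm^-1), or a
#'   [wavenumber_axis()].
#' @return numeric vector of template intensities.
#' @export
eval_template <- function(template, wavenumbers) {
  if (inherits(wavenumbers, "wavenumber_axis")) {
    wavenumbers <- wavenumbers$values
  }
  v <- rep(template$baseline, length(wavenumbers))
  pk <- template$peaks
  for (i in seq_len(nrow(pk))) {
    d <- wavenumbers - pk$center[i]
    v <- v + if (pk$shape[i] == "lorentzian") {
      pk$amplitude[i] * pk$width[i]^2 / (d^2 + pk$width[i]^2)
    } else {
      pk$amplitude[i] * exp(-d^2 / (2 * pk$width[i]^2))
    }
  }
  v
}

## Compartment label codes used throughout the package
COMPARTMENTS <- c(background = 0L, cytoplasm = 1L, nucleus = 2L,
                  nucleolus = 3L, cell_periphery = 4L,
                  droplet_periphery = 5L, droplet = 6L)

## Compartments that carry their own template; the two periphery classes are
## rendered as 50/50 mixtures (droplet periphery: droplet + cytoplasm; cell
## periphery: cytoplasm + background).
TEMPLATED <- c("background", "nucleus", "nucleolus", "cytoplasm", "droplet")

#' Default compartment templates
#'
#' Built-in CH-stretch templates for the six templated compartments of the
#' phantom generator. Protein-rich compartments (nucleus, nucleoli,
#' cytoplasm) are dominated by the 2930 cm^-1 CH3 symmetric stretch with a
#' 2880 cm^-1 shoulder and weak 2851 cm^-1 CH2 signal; the lipid droplet
#' template is dominated by 2851/2880 cm^-1 CH2 bands with a cholesteryl
#' ester band at 2965 cm^-1 and an unsaturated =CH band at 3015 cm^-1 whose
#' amplitude is calibrated (see [calibrate_tag_band()]) so that the
#' evaluated 3015/2965 cm^-1 height ratio equals `tag_ratio`, the literature
#' value for TAG-dominant droplets. The background is baseline-only
#' (solvent/non-resonant signal).
#'
#' @param tag_ratio target evaluated 3015/2965 cm^-1 intensity ratio of the
#'   droplet template (default 0.75, TAG-dominant composition).
#' @return named list of [spectral_template()]s for
#'   `background`, `cytoplasm`, `nucleus`, `nucleolus`, `droplet` and
#'   `droplet_periphery` (the latter a marker resolved to a mixture at
#'   render time).
#' @export
default_templates <- function(tag_ratio = 0.75) {
  pk <- function(center, amplitude, width) {
    data.frame(center = center, amplitude = amplitude, width = width,
               shape = "gaussian")
  }
  droplet_base <- spectral_template(rbind(
    pk(2851, 0.60, 13), pk(2880, 0.38, 13),
    pk(2930, 0.16, 14), pk(2965, 0.26, 13)), baseline = 0.52)
  list(
    background = spectral_template(baseline = 0.59),
    cytoplasm = spectral_template(rbind(
      pk(2930, 0.95, 14), pk(2880, 0.80, 13),
      pk(2851, 0.62, 13), pk(3015, 0.09, 13)), baseline = 0.38),
    nucleus = spectral_template(rbind(
      pk(2930, 1.10, 14), pk(2880, 0.40, 13), pk(2851, 0.15, 13)),
      baseline = 0.48),
    nucleolus = spectral_template(rbind(
      pk(2930, 1.85, 14), pk(2880, 0.62, 13),
      pk(2851, 0.24, 13), pk(3015, 0.08, 13)), baseline = 0.34),
    droplet = calibrate_tag_band(droplet_base, tag_ratio = tag_ratio),
    droplet_periphery = "mixture"
  )
}

#' Calibrate the droplet =CH band to a target TAG/CE ratio
#'
#' Adds a Gaussian =CH stretch band at 3015 cm^-1 to a droplet template,
#' solving its amplitude in closed form so that the evaluated template
#' heights satisfy I(3015)/I(2965) = `tag_ratio` exactly. The equation is
#' linear in the unknown amplitude `a`:
#' `base(3015) + a = tag_ratio * (base(2965) + a * g)` with
#' `g = exp(-50^2 / (2 width^2))` the 3015-band tail at 2965 cm^-1.
#'
#' @param template droplet [spectral_template()] without a 3015 cm^-1 band.
#' @param tag_ratio target ratio (default 0.75).
#' @param width Gaussian sigma of the added band (cm^-1).
#' @return the calibrated [spectral_template()].
#' @export
calibrate_tag_band <- function(template, tag_ratio = 0.75, width = 13) {
  base <- eval_template(template, c(2965, 3015))
  g <- exp(-(3015 - 2965)^2 / (2 * width^2))
  a <- (tag_ratio * base[1] - base[2]) / (1 - tag_ratio * g)
  if (!is.finite(a) || a < 0) {
    stop("TAG band calibration infeasible: would need a negative amplitude")
  }
  template$peaks <- rbind(template$peaks,
                          data.frame(center = 3015, amplitude = a,
                                     width = width, shape = "gaussian"))
  template
}

## Spectra for all 7 label codes on a given axis: a matrix with one row per
## compartment code (row i = code i-1) and one column per channel.
compartment_spectra <- function(templates, wavenumbers) {
  need <- setdiff(TEMPLATED, names(templates))
  if (length(need)) {
    stop("templates missing compartment(s): ", paste(need, collapse = ", "))
  }
  sp <- lapply(templates[TEMPLATED], eval_template, wavenumbers = wavenumbers)
  out <- rbind(
    background = sp$background,
    cytoplasm = sp$cytoplasm,
    nucleus = sp$nucleus,
    nucleolus = sp$nucleolus,
    cell_periphery = 0.7 * sp$cytoplasm + 0.3 * sp$background,
    droplet_periphery = 0.5 * sp$droplet + 0.5 * sp$cytoplasm,
    droplet = sp$droplet
  )
  out[names(COMPARTMENTS)[order(COMPARTMENTS)], , drop = FALSE]
}

#' Phasor coordinates of a spectral template
#'
#' Evaluates a template on an axis and returns its first-harmonic (or
#' higher) phasor position, i.e. the point where noiseless pixels of that
#' compartment land on the phasor plot.
#'
#' @param template a [spectral_template()] or a numeric spectrum.
#' @param axis a [wavenumber_axis()].
#' @param harmonic Fourier harmonic (default 1).
#' @return named vector `c(G = , S = )`.
#' @export
template_phasor <- function(template, axis, harmonic = 1L) {
  spec <- if (inherits(template, "spectral_template")) {
    eval_template(template, axis)
  } else {
    as.numeric(template)
  }
  n <- length(spec)
  k <- seq_len(n) - 1
  tot <- sum(spec)
  if (tot <= 0) stop("template has non-positive spectral sum")
  c(G = sum(spec * cos(2 * pi * harmonic * k / n)) / tot,
    S = sum(spec * sin(2 * pi * harmonic * k / n)) / tot)
}
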