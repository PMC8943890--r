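#' Read a hyperspectral stack from a multi-page TIFF plus axis sidecar
#'
#' The on-disk convention pairs a multi-page TIFF (one page per wavenumber
#' channel) with a structured-text (YAML) sidecar listing one Raman shift per
#' page under the key `wavenumbers`. Stacks written by [write_stack()] are
#' 64-bit float TIFFs and round-trip losslessly; standard 8/16/32-bit TIFFs
#' from other software are read through the `tiff` package.
#'
#' @param path multi-page TIFF file.
#' @param axis_path sidecar file; defaults to `<path without ext>_axis.yml`.
#' @return a [hyper_stack()].
#' @seealso [write_stack()]
#' @export
read_stack <- function(path, axis_path = default_sidecar(path)) {
  pages <- read_tiff_pages(path)
  side <- read_sidecar(axis_path)
  if (is.null(side$wavenumbers)) {
    stop("sidecar ", axis_path, " has no 'wavenumbers' entry")
  }
  if (length(side$wavenumbers) != length(pages)) {
    stop(sprintf(
      "page count (%d) does not match sidecar axis length (%d)",
      length(pages), length(side$wavenumbers)))
  }
  axis <- wavenumber_axis(side$wavenumbers)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  hyper_stack(arr, axis, pixel_size = side$pixel_size)
}

#' Write a hyperspectral stack as a 64-bit float multi-page TIFF
#'
#' Writes one TIFF page per channel and a YAML sidecar carrying the
#' wavenumber axis (and pixel size, when known). Intensities are stored as
#' IEEE doubles, so `read_stack(write_stack(s))` reproduces them bit-exactly,
#' including negative noise excursions.
#'
#' @param stack a [hyper_stack()].
#' @param path output TIFF path.
#' @param axis_path sidecar path; defaults to `<path without ext>_axis.yml`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, axis_path = default_sidecar(path)) {
  stopifnot(inherits(stack, "hyper_stack"))
  write_tiff64(stack$intensities, path)
  side <- list(wavenumbers = as.numeric(stack$axis$values))
  if (!is.null(stack$pixel_size)) side$pixel_size <- stack$pixel_size
  yaml::write_yaml(side, axis_path, precision = 17L)
  invisible(path)
}

#' Read/write single-frequency Z-stacks
#'
#' Z-stacks use the same TIFF convention with one page per focal plane and a
#' sidecar recording `z_step` (micrometres) and optionally the acquisition
#' `wavenumber`.
#'
#' @param zstack a [z_stack()].
#' @param path TIFF file.
#' @param meta_path sidecar; defaults to `<path without ext>_meta.yml`.
#' @return `write_zstack` returns `path` invisibly; `read_zstack` a
#'   [z_stack()].
#' @export
write_zstack <- function(zstack, path,
                         meta_path = default_sidecar(path, "_meta.yml")) {
  stopifnot(inherits(zstack, "z_stack"))
  d <- dim(zstack$intensities)
  pages <- lapply(seq_len(d[1]),
                  function(p) matrix(zstack$intensities[p, , ], d[2], d[3]))
  write_tiff64(pages, path)
  side <- list(z_step = zstack$z_step)
  if (!is.null(zstack$wavenumber)) side$wavenumber <- zstack$wavenumber
  yaml::write_yaml(side, meta_path, precision = 17L)
  invisible(path)
}

#' @rdname write_zstack
#' @export
read_zstack <- function(path,
                        meta_path = default_sidecar(path, "_meta.yml")) {
  pages <- read_tiff_pages(path)
  side <- if (file.exists(meta_path)) read_sidecar(meta_path) else list()
  arr <- array(0, c(length(pages), dim(pages[[1]])))
  for (p in seq_along(pages)) arr[p, , ] <- pages[[p]]
  z_stack(arr, z_step = side$z_step %||% 1,
          wavenumber = side$wavenumber)
}

default_sidecar <- function(path, suffix = "_axis.yml") {
  paste0(tools::file_path_sans_ext(path), suffix)
}

read_sidecar <- function(path) {
  if (!file.exists(path)) stop("sidecar file not found: ", path)
  yaml::read_yaml(path)
}

read_tiff_pages <- function(path) {
  if (!file.exists(path)) stop("TIFF file not found: ", path)
  pages <- read_tiff64(path)
  if (is.null(pages)) {  # not our float64 flavour: use the libtiff bindings
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1]  # collapse RGB to grey
      p
    })
  }
  if (!length(pages)) stop("no pages in TIFF file: ", path)
  pages
}

## ---------------------------------------------------------------------------
## Pipeline configuration

#' Default pipeline configuration
#'
#' Returns the full configuration record used by [run_pipeline()], with the
#' generator block describing the synthetic dose-response study (atorvastatin
#' 0.5--25 uM doses, three replicates), the phasor block (first harmonic),
#' the segmentation block (phasor ROI half-width) and the quantification
#' block (droplet class, minimum droplet pixel count, peak-ratio
#' wavenumbers).
#'
#' @param seed integer seed driving all simulation randomness.
#' @return a named list of configuration blocks.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    generator = list(
      image_size = c(256L, 256L),
      n_cells = 8L,
      droplet_density = 2,
      droplet_radius_range = c(2, 3),
      snr = 20,
      wavenumber_range = c(2800, 3050),
      n_channels = 40L,
      doses = c(0, 0.5, 1, 5, 10, 25),
      multipliers = c(1, 1, 1, 3, 5, 6),
      n_replicates = 3L
    ),
    phasor = list(harmonic = 1L, n_bins = 128L),
    segmentation = list(roi_half_width = 0.05),
    quantification = list(
      droplet_label = "droplet",
      min_droplet_px = 4L,
      ratio_wavenumbers = c(3015, 2965)
    )
  )
}

#' Load and validate a pipeline configuration file
#'
#' Reads a YAML configuration with blocks `generator`, `phasor`,
#' `segmentation` and `quantification`, fills defaults for anything omitted
#' (a minimal file containing only `seed` is valid), rejects unknown keys,
#' and validates values.
#'
#' @param path YAML file.
#' @return validated configuration list as from [default_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must contain a YAML mapping")
  validate_config(raw, source = path)
}

validate_config <- function(raw, source = "config") {
  if (is.null(raw$seed)) {
    stop("config is missing required block 'seed' (", source, ")")
  }
  def <- default_config(raw$seed)
  known_blocks <- names(def)
  unknown <- setdiff(names(raw), known_blocks)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- def
  for (blk in setdiff(intersect(names(raw), known_blocks), "seed")) {
    bad <- setdiff(names(raw[[blk]]), names(def[[blk]]))
    if (length(bad)) {
      stop(sprintf("unknown key(s) in config block '%s': %s", blk,
                   paste(bad, collapse = ", ")))
    }
    cfg[[blk]] <- modifyList(def[[blk]], raw[[blk]])
  }
  g <- cfg$generator
  if (!is.numeric(g$snr) || g$snr <= 0) {
    stop("generator.snr must be positive (use Inf for noiseless)")
  }
  if (g$droplet_density < 0) stop("generator.droplet_density must be >= 0")
  if (length(g$doses) != length(g$multipliers)) {
    stop("generator.doses and generator.multipliers must have equal length")
  }
  if (any(g$multipliers < 0)) stop("generator.multipliers must be >= 0")
  if (cfg$phasor$harmonic < 1 ||
      cfg$phasor$harmonic != round(cfg$phasor$harmonic)) {
    stop("phasor.harmonic must be a positive integer")
  }
  if (cfg$segmentation$roi_half_width <= 0) {
    stop("segmentation.roi_half_width must be positive")
  }
  if (cfg$quantification$min_droplet_px < 1) {
    stop("quantification.min_droplet_px must be >= 1")
  }
  cfg
}
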