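#' Phasor-plane regions of interest
#'
#' A labelled region of the (G, S) phasor plane used to segment image
#' pixels by spectral similarity, mirroring the manual coloured-box ROIs
#' drawn on phasor plots. Rectangles are axis-aligned in phasor units;
#' polygons are closed vertex lists. Containment includes the boundary.
#'
#' @param label ROI name (e.g. `"droplet"`).
#' @param g_min,g_max,s_min,s_max rectangle bounds (ordered).
#' @param color display colour.
#' @return an object of class `phasor_roi`.
#' @export
roi_rect <- function(label, g_min, g_max, s_min, s_max, color = "yellow") {
  if (!(g_min <= g_max && s_min <= s_max)) {
    stop("rectangle bounds must be ordered: g_min <= g_max, s_min <= s_max")
  }
  structure(list(label = label, shape = "rect",
                 bounds = c(g_min = unname(g_min), g_max = unname(g_max),
                            s_min = unname(s_min), s_max = unname(s_max)),
                 color = color),
            class = "phasor_roi")
}

#' @rdname roi_rect
#' @param vertices numeric matrix with >= 3 rows and columns (G, S).
#' @export
roi_polygon <- function(label, vertices, color = "yellow") {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L || ncol(vertices) != 2L ||
      any(!is.finite(vertices))) {
    stop("polygon ROI needs >= 3 finite (G, S) vertices")
  }
  structure(list(label = label, shape = "polygon", vertices = vertices,
                 color = color),
            class = "phasor_roi")
}

#' @export
print.phasor_roi <- function(x, ...) {
  cat(sprintf("<phasor_roi> '%s' (%s, %s)\n", x$label, x$shape, x$color))
  invisible(x)
}

roi_contains <- function(roi, G, S) {
  if (roi$shape == "rect") {
    b <- roi$bounds
    G >= b["g_min"] & G <= b["g_max"] & S >= b["s_min"] & S <= b["s_max"]
  } else {
    pracma::inpolygon(G, S, roi$vertices[, 1], roi$vertices[, 2],
                      boundary = TRUE)
  }
}

#' Default phasor ROIs centred on the template cluster positions
#'
#' Builds the seven-compartment ROI set (droplet, nucleolus, nucleus,
#' cytoplasm, droplet periphery, cell periphery, background) as square
#' boxes of half-width `half_width` centred on each compartment's noiseless
#' template phasor position on the given axis. This replaces the manual
#' phasor-plot ROI drawing step with a scripted, reproducible equivalent.
#' Scored cell compartments are listed before the mixture (periphery)
#' classes so that first-wins overlap resolution favours them.
#'
#' @param axis a [wavenumber_axis()].
#' @param templates compartment templates ([default_templates()] by
#'   default).
#' @param half_width box half-width in phasor units (default 0.05).
#' @param harmonic phasor harmonic (default 1).
#' @return ordered list of [roi_rect()]s.
#' @export
default_phasor_rois <- function(axis, templates = default_templates(),
                                half_width = 0.05, harmonic = 1L) {
  spectra <- compartment_spectra(templates, axis$values)
  order <- c("droplet", "nucleolus", "nucleus", "cytoplasm",
             "droplet_periphery", "cell_periphery", "background")
  colors <- c(droplet = "yellow", nucleolus = "magenta", nucleus = "blue",
              cytoplasm = "red", droplet_periphery = "green",
              cell_periphery = "orange", background = "grey")
  lapply(order, function(cls) {
    p <- template_phasor(spectra[cls, ], axis, harmonic = harmonic)
    roi_rect(cls, p["G"] - half_width, p["G"] + half_width,
             p["S"] - half_width, p["S"] + half_width,
             color = colors[[cls]])
  })
}

#' Segment image pixels by phasor-plane ROIs
#'
#' Assigns every valid pixel the label of the first ROI (in list order)
#' whose region contains its (G, S) coordinate; boundary points are
#' contained. Pixels in no ROI, and invalid pixels, get label 0.
#'
#' @param field a `phasor_field` from [phasor_transform()].
#' @param rois ordered list of [roi_rect()]/[roi_polygon()] objects.
#' @return an object of class `segmentation_map` with `labels` (an
#'   [image2d()] of ROI indices, 0 = unassigned) and `roi_list`.
#' @export
segment_by_rois <- function(field, rois) {
  stopifnot(inherits(field, "phasor_field"))
  if (!length(rois)) stop("roi list must not be empty")
  if (!all(vapply(rois, inherits, logical(1), "phasor_roi"))) {
    stop("rois must be a list of phasor_roi objects")
  }
  ok <- as_matrix2d(field$valid) > 0
  G <- field$G[ok]
  S <- field$S[ok]
  lab <- integer(length(G))
  for (i in rev(seq_along(rois))) {  # first-listed ROI wins overlaps
    lab[roi_contains(rois[[i]], G, S)] <- i
  }
  labels <- matrix(0L, nrow(field$G), ncol(field$G))
  labels[ok] <- lab
  structure(list(labels = image2d(labels + 0, "label"), roi_list = rois),
            class = "segmentation_map")
}

#' @export
print.segmentation_map <- function(x, ...) {
  cat(sprintf("<segmentation_map> %d x %d, %d ROIs (%s)\n",
              nrow(x$labels), ncol(x$labels), length(x$roi_list),
              paste(roi_labels(x), collapse = ", ")))
  invisible(x)
}

#' ROI labels of a segmentation map
#' @param seg a `segmentation_map`.
#' @return character vector of ROI labels in list order.
#' @export
roi_labels <- function(seg) {
  vapply(seg$roi_list, `[[`, character(1), "label")
}

roi_index <- function(seg, label) {
  idx <- match(label, roi_labels(seg))
  if (is.na(idx)) {
    stop(sprintf("label '%s' is not in the segmentation's ROI list", label))
  }
  idx
}

#' Mean SRS spectrum of a segmented class
#'
#' Per-channel arithmetic mean over all pixels carrying the given ROI
#' label, optionally min-max normalised to \[0, 1\] for plotting (the
#' convention for comparing ROI spectra across compartments). A constant
#' spectrum normalises to all zeros.
#'
#' @param stack the [hyper_stack()] the segmentation came from.
#' @param seg a `segmentation_map`.
#' @param label ROI label.
#' @param normalize min-max rescale to \[0, 1\]?
#' @return an object of class `spectrum_profile` with fields `wavenumbers`,
#'   `mean_intensity`, `n_pixels`, `normalized`.
#' @export
roi_mean_spectrum <- function(stack, seg, label, normalize = FALSE) {
  stopifnot(inherits(stack, "hyper_stack"),
            inherits(seg, "segmentation_map"))
  idx <- roi_index(seg, label)
  member <- as_matrix2d(seg$labels) == idx
  if (!any(member)) {
    stop(sprintf("no pixels carry label '%s'", label))
  }
  arr <- stack$intensities
  m <- matrix(arr, nrow = prod(dim(arr)[1:2]), ncol = dim(arr)[3])
  mean_int <- colMeans(m[as.vector(member), , drop = FALSE])
  if (normalize) {
    rng <- range(mean_int)
    mean_int <- if (rng[2] > rng[1]) {
      (mean_int - rng[1]) / (rng[2] - rng[1])
    } else {
      rep(0, length(mean_int))
    }
  }
  structure(list(wavenumbers = stack$axis, mean_intensity = mean_int,
                 n_pixels = sum(member), normalized = normalize,
                 label = label),
            class = "spectrum_profile")
}

#' @export
print.spectrum_profile <- function(x, ...) {
  cat(sprintf("<spectrum_profile> '%s', %d pixels, %d channels%s\n",
              x$label, x$n_pixels, x$wavenumbers$n_channels,
              if (x$normalized) ", normalized 0-1" else ""))
  invisible(x)
}

#' Render segmented classes as masks and a colour overlay
#'
#' Produces a binary mask per requested label and an RGB overlay in which
#' labels are painted in list order (later entries over earlier ones).
#' With `merge = TRUE` a combined union mask of the requested labels is
#' also returned, mirroring the merged droplet + droplet-periphery display.
#'
#' @param seg a `segmentation_map`.
#' @param labels_to_show labels to render (default: all).
#' @param merge also return the union mask of the shown labels?
#' @return list with `masks` (named list of mask [image2d()]s), `overlay`
#'   (rows x cols x 3 RGB array) and, when `merge = TRUE`, `merged` (mask).
#' @export
render_segmented_image <- function(seg, labels_to_show = roi_labels(seg),
                                   merge = FALSE) {
  all_labels <- roi_labels(seg)
  unknown <- setdiff(labels_to_show, all_labels)
  if (length(unknown)) {
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  }
  lab <- as_matrix2d(seg$labels)
  masks <- lapply(labels_to_show, function(l) {
    image2d((lab == match(l, all_labels)) + 0, "mask")
  })
  names(masks) <- labels_to_show
  overlay <- array(0, c(nrow(lab), ncol(lab), 3))
  for (l in labels_to_show) {
    rgb <- col2rgb(seg$roi_list[[match(l, all_labels)]]$color)[, 1] / 255
    sel <- masks[[l]] == 1
    for (ch in 1:3) {
      plane <- overlay[, , ch]
      plane[sel] <- rgb[ch]
      overlay[, , ch] <- plane
    }
  }
  out <- list(masks = masks, overlay = overlay)
  if (merge) {
    un <- Reduce(`+`, lapply(masks, as_matrix2d))
    out$merged <- image2d((un > 0) + 0, "mask")
  }
  out
}
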