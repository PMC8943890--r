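#' Specification of a synthetic hyperspectral phantom
#'
#' Describes a multi-cell field of view emulating fixed breast-cancer-like
#' cells imaged by hyperspectral SRS: elliptical cells with a disc nucleus
#' containing 1--2 nucleoli, cytoplasmic lipid droplets (disc-shaped, with a
#' 1 px periphery annulus), a cell-periphery annulus, and a baseline-only
#' background. Each compartment's spectrum comes from its
#' [spectral_template()]; detector noise is zero-mean Gaussian with standard
#' deviation `max(droplet template)/snr`.
#'
#' @param image_size `c(rows, cols)` of the field of view.
#' @param n_cells number of cells to place (>= 0).
#' @param droplet_density expected droplets per cell (Poisson mean, >= 0);
#'   dose-response series scale this by per-dose multipliers.
#' @param droplet_radius_range `c(min, max)` droplet radius in pixels.
#' @param templates named list of compartment templates as from
#'   [default_templates()]; must cover background, nucleus, nucleolus,
#'   cytoplasm, droplet and droplet_periphery (the latter may be the string
#'   `"mixture"` to use a 50/50 droplet + cytoplasm blend).
#' @param snr peak-signal to noise-standard-deviation ratio (> 0); `Inf`
#'   gives a noiseless phantom.
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   phantoms.
#' @param cell_major_range,cell_minor_range ellipse semi-axis ranges (px).
#' @param nucleus_frac nucleus radius as a fraction of the cell minor
#'   semi-axis.
#' @param nucleolus_radius_range nucleolus radius range (px).
#' @param cell_periphery_width,droplet_periphery_width annulus widths (px).
#' @param max_place_tries rejection-sampling attempts before giving up on
#'   placing a cell or droplet.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(256L, 256L),
                         n_cells = 8L,
                         droplet_density = 2,
                         droplet_radius_range = c(2, 3),
                         templates = default_templates(),
                         snr = 20,
                         seed = 1L,
                         cell_major_range = c(24, 30),
                         cell_minor_range = c(17, 22),
                         nucleus_frac = 0.42,
                         nucleolus_radius_range = c(2.5, 3.5),
                         cell_periphery_width = 2,
                         droplet_periphery_width = 1,
                         max_place_tries = 400L) {
  if (length(image_size) != 2L || any(image_size < 8)) {
    stop("image_size must be c(rows, cols) with both >= 8")
  }
  if (n_cells < 0) stop("n_cells must be >= 0")
  if (droplet_density < 0) stop("droplet_density must be >= 0")
  if (!(is.numeric(snr) && length(snr) == 1L && snr > 0)) {
    stop("snr must be positive (Inf for noiseless)")
  }
  need <- c(TEMPLATED, "droplet_periphery")
  missing <- setdiff(need, names(templates))
  if (length(missing)) {
    stop("templates must include all six compartments; missing: ",
         paste(missing, collapse = ", "))
  }
  structure(list(
    image_size = as.integer(image_size), n_cells = as.integer(n_cells),
    droplet_density = droplet_density,
    droplet_radius_range = droplet_radius_range,
    templates = templates, snr = snr, seed = as.integer(seed),
    cell_major_range = cell_major_range,
    cell_minor_range = cell_minor_range,
    nucleus_frac = nucleus_frac,
    nucleolus_radius_range = nucleolus_radius_range,
    cell_periphery_width = cell_periphery_width,
    droplet_periphery_width = droplet_periphery_width,
    max_place_tries = as.integer(max_place_tries)),
    class = "phantom_spec")
}

## Pixels of an ellipse (centre cx, cy in row/col units, semi-axes a >= b,
## orientation theta), optionally grown/shrunk by `grow` pixels on both axes.
ellipse_pixels <- function(nr, nc, cy, cx, a, b, theta, grow = 0) {
  a <- a + grow
  b <- b + grow
  if (a <= 0 || b <= 0) return(integer())
  ext <- ceiling(a)
  rows <- max(1L, floor(cy - ext)):min(nr, ceiling(cy + ext))
  cols <- max(1L, floor(cx - ext)):min(nc, ceiling(cx + ext))
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  keep <- which(u^2 + v^2 <= 1)
  ri <- ((keep - 1L) %% length(rows)) + 1L
  ci <- ((keep - 1L) %/% length(rows)) + 1L
  cbind(rows[ri], cols[ci])
}

disc_pixels <- function(nr, nc, cy, cx, r) {
  ellipse_pixels(nr, nc, cy, cx, r, r, 0)
}

px_index <- function(px, nr) (px[, 2L] - 1L) * nr + px[, 1L]

## Draw the label geometry of a phantom field using the current RNG stream.
## Returns label map (codes in COMPARTMENTS), per-cell and per-droplet
## instance maps, and the droplet-periphery instance map.
render_geometry <- function(spec) {
  nr <- spec$image_size[1]
  nc <- spec$image_size[2]
  lab <- matrix(0L, nr, nc)
  cellmap <- matrix(0L, nr, nc)
  dropmap <- matrix(0L, nr, nc)
  annmap <- matrix(0L, nr, nc)
  droplet_id <- 0L
  for (i in seq_len(spec$n_cells)) {
    placed <- FALSE
    for (try in seq_len(spec$max_place_tries)) {
      a <- runif(1, spec$cell_major_range[1], spec$cell_major_range[2])
      b <- runif(1, spec$cell_minor_range[1], spec$cell_minor_range[2])
      theta <- runif(1, 0, pi)
      cy <- runif(1, a + 2, nr - a - 1)
      cx <- runif(1, a + 2, nc - a - 1)
      clear <- ellipse_pixels(nr, nc, cy, cx, a, b, theta, grow = 2)
      if (any(cellmap[px_index(clear, nr)] > 0L)) next
      body <- ellipse_pixels(nr, nc, cy, cx, a, b, theta)
      core <- ellipse_pixels(nr, nc, cy, cx, a, b, theta,
                             grow = -spec$cell_periphery_width)
      ib <- px_index(body, nr)
      lab[ib] <- COMPARTMENTS[["cell_periphery"]]
      lab[px_index(core, nr)] <- COMPARTMENTS[["cytoplasm"]]
      cellmap[ib] <- i
      ## nucleus: disc near the cell centre, inside the cytoplasm
      rn <- spec$nucleus_frac * b
      ny <- cy + runif(1, -0.15, 0.15) * a
      nx <- cx + runif(1, -0.15, 0.15) * a
      nuc <- disc_pixels(nr, nc, ny, nx, rn)
      inuc <- px_index(nuc, nr)
      inuc <- inuc[lab[inuc] == COMPARTMENTS[["cytoplasm"]] &
                   cellmap[inuc] == i]
      lab[inuc] <- COMPARTMENTS[["nucleus"]]
      for (k in seq_len(sample(1:2, 1))) {
        ro <- runif(1, spec$nucleolus_radius_range[1],
                    spec$nucleolus_radius_range[2])
        ang <- runif(1, 0, 2 * pi)
        rad <- runif(1, 0, max(rn - ro - 1, 0))
        nop <- disc_pixels(nr, nc, ny + rad * sin(ang), nx + rad * cos(ang),
                           ro)
        ino <- px_index(nop, nr)
        ino <- ino[lab[ino] == COMPARTMENTS[["nucleus"]]]
        lab[ino] <- COMPARTMENTS[["nucleolus"]]
      }
      ## droplets: Poisson count, uniform in the cytoplasm, rejected against
      ## the nucleus, peripheries and other droplets
      n_drop <- rpois(1, spec$droplet_density)
      for (d in seq_len(n_drop)) {
        ok <- FALSE
        for (dtry in seq_len(spec$max_place_tries)) {
          r <- runif(1, spec$droplet_radius_range[1],
                     spec$droplet_radius_range[2])
          dy <- runif(1, cy - a, cy + a)
          dx <- runif(1, cx - a, cx + a)
          disc <- disc_pixels(nr, nc, dy, dx, r)
          if (!nrow(disc)) next
          idisc <- px_index(disc, nr)
          free <- lab[idisc] %in% COMPARTMENTS[c("cytoplasm",
                                                 "droplet_periphery")]
          if (!all(free & cellmap[idisc] == i)) next
          droplet_id <- droplet_id + 1L
          lab[idisc] <- COMPARTMENTS[["droplet"]]
          annmap[idisc] <- 0L
          dropmap[idisc] <- droplet_id
          ann <- disc_pixels(nr, nc, dy, dx,
                             r + spec$droplet_periphery_width)
          iann <- px_index(ann, nr)
          iann <- iann[lab[iann] == COMPARTMENTS[["cytoplasm"]] &
                       cellmap[iann] == i]
          lab[iann] <- COMPARTMENTS[["droplet_periphery"]]
          annmap[iann] <- droplet_id
          ok <- TRUE
          break
        }
        if (!ok) {
          stop(sprintf(
            "could not place droplet %d of %d in cell %d after %d tries;",
            d, n_drop, i, spec$max_place_tries),
            " reduce droplet_density or droplet size")
        }
      }
      placed <- TRUE
      break
    }
    if (!placed) {
      stop(sprintf("could not place cell %d after %d tries", i,
                   spec$max_place_tries))
    }
  }
  list(label = lab, cellmap = cellmap, dropmap = dropmap, annmap = annmap,
       n_droplets = droplet_id)
}

ground_truth <- function(geom) {
  lab <- geom$label
  cell_px <- sum(lab > 0L)
  frac <- if (cell_px > 0L) {
    sum(lab == COMPARTMENTS[["droplet"]]) / cell_px
  } else 0
  list(label_map = image2d(lab + 0, "label"),
       cell_instance_map = image2d(geom$cellmap + 0, "label"),
       droplet_instance_map = image2d(geom$dropmap + 0, "label"),
       true_droplet_area_fraction = frac)
}

#' Generate a hyperspectral phantom with ground truth
#'
#' Renders the geometry described by a [phantom_spec()], evaluates every
#' compartment's spectral template on the axis, assembles the per-pixel
#' hyperspectral block and adds zero-mean Gaussian detector noise with
#' standard deviation `max(droplet template on axis) / snr`. Deterministic
#' given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param axis a [wavenumber_axis()].
#' @return list with elements `stack` (a [hyper_stack()]) and
#'   `ground_truth` (label map, cell and droplet instance maps, and the true
#'   droplet area fraction `droplet px / cell px`, reported as 0 for a field
#'   without cells).
#' @examples
#' ax <- wavenumber_axis(seq(2800, 3050, length.out = 40))
#' ph <- generate_phantom(phantom_spec(image_size = c(64, 64), n_cells = 1,
#'                                     seed = 7), ax)
#' ph$ground_truth$true_droplet_area_fraction
#' @export
generate_phantom <- function(spec, axis) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!inherits(axis, "wavenumber_axis")) axis <- wavenumber_axis(axis)
  with_seed(spec$seed, {
    geom <- render_geometry(spec)
    stack <- render_spectra(spec, geom$label, axis)
    list(stack = stack, ground_truth = ground_truth(geom))
  })
}

render_spectra <- function(spec, lab, axis) {
  spectra <- compartment_spectra(spec$templates, axis$values)
  if (is.list(spec$templates$droplet_periphery) &&
      inherits(spec$templates$droplet_periphery, "spectral_template")) {
    spectra["droplet_periphery", ] <-
      eval_template(spec$templates$droplet_periphery, axis$values)
  }
  nr <- nrow(lab)
  nc <- ncol(lab)
  block <- spectra[as.integer(lab) + 1L, , drop = FALSE]
  if (is.finite(spec$snr)) {
    noise_sd <- max(spectra["droplet", ]) / spec$snr
    block <- block + rnorm(length(block), sd = noise_sd)
  }
  hyper_stack(array(block, c(nr, nc, axis$n_channels)), axis)
}

#' Generate a dose-response series of phantoms
#'
#' Emulates a statin dose-response imaging experiment: for each dose and
#' replicate an independent phantom is generated whose droplet density is
#' the base density times the dose's accumulation multiplier. Per-phantom
#' seeds are derived deterministically from `(seed, dose index, replicate)`.
#'
#' @param base_spec a [phantom_spec()]; its `droplet_density` is the control
#'   density.
#' @param doses vector of condition labels (e.g. concentrations in uM).
#' @param accumulation_curve numeric multipliers, either named by dose label
#'   or positional, one per dose.
#' @param axis a [wavenumber_axis()] for the generated stacks.
#' @param n_replicates replicate phantoms per dose (>= 1).
#' @param seed master seed for the series.
#' @return list with one element per dose x replicate: `dose`, `replicate`,
#'   `seed`, `stack`, `ground_truth`.
#' @export
generate_dose_series <- function(base_spec, doses, accumulation_curve, axis,
                                 n_replicates = 3L, seed = 1L) {
  if (!length(doses)) stop("doses must be non-empty")
  mult <- if (!is.null(names(accumulation_curve))) {
    unname(accumulation_curve[as.character(doses)])
  } else {
    as.numeric(accumulation_curve)
  }
  if (length(mult) != length(doses) || any(is.na(mult))) {
    stop("accumulation_curve must provide one multiplier per dose")
  }
  if (any(mult < 0)) stop("accumulation multipliers must be >= 0")
  out <- vector("list", length(doses) * n_replicates)
  idx <- 0L
  for (d in seq_along(doses)) {
    for (r in seq_len(n_replicates)) {
      idx <- idx + 1L
      sp <- base_spec
      sp$droplet_density <- base_spec$droplet_density * mult[d]
      sp$seed <- derive_seed(seed, d, r)
      ph <- generate_phantom(sp, axis)
      out[[idx]] <- list(dose = doses[d], replicate = r, seed = sp$seed,
                         stack = ph$stack, ground_truth = ph$ground_truth)
    }
  }
  out
}

derive_seed <- function(seed, dose_index, replicate) {
  as.integer((as.numeric(seed) %% 1e6 * 2099 + dose_index * 1000 +
                replicate) %% 2147483647)
}

#' Generate a single-frequency Z-stack phantom
#'
#' Renders the phantom geometry at one wavenumber across `n_planes` focal
#' planes. Each droplet is assigned a random focal plane and is rendered
#' (with its periphery annulus) only in that plane, over a constant cell
#' body; the union of per-plane droplet footprints therefore equals the
#' ground-truth droplet instance map. Gaussian noise uses standard deviation
#' `droplet template value at the imaging wavenumber / snr`.
#'
#' @param spec a [phantom_spec()].
#' @param n_planes number of focal planes (>= 1).
#' @param channel_wavenumber imaging wavenumber in cm^-1 (2851 for CH2
#'   lipid contrast).
#' @param seed seed; defaults to `spec$seed`.
#' @return list with `zstack` (a [z_stack()]) and `ground_truth`.
#' @export
generate_zstack <- function(spec, n_planes, channel_wavenumber = 2851,
                            seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_planes < 1) stop("n_planes must be >= 1")
  with_seed(seed, {
    geom <- render_geometry(spec)
    vals <- compartment_spectra(spec$templates, channel_wavenumber)[, 1]
    lab <- geom$label
    nr <- nrow(lab)
    nc <- ncol(lab)
    base <- matrix(vals[as.integer(lab) + 1L], nr, nc)
    cyto <- vals[[ "cytoplasm" ]]
    droplet_px <- lab == COMPARTMENTS[["droplet"]]
    ann_px <- lab == COMPARTMENTS[["droplet_periphery"]]
    base[droplet_px | ann_px] <- cyto  # cell body without droplets
    planes_of <- if (geom$n_droplets > 0L) {
      sample.int(n_planes, geom$n_droplets, replace = TRUE)
    } else integer()
    arr <- array(0, c(n_planes, nr, nc))
    noise_sd <- vals[["droplet"]] / spec$snr
    for (p in seq_len(n_planes)) {
      img <- base
      here <- which(planes_of == p)
      if (length(here)) {
        img[droplet_px & geom$dropmap %in% here] <- vals[["droplet"]]
        img[ann_px & geom$annmap %in% here] <- vals[["droplet_periphery"]]
      }
      if (is.finite(spec$snr)) {
        img <- img + rnorm(length(img), sd = noise_sd)
      }
      arr[p, , ] <- img
    }
    list(zstack = z_stack(arr, z_step = 1, wavenumber = channel_wavenumber),
         ground_truth = ground_truth(geom),
         droplet_planes = planes_of)
  })
}
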