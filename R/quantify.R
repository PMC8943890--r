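#' Lipid droplet area as a percentage of total cell area
#'
#' The primary lipid-accumulation phenotype metric: the droplet-class pixel
#' count inside the cell mask, expressed as a percentage of the cell mask
#' area. The cell mask conventionally comes from
#' `threshold_mask(average_projection(stack))`. Only the droplet class
#' counts; the droplet-periphery class (a mixed-spectrum boundary) does
#' not.
#'
#' @param seg a `segmentation_map`.
#' @param droplet_label droplet ROI label (default `"droplet"`).
#' @param cell_mask binary mask of total cell area.
#' @return percentage in \[0, 100\].
#' @export
percent_area <- function(seg, droplet_label = "droplet", cell_mask) {
  idx <- roi_index(seg, droplet_label)
  msk <- as_matrix2d(cell_mask)
  if (!all(msk %in% c(0, 1))) stop("cell_mask must be binary")
  denom <- sum(msk)
  if (denom == 0) stop("cell mask is empty: total cell area is zero")
  lab <- as_matrix2d(seg$labels)
  100 * sum(lab == idx & msk == 1) / denom
}

#' TAG/CE composition ratio from a droplet spectrum
#'
#' Ratio of the spectrum heights at the unsaturated =CH band (3015
#' cm\eqn{^{-1}}, triacylglycerols) and the 2965 cm\eqn{^{-1}} band
#' (cholesteryl esters): ~0.75 indicates TAG-dominant droplets. Because the
#' ~6 cm\eqn{^{-1}} channel spacing does not land on the target wavenumbers
#' exactly, each height is linearly interpolated between the two flanking
#' channels. The ratio is invariant to global intensity scaling, so it must
#' be computed from an un-normalised droplet-class mean spectrum.
#'
#' @param profile un-normalised `spectrum_profile` (droplet class).
#' @param num_wavenumber numerator wavenumber (default 3015 cm^-1).
#' @param den_wavenumber denominator wavenumber (default 2965 cm^-1).
#' @return the unitless intensity ratio.
#' @export
peak_ratio <- function(profile, num_wavenumber = 3015,
                       den_wavenumber = 2965) {
  stopifnot(inherits(profile, "spectrum_profile"))
  if (isTRUE(profile$normalized)) {
    stop("peak_ratio requires an un-normalised spectrum profile")
  }
  wn <- profile$wavenumbers$values
  for (w in c(num_wavenumber, den_wavenumber)) {
    if (w < min(wn) || w > max(wn)) {
      stop(sprintf("wavenumber %g cm^-1 is outside the axis range %g-%g",
                   w, min(wn), max(wn)))
    }
  }
  num <- approx(wn, profile$mean_intensity, xout = num_wavenumber)$y
  den <- approx(wn, profile$mean_intensity, xout = den_wavenumber)$y
  if (den <= 0) {
    stop("interpolated denominator intensity is not positive")
  }
  num / den
}

#' Percentage of cells containing lipid droplets
#'
#' A cell counts as droplet-positive when its footprint contains at least
#' `min_droplet_px` droplet-class pixels (guarding against single stray
#' pixels).
#'
#' @param cell_instances label [image2d()] of per-cell instance ids (from
#'   ground truth, or [label_components()] of the cell mask).
#' @param seg a `segmentation_map`.
#' @param droplet_label droplet ROI label.
#' @param min_droplet_px minimum droplet pixels per positive cell.
#' @return percentage in \[0, 100\].
#' @export
percent_cells_with_droplets <- function(cell_instances, seg,
                                        droplet_label = "droplet",
                                        min_droplet_px = 4L) {
  inst <- as_matrix2d(cell_instances)
  ids <- sort(unique(inst[inst > 0]))
  if (!length(ids)) stop("cell instance map contains no cells")
  idx <- roi_index(seg, droplet_label)
  droplet <- as_matrix2d(seg$labels) == idx
  counts <- vapply(ids, function(i) sum(droplet[inst == i]), numeric(1))
  100 * sum(counts >= min_droplet_px) / length(ids)
}

#' Mean projection intensity per cell
#'
#' Arithmetic mean of a projection image over each cell footprint,
#' reproducing the per-cell CH2 signal quantification from a maximum
#' intensity projection.
#'
#' @param projection intensity [image2d()] (e.g. from [max_projection()]).
#' @param cell_instances label [image2d()] of cell instance ids.
#' @return data frame with columns `cell` and `mean_intensity`, ordered by
#'   cell id. Instance ids without pixels are skipped with a warning.
#' @export
per_cell_mean_intensity <- function(projection, cell_instances) {
  proj <- as_matrix2d(projection)
  inst <- as_matrix2d(cell_instances)
  if (!all(dim(proj) == dim(inst))) stop("shapes differ")
  ids <- seq_len(max(0, max(inst)))
  present <- ids[ids %in% inst]
  if (length(present) < length(ids)) {
    warning("skipping ", length(ids) - length(present),
            " empty cell instance id(s)")
  }
  data.frame(
    cell = present,
    mean_intensity = vapply(present, function(i) mean(proj[inst == i]),
                            numeric(1)))
}

#' Two-sample Student's t-test with significance stars
#'
#' Classic pooled-variance two-sample t-test (equal replicate counts across
#' doses make Welch unnecessary), two-tailed, with significance stars
#' assigned at P <= 0.05 (`*`) and P <= 0.01 (`**`). Degenerate input with
#' zero pooled variance and equal means returns t = 0, p = 1.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return object of class `srs_ttest`: `statistic`, `df`, `p_value`,
#'   `stars`.
#' @examples
#' students_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
students_t_test <- function(group_a, group_b) {
  a <- as.numeric(group_a)
  b <- as.numeric(group_b)
  if (length(a) < 2L || length(b) < 2L || any(!is.finite(c(a, b)))) {
    stop("both groups need >= 2 finite observations")
  }
  df <- length(a) + length(b) - 2L
  pooled <- ((length(a) - 1) * stats::var(a) +
               (length(b) - 1) * stats::var(b)) / df
  if (pooled == 0) {
    if (mean(a) == mean(b)) {
      tt <- list(statistic = 0, df = df, p_value = 1)
    } else {
      tt <- list(statistic = sign(mean(a) - mean(b)) * Inf, df = df,
                 p_value = 0)
    }
  } else {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    tt <- list(statistic = unname(ht$statistic),
               df = unname(ht$parameter), p_value = ht$p.value)
  }
  tt$stars <- if (tt$p_value <= 0.01) "**" else
    if (tt$p_value <= 0.05) "*" else "ns"
  structure(tt, class = "srs_ttest")
}

#' @export
print.srs_ttest <- function(x, ...) {
  cat(sprintf("t = %.4f, df = %d, p = %.4g (%s)\n", x$statistic, x$df,
              x$p_value, x$stars))
  invisible(x)
}

#' Per-image quantification record
#'
#' Computes all phenotype metrics for one segmented stack: percent droplet
#' area, the 3015/2965 cm^-1 peak ratio of the droplet-class mean spectrum
#' (NA when the image has no droplet pixels), the number of cells, the
#' percentage of droplet-positive cells, and the mean per-cell average
#' projection intensity. Cell instances come from ground truth when
#' supplied, otherwise from 8-connected components of the cell mask.
#'
#' @param stack a [hyper_stack()].
#' @param seg its `segmentation_map`.
#' @param ground_truth optional generator ground truth.
#' @param droplet_label droplet ROI label.
#' @param min_droplet_px threshold for droplet-positive cells.
#' @param ratio_wavenumbers `c(numerator, denominator)` in cm^-1.
#' @param condition,replicate labels copied into the record.
#' @return one-row data frame (a QuantRecord).
#' @export
quantify_stack <- function(stack, seg, ground_truth = NULL,
                           droplet_label = "droplet", min_droplet_px = 4L,
                           ratio_wavenumbers = c(3015, 2965),
                           condition = NA, replicate = NA_integer_) {
  proj <- average_projection(stack)
  cell_mask <- threshold_mask(proj, "otsu")
  inst <- if (!is.null(ground_truth)) {
    ground_truth$cell_instance_map
  } else {
    label_components(cell_mask, connectivity = 8L)
  }
  pa <- percent_area(seg, droplet_label, cell_mask)
  idx <- roi_index(seg, droplet_label)
  pr <- if (any(as_matrix2d(seg$labels) == idx)) {
    prof <- roi_mean_spectrum(stack, seg, droplet_label, normalize = FALSE)
    peak_ratio(prof, ratio_wavenumbers[1], ratio_wavenumbers[2])
  } else {
    NA_real_
  }
  ids <- unique(as.vector(as_matrix2d(inst)))
  n_cells <- sum(ids > 0)
  pcwd <- if (n_cells > 0) {
    percent_cells_with_droplets(inst, seg, droplet_label, min_droplet_px)
  } else {
    NA_real_
  }
  mci <- if (n_cells > 0) {
    mean(per_cell_mean_intensity(proj, inst)$mean_intensity)
  } else {
    NA_real_
  }
  data.frame(condition = condition, replicate = replicate,
             percent_area = pa, peak_ratio = pr, n_cells = n_cells,
             percent_cells_with_droplets = pcwd, mean_cell_intensity = mci)
}

#' Dose-response summary table with per-dose t-tests
#'
#' Aggregates per-image quantification records into the standard
#' dose-response report: per condition, mean and sample SD of percent
#' droplet area and of the peak ratio, plus a pooled-variance Student's
#' t-test of each dose's percent-area replicates against the control
#' condition (two-tailed; stars at P <= 0.05 / P <= 0.01). No
#' multiple-testing correction is applied across doses; stars are
#' per-dose.
#'
#' @param records data frame of [quantify_stack()] rows (columns
#'   `condition`, `replicate`, `percent_area`, `peak_ratio`).
#' @param control_condition the control label (compared against itself it
#'   reports no test).
#' @return data frame with one row per condition, in order of first
#'   appearance: replicate count, means, SDs, and `t_statistic`, `df`,
#'   `p_value`, `stars` (NA for the control row).
#' @export
dose_response_table <- function(records, control_condition) {
  if (!all(c("condition", "percent_area", "peak_ratio") %in%
             names(records))) {
    stop("records must have condition, percent_area and peak_ratio columns")
  }
  conditions <- unique(records$condition)
  if (!control_condition %in% conditions) {
    stop(sprintf("control condition '%s' is missing from the records",
                 control_condition))
  }
  tab <- table(records$condition)
  if (any(tab < 2)) {
    stop("every condition needs >= 2 replicates; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  ctrl <- records$percent_area[records$condition == control_condition]
  rows <- lapply(conditions, function(cond) {
    sub <- records[records$condition == cond, ]
    row <- data.frame(
      condition = cond, n_replicates = nrow(sub),
      mean_percent_area = mean(sub$percent_area),
      sd_percent_area = sd(sub$percent_area),
      mean_peak_ratio = mean(sub$peak_ratio),
      sd_peak_ratio = sd(sub$peak_ratio),
      t_statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
      stars = NA_character_)
    if (!identical(cond, control_condition)) {
      tt <- students_t_test(sub$percent_area, ctrl)
      row$t_statistic <- tt$statistic
      row$df <- tt$df
      row$p_value <- tt$p_value
      row$stars <- tt$stars
    }
    row
  })
  do.call(rbind, rows)
}
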