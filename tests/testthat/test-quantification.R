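seg_from_labels <- function(lab, labels = c("droplet")) {
  rois <- lapply(labels, function(l) roi_rect(l, 0, 1, 0, 1))
  structure(list(labels = image2d(lab + 0, "label"), roi_list = rois),
            class = "segmentation_map")
}

test_that("percent_area counts droplet pixels inside the cell mask", {
  lab <- matrix(0, 10, 10)
  lab[1:5, 1:5] <- 1          # 25 droplet px
  seg <- seg_from_labels(lab)
  mask <- matrix(1, 10, 10)   # 100 cell px
  expect_equal(percent_area(seg, "droplet", mask), 25)
  expect_equal(percent_area(seg_from_labels(matrix(0, 10, 10)),
                            "droplet", mask), 0)
  expect_error(percent_area(seg, "droplet", matrix(0, 10, 10)), "empty")
  expect_error(percent_area(seg, "nope", mask), "not in")
  # droplet pixels outside the mask do not count
  mask2 <- matrix(0, 10, 10); mask2[6:10, ] <- 1
  expect_equal(percent_area(seg, "droplet", mask2), 0)
})

test_that("percent_area ignores relabelling of non-droplet classes", {
  set.seed(30)
  lab <- matrix(sample(0:3, 144, replace = TRUE), 12, 12)
  seg <- seg_from_labels(lab, c("droplet", "x", "y", "z"))
  mask <- matrix(1, 12, 12)
  base <- percent_area(seg, "droplet", mask)
  shuffled <- lab
  shuffled[lab == 2] <- 3
  shuffled[lab == 3] <- 2
  expect_equal(percent_area(seg_from_labels(shuffled,
                                            c("droplet", "x", "y", "z")),
                            "droplet", mask), base)
})

test_that("peak_ratio interpolates linearly and scales invariantly", {
  ax <- wavenumber_axis(seq(2900, 3050, by = 10))
  mk_prof <- function(ints, normalized = FALSE) {
    structure(list(wavenumbers = ax, mean_intensity = ints,
                   n_pixels = 1L, normalized = normalized, label = "d"),
              class = "spectrum_profile")
  }
  ints <- rep(1, ax$n_channels)
  ints[ax$values == 2960] <- 1
  ints[ax$values == 2970] <- 3          # midpoint 2965 -> 2
  ints[ax$values == 3010] <- 4
  ints[ax$values == 3020] <- 4          # flat at 3015 -> 4
  expect_equal(peak_ratio(mk_prof(ints)), 2)
  expect_equal(peak_ratio(mk_prof(ints * 7)), 2)  # global scale invariant
  expect_equal(peak_ratio(mk_prof(rep(2, ax$n_channels))), 1)
  expect_error(peak_ratio(mk_prof(ints, normalized = TRUE)), "normalis")
  expect_error(peak_ratio(mk_prof(ints), num_wavenumber = 3100), "outside")
  expect_error(peak_ratio(mk_prof(rep(0, ax$n_channels))), "positive")
})

test_that("percent_cells_with_droplets applies the pixel threshold", {
  inst <- matrix(0, 9, 9)
  inst[1:3, 1:3] <- 1; inst[5:7, 1:3] <- 2; inst[1:3, 5:7] <- 3
  lab <- matrix(0, 9, 9)
  lab[1:2, 1:2] <- 1                     # 4 droplet px in cell 1
  seg <- seg_from_labels(lab)
  expect_equal(percent_cells_with_droplets(inst, seg), 100 / 3,
               tolerance = 1e-10)
  lab2 <- lab; lab2[5:6, 1:2] <- 1; lab2[1:2, 5:6] <- 1
  expect_equal(percent_cells_with_droplets(inst, seg_from_labels(lab2)),
               100)
  # below the 4-px default threshold a cell does not count
  lab3 <- matrix(0, 9, 9); lab3[1, 1:3] <- 1
  expect_equal(percent_cells_with_droplets(inst, seg_from_labels(lab3)), 0)
  expect_error(percent_cells_with_droplets(matrix(0, 9, 9), seg), "no cells")
})

test_that("per_cell_mean_intensity equals a naive per-cell loop", {
  inst <- matrix(0, 2, 2); inst[1, ] <- 1
  proj <- matrix(c(2, 0, 4, 0), 2, 2)
  out <- per_cell_mean_intensity(proj, inst)
  expect_equal(out$mean_intensity, 3)
  const <- matrix(5, 2, 2)
  expect_equal(per_cell_mean_intensity(const, inst)$mean_intensity, 5)
  set.seed(33)
  inst2 <- matrix(sample(0:4, 400, replace = TRUE), 20, 20)
  proj2 <- matrix(rnorm(400), 20, 20)
  got <- per_cell_mean_intensity(proj2, inst2)
  for (i in 1:4) {
    expect_equal(got$mean_intensity[got$cell == i],
                 mean(proj2[inst2 == i]), tolerance = 1e-12)
  }
  inst3 <- inst2; inst3[inst3 == 2] <- 4  # id 2 becomes empty
  expect_warning(per_cell_mean_intensity(proj2, inst3), "empty")
})

test_that("students_t_test matches the closed-form pooled t", {
  tt <- students_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(tt$df, 4)
  expect_equal(tt$p_value, 0.2878641, tolerance = 1e-6)
  expect_equal(tt$stars, "ns")

  same <- students_t_test(c(1, 1, 2), c(1, 1, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  deg <- students_t_test(c(1, 1), c(1, 1))  # zero pooled variance
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p_value, 1)

  sep <- students_t_test(c(0, 0, 0), c(10, 10, 10.0001))
  expect_lt(sep$p_value, 0.01)
  expect_equal(sep$stars, "**")

  expect_error(students_t_test(1, c(1, 2)), ">= 2")
  expect_error(students_t_test(c(1, NA, 2), c(1, 2)), "finite")

  set.seed(40)
  for (i in 1:50) {
    a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1), mean = runif(1))
    got <- students_t_test(a, b)
    ref <- pooled_t_oracle(a, b)
    expect_equal(got$statistic, ref$t, tolerance = 1e-9)
    expect_equal(got$df, ref$df)
    expect_equal(got$p_value, ref$p, tolerance = 1e-9)
    flip <- students_t_test(b, a)   # antisymmetry
    expect_equal(flip$statistic, -got$statistic, tolerance = 1e-12)
    expect_equal(flip$p_value, got$p_value, tolerance = 1e-12)
  }
})

test_that("star assignment follows the P <= 0.05 / P <= 0.01 thresholds", {
  star_of <- function(p) {
    if (p <= 0.01) "**" else if (p <= 0.05) "*" else "ns"
  }
  set.seed(41)
  for (i in 1:40) {
    a <- rnorm(4); b <- rnorm(4, mean = runif(1, 0, 3))
    tt <- students_t_test(a, b)
    expect_equal(tt$stars, star_of(tt$p_value))
  }
})

test_that("dose_response_table summarises replicates and tests vs control", {
  rec <- data.frame(
    condition = rep(c("ctrl", "lo", "hi"), each = 3),
    replicate = rep(1:3, 3),
    percent_area = c(10, 10, 10, 10, 10, 10, 20, 21, 22),
    peak_ratio = rep(0.75, 9))
  tab <- dose_response_table(rec, "ctrl")
  expect_equal(tab$condition, c("ctrl", "lo", "hi"))
  expect_equal(tab$mean_percent_area, c(10, 10, 21))
  expect_equal(tab$sd_percent_area, c(0, 0, 1))
  expect_true(is.na(tab$p_value[1]))
  expect_equal(tab$stars[2], "ns")       # identical to control
  expect_equal(tab$stars[3], "**")
  expect_error(dose_response_table(rec, "missing"), "control")
  expect_error(dose_response_table(rec[-c(1, 2), ], "ctrl"),
               "replicates")
  # a control-only experiment yields a one-row table without tests
  solo <- dose_response_table(rec[rec$condition == "ctrl", ], "ctrl")
  expect_equal(nrow(solo), 1L)
  expect_true(is.na(solo$t_statistic))
})

test_that("8-connected labelling matches a brute-force flood fill", {
  m <- matrix(0, 5, 5); m[1, 1] <- 1; m[2, 2] <- 1  # diagonal pair
  expect_equal(max(unclass(label_components(m))), 1)
  expect_equal(max(unclass(label_components(m, connectivity = 4L))), 2)
  set.seed(44)
  for (i in 1:8) {
    mask <- matrix(rbinom(15 * 15, 1, 0.4), 15, 15)
    got <- unclass(label_components(mask))
    ref <- bfs_components8(mask)
    expect_equal(max(got), max(ref))
    # identical partitions up to label naming: the label pairing must be a
    # bijection between the two labellings
    pairs <- unique(cbind(as.vector(got), as.vector(ref)))
    expect_equal(nrow(pairs), length(unique(as.vector(got))))
    expect_equal(nrow(pairs), length(unique(as.vector(ref))))
  }
})

test_that("quantify_stack produces a coherent record on a phantom", {
  ax <- test_axis()
  ph <- generate_phantom(small_spec(seed = 23, snr = Inf,
                                    droplet_density = 3), ax)
  seg <- segment_by_rois(phasor_transform(ph$stack),
                         default_phasor_rois(ax))
  rec <- quantify_stack(ph$stack, seg, ph$ground_truth,
                        condition = "ctrl", replicate = 1L)
  expect_equal(rec$n_cells, 2L)
  expect_equal(rec$percent_area,
               100 * ph$ground_truth$true_droplet_area_fraction,
               tolerance = 1)
  expect_equal(rec$peak_ratio, 0.75, tolerance = 0.02)
  expect_true(rec$percent_cells_with_droplets %in% c(0, 50, 100))
  # with no droplets the ratio is NA and percent area 0
  ph0 <- generate_phantom(small_spec(seed = 24, snr = Inf,
                                     droplet_density = 0), ax)
  seg0 <- segment_by_rois(phasor_transform(ph0$stack),
                          default_phasor_rois(ax))
  rec0 <- quantify_stack(ph0$stack, seg0, ph0$ground_truth)
  expect_equal(rec0$percent_area, 0)
  expect_true(is.na(rec0$peak_ratio))
})
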