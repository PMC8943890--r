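field_from_points <- function(pts) {
  # synthetic 1 x n phasor field with prescribed (G, S) coordinates
  structure(list(G = matrix(pts[, 1], 1), S = matrix(pts[, 2], 1),
                 valid = image2d(matrix(1, 1, nrow(pts)), "mask"),
                 harmonic = 1L),
            class = "phasor_field")
}

test_that("rectangle ROI containment is closed and first-listed wins", {
  pts <- rbind(c(0.5, 0.5), c(0.9, -0.9), c(0.4, 0.4), c(0.45, 0.55))
  field <- field_from_points(pts)
  rois <- list(roi_rect("a", 0.4, 0.6, 0.4, 0.6),
               roi_rect("b", 0.35, 0.5, 0.35, 0.6))
  seg <- segment_by_rois(field, rois)
  lab <- as.vector(unclass(seg$labels))
  expect_equal(lab[1], 1)  # inside both -> first listed
  expect_equal(lab[2], 0)  # outside every ROI
  expect_equal(lab[3], 1)  # on the closed boundary of 'a'
  expect_equal(lab[4], 1)
  seg2 <- segment_by_rois(field, rev(rois))
  expect_equal(as.vector(unclass(seg2$labels))[1], 1)  # now 'b' wins
  expect_error(segment_by_rois(field, list()), "empty")
  expect_error(roi_rect("x", 0.6, 0.4, 0, 1), "ordered")
})

test_that("polygon ROIs contain interior and boundary points", {
  tri <- roi_polygon("tri", rbind(c(0, 0), c(0.5, 0), c(0, 0.5)))
  pts <- rbind(c(0.1, 0.1), c(0.25, 0), c(0.4, 0.4), c(-0.01, 0))
  seg <- segment_by_rois(field_from_points(pts), list(tri))
  expect_equal(as.vector(unclass(seg$labels)), c(1, 1, 0, 0))
  expect_error(roi_polygon("bad", rbind(c(0, 0), c(1, 1))), "3")
})

test_that("invalid pixels are never assigned to an ROI", {
  arr <- array(0, c(1, 2, 4))
  arr[1, 1, ] <- c(1, 1, 1, 1)   # valid, phasor (0,0)
  arr[1, 2, ] <- c(0, 0, 0, 0)   # invalid
  pf <- phasor_transform(arr)
  seg <- segment_by_rois(pf, list(roi_rect("all", -1, 1, -1, 1)))
  expect_equal(as.vector(unclass(seg$labels)), c(1, 0))
})

test_that("roi_mean_spectrum averages member pixels and normalises 0-1", {
  ax <- test_axis(2)
  arr <- array(0, c(1, 2, 2))
  arr[1, 1, ] <- c(0, 2)
  arr[1, 2, ] <- c(2, 4)
  st <- hyper_stack(arr, ax)
  pf <- phasor_transform(st)
  seg <- segment_by_rois(pf, list(roi_rect("all", -1, 1, -1, 1)))
  prof <- roi_mean_spectrum(st, seg, "all")
  expect_equal(prof$mean_intensity, c(1, 3))
  expect_equal(prof$n_pixels, 2L)
  norm <- roi_mean_spectrum(st, seg, "all", normalize = TRUE)
  expect_equal(norm$mean_intensity, c(0, 1))
  # a single member pixel returns its own spectrum
  one <- segment_by_rois(pf, list(roi_rect("one", -1, -0.99, -1, 1)))
  expect_equal(roi_mean_spectrum(st, one, "one")$mean_intensity, c(0, 2))
  expect_error(roi_mean_spectrum(st, seg, "nope"), "not in")
  empty <- segment_by_rois(pf, list(roi_rect("void", 0.9, 1, 0.9, 1)))
  expect_error(roi_mean_spectrum(st, empty, "void"), "void")
  # constant mean spectrum normalises to all zeros by convention
  cst <- hyper_stack(array(5, c(1, 2, 2)), ax)
  segc <- segment_by_rois(phasor_transform(cst),
                          list(roi_rect("all", -1, 1, -1, 1)))
  expect_equal(roi_mean_spectrum(cst, segc, "all",
                                 normalize = TRUE)$mean_intensity, c(0, 0))
})

test_that("noiseless phantom droplet spectrum equals its template", {
  ax <- test_axis()
  ph <- generate_phantom(small_spec(seed = 6, snr = Inf,
                                    droplet_density = 4), ax)
  seg <- segment_by_rois(phasor_transform(ph$stack),
                         default_phasor_rois(ax))
  prof <- roi_mean_spectrum(ph$stack, seg, "droplet")
  tpl <- eval_template(default_templates()$droplet, ax)
  expect_lt(max(abs(prof$mean_intensity - tpl)), 1e-9)
  expect_equal(prof$n_pixels,
               sum(unclass(ph$ground_truth$label_map) == 6))
})

test_that("render_segmented_image masks, merges and rejects unknowns", {
  pts <- rbind(c(0.5, 0.5), c(-0.5, -0.5), c(0, 0))
  field <- field_from_points(pts)
  rois <- list(roi_rect("a", 0.4, 0.6, 0.4, 0.6),
               roi_rect("b", -0.6, -0.4, -0.6, -0.4))
  seg <- segment_by_rois(field, rois)
  r1 <- render_segmented_image(seg, "a")
  expect_equal(as.vector(unclass(r1$masks$a)), c(1, 0, 0))
  rm <- render_segmented_image(seg, c("a", "b"), merge = TRUE)
  expect_equal(as.vector(unclass(rm$merged)), c(1, 1, 0))
  expect_error(render_segmented_image(seg, "zz"), "unknown")
  # full-class overlay paints every assigned pixel at most one colour
  all7 <- render_segmented_image(seg)
  painted <- Reduce(`+`, lapply(all7$masks, unclass))
  expect_true(all(painted <= 1))
})

test_that("default ROIs recover compartments on a small phantom", {
  ax <- test_axis()
  ph <- generate_phantom(small_spec(seed = 19, snr = Inf,
                                    droplet_density = 3), ax)
  seg <- segment_by_rois(phasor_transform(ph$stack),
                         default_phasor_rois(ax))
  expect_gte(segmentation_accuracy(seg, ph$ground_truth), 0.99)
})
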