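# Shared fixtures: a default 40-channel CH-stretch axis and a small, fast
# phantom spec (two cells in a 96 x 96 field) for unit tests. Acceptance
# tests use full-size phantoms and build their own specs.

test_axis <- function(n = 40L) {
  wavenumber_axis(seq(2800, 3050, length.out = n))
}

small_spec <- function(...) {
  args <- list(image_size = c(96L, 96L), n_cells = 2L,
               cell_major_range = c(14, 18), cell_minor_range = c(10, 13),
               droplet_radius_range = c(1.5, 2.5))
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

# Strip image2d class/attributes down to a plain matrix for comparisons.
as_mat <- function(x) {
  x <- unclass(x)
  attr(x, "meaning") <- NULL
  x
}

# Independent naive phasor: per-pixel double loop over the Fourier sum.
naive_phasor <- function(arr, harmonic = 1L) {
  nr <- dim(arr)[1]; nc <- dim(arr)[2]; n <- dim(arr)[3]
  G <- S <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      spec <- arr[i, j, ]
      tot <- sum(spec)
      if (tot > 0) {
        g <- s <- 0
        for (k in seq_len(n)) {
          ang <- 2 * pi * harmonic * (k - 1) / n
          g <- g + spec[k] * cos(ang)
          s <- s + spec[k] * sin(ang)
        }
        G[i, j] <- g / tot
        S[i, j] <- s / tot
      }
    }
  }
  list(G = G, S = S)
}

# Independent pooled-variance two-sample t oracle (closed form + pt).
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2, p = 2 * pt(-abs(t), na + nb - 2))
}

# Brute-force 8-connected labelling by flood fill (queue-based).
bfs_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] == 1 && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j)); lab[i, j] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di; jj <- p[2] + dj
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              mask[ii, jj] == 1 && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            queue[[length(queue) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# Map a segmentation + ground truth to class-recovery accuracy over the
# non-periphery compartments (peripheries are mixed-spectrum boundaries).
segmentation_accuracy <- function(seg, ground_truth) {
  lab <- unclass(ground_truth$label_map)
  truth <- names(srsphasor:::COMPARTMENTS)[
    match(lab, srsphasor:::COMPARTMENTS)]
  pred <- c("none", roi_labels(seg))[unclass(seg$labels) + 1]
  keep <- !truth %in% c("cell_periphery", "droplet_periphery")
  mean(pred[keep] == truth[keep])
}
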