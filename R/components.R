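#' Connected components of a binary mask
#'
#' Labels connected foreground regions of a mask, by default with
#' 8-connectivity (diagonal neighbours connect), the convention used when
#' deriving cell instances from a thresholded projection. The 4-connected
#' labelling is delegated to `EBImage::bwlabel`; 8-connectivity is obtained
#' by merging labels that touch diagonally via union-find, then compacting
#' label ids to 1..n in raster order of first occurrence.
#'
#' @param mask binary matrix or mask [image2d()].
#' @param connectivity 4 or 8 (default 8).
#' @return a label [image2d()] with components numbered 1..n.
#' @export
label_components <- function(mask, connectivity = 8L) {
  m <- as_matrix2d(mask)
  if (!all(m %in% c(0, 1))) stop("mask must be binary")
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  if (connectivity == 8L && max(lab) > 1L) {
    nr <- nrow(lab)
    nc <- ncol(lab)
    ## pairs of different labels touching along either diagonal
    d1 <- cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1]))
    d2 <- cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))
    pairs <- rbind(d1, d2)
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      parent <- seq_len(max(lab))
      find <- function(x) {
        while (parent[x] != x) {
          parent[x] <<- parent[parent[x]]
          x <- parent[x]
        }
        x
      }
      for (i in seq_len(nrow(pairs))) {
        a <- find(pairs[i, 1])
        b <- find(pairs[i, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      roots <- vapply(seq_len(max(lab)), find, integer(1))
      lab[lab > 0L] <- roots[lab[lab > 0L]]
    }
  } else if (!connectivity %in% c(4L, 8L)) {
    stop("connectivity must be 4 or 8")
  }
  ## compact ids
  ids <- unique(lab[lab > 0L])
  if (length(ids)) {
    remap <- integer(max(ids))
    remap[ids] <- seq_along(ids)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  image2d(lab + 0, "label")
}
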