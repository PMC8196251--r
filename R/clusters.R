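# 3D connected-component labeling for suprathreshold voxel sets.
# Sparse union-find over the TRUE voxels only, so labeling cost scales
# with the suprathreshold count, not the grid — this is what keeps the
# permutation loop cheap under the null.

conn_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(off != 0)
  off <- switch(as.character(connectivity),
    "6"  = off[nz == 1, , drop = FALSE],
    "18" = off[nz >= 1 & nz <= 2, , drop = FALSE],
    "26" = off[nz >= 1, , drop = FALSE],
    stop("connectivity must be 6, 18 or 26"))
  # keep one of each +/- pair: edges are undirected
  off[off[, 3] > 0 | (off[, 3] == 0 & off[, 2] > 0) |
      (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0), , drop = FALSE]
}

#' Label connected components of a 3D binary map
#'
#' @param binmap 3D logical array (suprathreshold voxels TRUE).
#' @param connectivity Neighborhood: 6 (faces), 18 (+edges) or 26
#'   (+corners, the usual neuroimaging default).
#' @return Integer 3D array; 0 for background, components numbered 1..K
#'   in order of their first voxel in column-major order (deterministic).
#' @export
label_clusters <- function(binmap, connectivity = 26) {
  dims <- dim(binmap)
  if (length(dims) != 3L) stop("binmap must be a 3D array")
  binmap[is.na(binmap)] <- FALSE
  labels <- array(0L, dim = dims)
  idx <- which(binmap)
  nv <- length(idx)
  if (nv == 0L) return(labels)

  rank_of <- integer(prod(dims))   # linear index -> 1..nv (0 = not TRUE)
  rank_of[idx] <- seq_len(nv)
  coords <- arrayInd(idx, dims)
  parent <- seq_len(nv)

  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  for (off in seq_len(nrow(offsets <- conn_offsets(connectivity)))) {
    d <- offsets[off, ]
    nb <- sweep(coords, 2, d, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nidx <- (nb[ok, 3] - 1L) * dims[1] * dims[2] +
            (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
    j <- rank_of[nidx]
    has_edge <- j > 0L
    if (!any(has_edge)) next
    a <- which(ok)[has_edge]        # rank of source voxel
    b <- j[has_edge]
    for (e in seq_along(a)) {
      ra <- find_root(a[e]); rb <- find_root(b[e])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }

  roots <- vapply(seq_len(nv), find_root, integer(1))
  # components numbered by first occurrence in column-major voxel order
  comp <- match(roots, unique(roots))
  labels[idx] <- comp
  labels
}

#' Tabulate suprathreshold clusters of a statistic map
#'
#' @param stat_map 3D statistic array (NA outside the mask or where the
#'   statistic is undefined; NA voxels never enter a cluster).
#' @param threshold Cluster-forming threshold; voxels with statistic
#'   strictly greater are suprathreshold.
#' @param connectivity Passed to [label_clusters()].
#' @return Data frame: `cluster`, `extent`, `peak_x`, `peak_y`, `peak_z`
#'   (0-based voxel indices), `peak_stat`; zero rows if nothing survives.
#' @export
cluster_table <- function(stat_map, threshold, connectivity = 26) {
  supra <- !is.na(stat_map) & stat_map > threshold
  labels <- label_clusters(supra, connectivity)
  k <- max(labels)
  if (k == 0L)
    return(data.frame(cluster = integer(0), extent = integer(0),
                      peak_x = integer(0), peak_y = integer(0),
                      peak_z = integer(0), peak_stat = numeric(0)))
  idx <- which(labels > 0L)
  lab <- labels[idx]
  stat <- stat_map[idx]
  extents <- tabulate(lab, nbins = k)
  peak_rows <- vapply(seq_len(k), function(l) {
    in_l <- which(lab == l)
    in_l[which.max(stat[in_l])]
  }, integer(1))
  peaks <- arrayInd(idx[peak_rows], dim(stat_map)) - 1L  # 0-based
  data.frame(cluster = seq_len(k), extent = extents,
             peak_x = peaks[, 1], peak_y = peaks[, 2], peak_z = peaks[, 3],
             peak_stat = stat[peak_rows])
}
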