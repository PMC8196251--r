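# Similarity of spatial alteration patterns across SVD subtypes.
#
# Each subtype's unthresholded t map (subtype vs control) is flattened to
# an in-mask vector; pairwise Pearson correlation r gives the distance
# 1 - r; average-linkage agglomeration builds the dendrogram; the
# Calinski-Harabasz criterion picks the number of clusters.

#' Flatten statistic maps to pattern vectors
#'
#' @param statmaps Named list of 3D statistic arrays (or `"stat_map"`
#'   objects) on one grid.
#' @param mask 3D logical analysis mask (>= 3 voxels).
#' @return Matrix, one row per map, columns = in-mask voxels in a fixed
#'   (column-major) order.
#' @export
vectorize_statmaps <- function(statmaps, mask) {
  mask <- mask & !is.na(mask)
  if (sum(mask) < 3L) stop("mask must contain at least 3 voxels")
  maps <- lapply(statmaps, function(m) if (inherits(m, "stat_map")) m$map else m)
  if (!all(vapply(maps, function(m) identical(dim(m), dim(mask)), logical(1))))
    stop("all statistic maps must share the mask grid")
  V <- t(vapply(maps, function(m) m[mask], numeric(sum(mask))))
  if (anyNA(V)) stop("NA statistic inside the mask")
  vars <- apply(V, 1, stats::var)
  if (any(vars == 0))
    stop("constant (zero-variance) pattern vector: ",
         paste(rownames(V)[vars == 0], collapse = ", "))
  V
}

#' Correlation distance between pattern vectors
#'
#' @param vectors Matrix from [vectorize_statmaps()] (rows = patterns).
#' @return Symmetric matrix of `1 - r` (Pearson), zero diagonal, entries
#'   in `[0, 2]`.
#' @export
pattern_distance <- function(vectors) {
  if (nrow(vectors) < 2L) stop("need at least 2 pattern vectors")
  if (any(apply(vectors, 1, stats::var) == 0))
    stop("zero-variance pattern vector")
  d <- 1 - cor(t(vectors))
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) agglomeration
#'
#' Unweighted average inter-cluster distance; at each step the pair with
#' the smallest distance merges, ties broken by the lowest item index.
#' Returns an `hclust`-compatible tree so [stats::cutree()] applies.
#'
#' @param distances Symmetric distance matrix (e.g. [pattern_distance()]).
#' @return Object of class `"hclust"` (merge, height, order, labels).
#' @export
average_linkage <- function(distances) {
  d <- as.matrix(distances)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 items")
  if (any(abs(d - t(d)) > 1e-8) || any(diag(d) != 0))
    stop("distances must be symmetric with zero diagonal")
  labels <- rownames(d)
  # active clusters: id < 0 is singleton -i, id > 0 is merge row
  id <- -seq_len(n)
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  active <- seq_len(n)
  for (step in seq_len(n - 1L)) {
    best <- c(NA_integer_, NA_integer_); bestd <- Inf
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1L):length(active)) {
        a <- active[ii]; b <- active[jj]
        if (d[a, b] < bestd - 1e-15) { bestd <- d[a, b]; best <- c(a, b) }
      }
    }
    a <- best[1]; b <- best[2]
    merge[step, ] <- sort(c(id[a], id[b]))   # cutree only needs the topology
    height[step] <- bestd
    # unweighted average update on the representative row a
    nb_cols <- setdiff(active, c(a, b))
    if (length(nb_cols)) {
      newd <- (size[a] * d[a, nb_cols] + size[b] * d[b, nb_cols]) /
              (size[a] + size[b])
      d[a, nb_cols] <- newd; d[nb_cols, a] <- newd
    }
    size[a] <- size[a] + size[b]
    id[a] <- step
    active <- setdiff(active, b)
  }
  tree <- list(merge = merge, height = height,
               order = order_dendrogram(merge, n),
               labels = labels, method = "average",
               dist.method = "1 - Pearson r")
  class(tree) <- "hclust"
  tree
}

# leaf order for plotting: recursive left-to-right traversal
order_dendrogram <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(n - 1L)
}

# Calinski-Harabasz index for a membership vector on row vectors
calinski_harabasz <- function(vectors, membership) {
  n <- nrow(vectors); k <- length(unique(membership))
  if (k < 2L || k >= n) return(NA_real_)
  grand <- colMeans(vectors)
  ssw <- 0; ssb <- 0
  for (g in unique(membership)) {
    rows <- vectors[membership == g, , drop = FALSE]
    cen <- colMeans(rows)
    ssw <- ssw + sum(sweep(rows, 2, cen)^2)
    ssb <- ssb + nrow(rows) * sum((cen - grand)^2)
  }
  if (ssb + ssw == 0) return(NA_real_)
  if (ssw == 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Cluster subtype patterns and select k by Calinski-Harabasz
#'
#' Builds the `1 - r` distance, the average-linkage tree, evaluates the
#' Calinski-Harabasz criterion at each candidate cut, and selects the
#' maximizing k (ties and within-tolerance ties go to the smallest k).
#'
#' @param vectors Matrix of pattern vectors (rows = subtypes).
#' @param ks Candidate cluster counts; default `2:(n-1)`.
#' @return Object of class `"cluster_solution"`: `distance`, `tree`,
#'   `ch` (named by k), `k` (selected, or NA if degenerate), `membership`.
#' @export
select_k_calinski <- function(vectors, ks = NULL) {
  n <- nrow(vectors)
  if (n < 3L) stop("need at least 3 pattern vectors to select k")
  if (is.null(ks)) ks <- 2:(n - 1)
  if (any(ks < 2 | ks > n - 1)) stop("candidate ks must lie in 2..n-1")
  d <- pattern_distance(vectors)
  if (max(d) < 1e-8) {
    warning("all patterns are identical up to numerical noise ",
            "(max 1 - r < 1e-8); Calinski-Harabasz is degenerate, ",
            "no k selected")
    return(structure(list(distance = d, tree = average_linkage(d),
                          ch = setNames(rep(NA_real_, length(ks)), ks),
                          k = NA_integer_, membership = NULL),
                     class = "cluster_solution"))
  }
  tree <- average_linkage(d)
  ch <- vapply(ks, function(k)
    calinski_harabasz(vectors, cutree(tree, k = k)), numeric(1))
  names(ch) <- ks
  if (all(is.na(ch))) {
    k_sel <- NA_integer_
    membership <- NULL
    warning("Calinski-Harabasz degenerate (no between-cluster dispersion); ",
            "no k selected")
  } else {
    k_sel <- ks[which.max(ch)]   # which.max takes the first (smallest k) tie
    membership <- cutree(tree, k = k_sel)
  }
  structure(list(distance = d, tree = tree, ch = ch, k = k_sel,
                 membership = membership),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("pattern clustering (1 - r, average linkage)\n")
  cat("Calinski-Harabasz by k:\n")
  print(round(x$ch, 3))
  if (is.na(x$k)) cat("no k selected (degenerate)\n")
  else {
    cat("selected k =", x$k, "\n")
    print(x$membership)
  }
  invisible(x)
}
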