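# Shared fixtures and independent oracles, built in code.

# tiny cohort spec: `n` subjects per group, fast to generate
tiny_spec <- function(n = 12, seed = 101) {
  cohort_spec(n_per_group = setNames(rep(n, 5), SVD_GROUPS()), seed = seed)
}

SVD_GROUPS <- function() c("control", "type1", "type2", "type3", "type4")

# small image world on a 16^3 grid with 4 well-separated blobs
tiny_image_spec <- function(..., seed = 202) {
  image_effect_spec(
    grid_shape = c(16, 16, 16),
    blob_centers = rbind(c(5, 5, 5), c(11, 11, 6), c(6, 11, 11),
                         c(11, 6, 11)),
    blob_radii = rep(2.5, 4),
    seed = seed, ...)
}

# --- independent oracles ---------------------------------------------------

# brute-force Kruskal-Wallis H via the plain rank formula (no reuse of the
# package path beyond base rank())
oracle_kw_H <- function(values, groups) {
  g <- factor(groups)
  n <- length(values)
  r <- rank(values)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# full hypergeometric enumeration of the two-sided Fisher p for a 2x2 table
oracle_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  obs <- dhyper(tab[1, 1], m, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# brute-force flood-fill connected-component labeling on a 3D logical array
oracle_flood_fill <- function(binmap, connectivity) {
  dims <- dim(binmap)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(off != 0)
  off <- switch(as.character(connectivity),
                "6" = off[nz == 1, , drop = FALSE],
                "18" = off[nz >= 1 & nz <= 2, , drop = FALSE],
                "26" = off[nz >= 1, , drop = FALSE])
  labels <- array(0L, dims)
  nextlab <- 0L
  for (i in seq_len(prod(dims))) {
    if (!binmap[i] || labels[i] > 0L) next
    nextlab <- nextlab + 1L
    queue <- matrix(arrayInd(i, dims), ncol = 3)
    labels[i] <- nextlab
    while (nrow(queue)) {
      v <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      for (o in seq_len(nrow(off))) {
        nb <- v + off[o, ]
        if (any(nb < 1) || any(nb > dims)) next
        if (binmap[nb] && labels[nb] == 0L) {
          labels[nb] <- nextlab
          queue <- rbind(queue, nb)
        }
      }
    }
  }
  labels
}

# do two labelings define the same partition of the TRUE voxels?
same_partition <- function(lab1, lab2) {
  idx <- which(lab1 > 0)
  if (!identical(which(lab2 > 0), idx)) return(FALSE)
  key <- paste(lab1[idx], lab2[idx])
  length(unique(key)) == length(unique(lab1[idx])) &&
    length(unique(key)) == length(unique(lab2[idx]))
}

# brute-force UPGMA: returns successive merge heights (for comparison with
# average_linkage) computed by direct recomputation of all pairwise average
# distances between current clusters at every step
oracle_upgma_heights <- function(d0) {
  d0 <- as.matrix(d0)
  clusters <- as.list(seq_len(nrow(d0)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1):length(clusters)) {
        dd <- mean(d0[clusters[[i]], clusters[[j]]])
        if (dd < bestd - 1e-15) { bestd <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}
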