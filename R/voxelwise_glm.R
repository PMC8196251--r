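# Permutation-based voxel-wise ANCOVA.
#
# Model per voxel: y = G b_g + C b_c + e, with G the per-group indicator
# (cell-means) columns of interest and C the nuisance covariates (age,
# sex, TIV) plus intercept.  Inference is nonparametric: the null
# distribution of the maximum suprathreshold cluster extent is built by
# Freedman-Lane permutation of the nuisance-model residuals, giving
# cluster-level family-wise-error corrected p-values.

#' Build a voxel-wise ANCOVA design from a subject table
#'
#' Cell-means coding: one indicator column per group present (ordered
#' control, type1..type4), plus mean-centered nuisance covariates.  The
#' group columns are the columns of interest; the intercept is implicit
#' in the group indicators (the nuisance-only model used for permutation
#' adds its own intercept).
#'
#' @param subjects Data frame with a group column and the covariates.
#' @param group_col Name of the group column.
#' @param covariates Covariate column names; a character `sex` column is
#'   recoded male = 1 / female = 0.
#' @param groups Groups to include, in order; default: those present,
#'   ordered as `control, type1..type4`.
#' @return Object of class `"voxel_design"`: `X` (n x p), `interest`
#'   (group column indices), `nuisance` (covariate indices), `groups`,
#'   `group_n`.
#' @export
design_matrix <- function(subjects, group_col = "svd_class",
                          covariates = c("age", "sex", "tiv"),
                          groups = NULL) {
  gl <- as.character(subjects[[group_col]])
  if (is.null(groups)) groups <- SVD_GROUPS[SVD_GROUPS %in% gl]
  keep <- gl %in% groups
  subjects <- subjects[keep, , drop = FALSE]
  gl <- gl[keep]
  n <- nrow(subjects)
  if (n == 0L) stop("no subjects in the requested groups")
  G <- sapply(groups, function(g) as.numeric(gl == g))
  if (any(colSums(G) < 2))
    stop("need >= 2 subjects per group; short: ",
         paste(groups[colSums(G) < 2], collapse = ", "))
  C <- NULL
  if (length(covariates)) {
    C <- sapply(covariates, function(v) {
      x <- subjects[[v]]
      if (!is.numeric(x)) x <- as.numeric(x == "male")
      x - mean(x)
    })
  }
  X <- cbind(G, C)
  colnames(X) <- c(groups, covariates)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  structure(list(X = X, interest = seq_along(groups),
                 nuisance = if (length(covariates))
                   length(groups) + seq_along(covariates) else integer(0),
                 groups = groups, group_n = colSums(G), keep = which(keep)),
            class = "voxel_design")
}

#' Contrast over the group (interest) columns
#'
#' @param type `"t"` (one-sided t on a weight vector), `"F"` (omnibus
#'   equality of the group means), or `"trend"` (ordered linear contrast).
#' @param weights For `"t"`: weights over the design's group columns, not
#'   all zero.  For `"trend"`: defaults to `c(-3, -1, 1, 3)` ascending
#'   over 4 ordered groups (reversed for descending); must sum to zero.
#' @param direction For `"trend"`: `"ascending"` or `"descending"`.
#' @return Object of class `"glm_contrast"`.
#' @export
contrast_spec <- function(type = c("t", "F", "trend"), weights = NULL,
                          direction = c("ascending", "descending")) {
  type <- match.arg(type)
  direction <- match.arg(direction)
  if (type == "trend") {
    if (is.null(weights)) weights <- c(-3, -1, 1, 3)
    if (direction == "descending") weights <- -weights
    if (abs(sum(weights)) > 1e-12) stop("trend weights must sum to zero")
  }
  if (type == "t" && (is.null(weights) || all(weights == 0)))
    stop("a t contrast needs nonzero weights")
  structure(list(type = type, weights = weights, direction = direction),
            class = "glm_contrast")
}

# Flatten a 4D array / list of 3D maps to the n x V in-mask data matrix.
images_to_matrix <- function(images, mask) {
  if (is.list(images)) {
    dims <- dim(images[[1]])
    if (!all(vapply(images, function(m) identical(dim(m), dims), logical(1))))
      stop("all images must share one grid")
    images <- array(unlist(images, use.names = FALSE), dim = c(dims, length(images)))
    images <- aperm(images, c(4, 1, 2, 3))
  } else if (length(dim(images)) == 4L) {
    # stored (x, y, z, subject); bring subjects to rows
    images <- aperm(images, c(4, 1, 2, 3))
  } else stop("images must be a 4D array or a list of 3D arrays")
  if (!identical(dim(images)[-1], dim(mask)))
    stop("image grid does not match the mask grid")
  n <- dim(images)[1]
  matrix(images, nrow = n)[, as.vector(mask), drop = FALSE]
}

stat_to_map <- function(stat, mask) {
  out <- array(NA_real_, dim = dim(mask))
  out[mask] <- stat
  out
}

# Core per-voxel OLS statistics on a data matrix (n x V).
# Returns list(stat, df, df1); degenerate voxels (zero residual variance)
# get NA.
voxel_stats <- function(Y, design, contrast) {
  X <- design$X
  n <- nrow(X); p <- ncol(X)
  XtXinv <- solve(crossprod(X))
  B <- XtXinv %*% crossprod(X, Y)              # p x V
  RSS <- colSums((Y - X %*% B)^2)
  df <- n - p
  degen <- RSS <= max(RSS, 1) * 1e-12
  s2 <- RSS / df
  if (contrast$type == "F") {
    # reduced model: common mean + nuisance
    X0 <- cbind(1, X[, design$nuisance, drop = FALSE])
    B0 <- solve(crossprod(X0), crossprod(X0, Y))
    RSS0 <- colSums((Y - X0 %*% B0)^2)
    q <- length(design$interest) - 1L
    stat <- ((RSS0 - RSS) / q) / s2
    stat[degen] <- NA_real_
    list(stat = stat, df = df, df1 = q)
  } else {
    w <- contrast$weights
    if (length(w) != length(design$interest))
      stop("contrast has ", length(w), " weights for ",
           length(design$interest), " group columns")
    cvec <- numeric(p)
    cvec[design$interest] <- w
    eff <- drop(crossprod(cvec, B))            # c'beta per voxel
    cXXc <- drop(t(cvec) %*% XtXinv %*% cvec)
    stat <- eff / sqrt(s2 * cXXc)
    stat[degen] <- NA_real_
    list(stat = stat, df = df, df1 = 1L)
  }
}

#' Fit the voxel-wise GLM and return a statistic map
#'
#' @param images 4D array (x, y, z, subject) or list of 3D arrays, in the
#'   row order of the design.
#' @param mask 3D logical analysis mask.
#' @param design A [design_matrix()].
#' @param contrast A [contrast_spec()].
#' @return Object of class `"stat_map"`: `map` (3D array, NA outside the
#'   mask and at degenerate voxels), `df`, `df1`, `contrast`, `mask`.
#' @export
fit_glm <- function(images, mask, design, contrast) {
  mask <- mask & !is.na(mask)
  Y <- images_to_matrix(images, mask)
  if (nrow(Y) != nrow(design$X))
    stop("number of images (", nrow(Y), ") != design rows (",
         nrow(design$X), ")")
  vs <- voxel_stats(Y, design, contrast)
  structure(list(map = stat_to_map(vs$stat, mask), df = vs$df,
                 df1 = vs$df1, contrast = contrast, mask = mask),
            class = "stat_map")
}

#' Permutation configuration
#'
#' @param n_permutations Random permutations for the max-cluster null
#'   distribution (default 10000; reduce for desk-scale runs).  If the
#'   full permutation space is no larger, it is enumerated exactly.
#' @param cluster_forming_t Primary threshold on the t map (default 3.1).
#'   F maps use the F value whose upper-tail probability matches this t
#'   at the error df.
#' @param alpha Cluster-level FWE significance level.
#' @param connectivity 6, 18 or 26.
#' @param seed Integer RNG seed for the permutation draw.
#' @return Object of class `"permutation_config"`.
#' @export
permutation_config <- function(n_permutations = 10000,
                               cluster_forming_t = 3.1, alpha = 0.05,
                               connectivity = 26, seed = NULL) {
  if (!is.numeric(n_permutations) || n_permutations < 1)
    stop("n_permutations must be >= 1")
  if (cluster_forming_t <= 0) stop("cluster_forming_t must be > 0")
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  if (n_permutations < 1 / alpha - 1)
    warning("n_permutations < 1/alpha: the smallest attainable FWE p (",
            signif(1 / (n_permutations + 1), 3), ") exceeds alpha")
  structure(list(n_permutations = as.integer(n_permutations),
                 cluster_forming_t = cluster_forming_t, alpha = alpha,
                 connectivity = connectivity, seed = seed),
            class = "permutation_config")
}

# F threshold with the same upper-tail probability as t = t_thr
f_threshold_matching_t <- function(t_thr, df1, df2) {
  p <- pt(t_thr, df2, lower.tail = FALSE)
  qf(p, df1, df2, lower.tail = FALSE)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Permutation-based cluster-level FWE inference
#'
#' Freedman-Lane scheme: the data are residualized against the nuisance
#' model (intercept + covariates), residuals are row-permuted and added
#' back to the nuisance fit, and the full model is refit per permutation.
#' The maximum suprathreshold cluster extent across each permuted map
#' forms the null; observed clusters get p = (1 + #\{null >= extent\}) /
#' (P + 1), or the exact enumeration fraction when the full permutation
#' group is no larger than the request.
#'
#' @inheritParams fit_glm
#' @param config A [permutation_config()].
#' @return Object of class `"cluster_inference"`: `stat_map` (a
#'   `"stat_map"`), `clusters` (a [cluster_table()] with `p_fwe`),
#'   `threshold` (cluster-forming value actually used), `null_max`
#'   (null max-extent distribution), `exact` (TRUE if enumerated),
#'   `config`.
#' @export
permutation_cluster_inference <- function(images, mask, design, contrast,
                                          config = permutation_config()) {
  stopifnot(inherits(config, "permutation_config"))
  mask <- mask & !is.na(mask)
  Y <- images_to_matrix(images, mask)
  n <- nrow(Y)
  if (n != nrow(design$X)) stop("images and design disagree on n")

  vs <- voxel_stats(Y, design, contrast)
  thr <- if (contrast$type == "F")
    f_threshold_matching_t(config$cluster_forming_t, vs$df1, vs$df)
  else config$cluster_forming_t
  obs_map <- stat_to_map(vs$stat, mask)
  obs_clusters <- cluster_table(obs_map, thr, config$connectivity)

  # Freedman-Lane: residualize against intercept + nuisance covariates
  Z <- cbind(1, design$X[, design$nuisance, drop = FALSE])
  BZ <- solve(crossprod(Z), crossprod(Z, Y))
  fitted0 <- Z %*% BZ
  E <- Y - fitted0

  exact <- FALSE
  n_fact <- factorial(n)
  if (n <= 9 && n_fact <= config$n_permutations) {
    perms <- all_permutations(n)
    exact <- TRUE
  } else {
    if (!is.null(config$seed)) set.seed(config$seed)
    perms <- t(replicate(config$n_permutations, sample.int(n)))
  }

  null_max <- apply(perms, 1, function(pr) {
    Ystar <- fitted0 + E[pr, , drop = FALSE]
    st <- voxel_stats(Ystar, design, contrast)$stat
    supra <- stat_to_map(st, mask) > thr
    supra[is.na(supra)] <- FALSE
    if (!any(supra)) return(0L)
    max(tabulate(label_clusters(supra, config$connectivity)))
  })

  if (nrow(obs_clusters)) {
    obs_clusters$p_fwe <- if (exact) {
      vapply(obs_clusters$extent,
             function(e) mean(null_max >= e), numeric(1))
    } else {
      vapply(obs_clusters$extent,
             function(e) (1 + sum(null_max >= e)) / (length(null_max) + 1),
             numeric(1))
    }
  } else obs_clusters$p_fwe <- numeric(0)

  structure(list(
    stat_map = structure(list(map = obs_map, df = vs$df, df1 = vs$df1,
                              contrast = contrast, mask = mask),
                         class = "stat_map"),
    clusters = obs_clusters, threshold = thr, null_max = null_max,
    exact = exact, config = config),
    class = "cluster_inference")
}

#' @export
print.cluster_inference <- function(x, ...) {
  cat(sprintf(
    "cluster inference: %s contrast, forming threshold %.3f, %d %s permutations\n",
    x$stat_map$contrast$type, x$threshold, length(x$null_max),
    if (x$exact) "exact" else "random"))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  else cat("no suprathreshold clusters\n")
  invisible(x)
}

#' Ordered trend inference across SVD subtypes
#'
#' Linear trend t contrast over ordered groups (default weights
#' `[-3, -1, +1, +3]` ascending, reversed for descending), followed by
#' the same permutation cluster-level FWE inference as
#' [permutation_cluster_inference()].
#'
#' @inheritParams permutation_cluster_inference
#' @param direction `"ascending"` (statistic increases along the group
#'   order) or `"descending"`.
#' @param weights Trend weights; length must equal the number of group
#'   columns in the design.
#' @return A `"cluster_inference"` object.
#' @export
trend_inference <- function(images, mask, design,
                            direction = c("ascending", "descending"),
                            config = permutation_config(),
                            weights = c(-3, -1, 1, 3)) {
  direction <- match.arg(direction)
  if (length(design$interest) != length(weights))
    stop("design has ", length(design$interest), " group columns but the ",
         "trend contrast has ", length(weights), " weights")
  ct <- contrast_spec("trend", weights = weights, direction = direction)
  permutation_cluster_inference(images, mask, design, ct, config)
}

#' Binary significance mask from a cluster inference
#'
#' @param inference A `"cluster_inference"`.
#' @param alpha FWE level (defaults to the one in its config).
#' @return 3D logical array: voxels in FWE-significant clusters.
#' @export
significant_voxels <- function(inference, alpha = NULL) {
  stopifnot(inherits(inference, "cluster_inference"))
  if (is.null(alpha)) alpha <- inference$config$alpha
  out <- array(FALSE, dim = dim(inference$stat_map$map))
  sig <- inference$clusters$cluster[inference$clusters$p_fwe <= alpha]
  if (!length(sig)) return(out)
  supra <- !is.na(inference$stat_map$map) &
    inference$stat_map$map > inference$threshold
  labels <- label_clusters(supra, inference$config$connectivity)
  out[labels %in% sig] <- TRUE
  out
}
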