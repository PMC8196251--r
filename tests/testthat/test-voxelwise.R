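# hand-built two-group image world: group 2 carries `effect` inside a blob
two_group_images <- function(n_per = 20, dims = c(10, 10, 10), effect = 1,
                             noise_sd = 1, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  blob <- array(FALSE, dims); blob[4:6, 4:6, 4:6] <- TRUE
  images <- array(rnorm(prod(dims) * n, sd = noise_sd), c(dims, n))
  for (i in (n_per + 1):n) images[, , , i] <- images[, , , i] + blob * effect
  mask <- array(TRUE, dims)
  subjects <- data.frame(svd_class = rep(c("control", "type1"), each = n_per),
                         age = runif(n, 50, 80),
                         sex = sample(c("male", "female"), n, replace = TRUE),
                         tiv = rnorm(n, 1.4e6, 1e5))
  list(images = images, mask = mask, blob = blob, subjects = subjects)
}

test_that("t map matches per-voxel lm() and F equals t^2 for one contrast", {
  w <- two_group_images(n_per = 12, dims = c(6, 6, 6), effect = 0.8)
  design <- design_matrix(w$subjects, "svd_class")
  ct <- contrast_spec("t", weights = c(-1, 1))
  sm <- fit_glm(w$images, w$mask, design, ct)
  fm <- fit_glm(w$images, w$mask, design, contrast_spec("F"))
  expect_equal(fm$map, sm$map^2, tolerance = 1e-8)   # q = 1 identity

  # closed-form OLS oracle at a handful of voxels
  idx <- rbind(c(1, 1, 1), c(4, 4, 4), c(6, 2, 5))
  for (r in seq_len(nrow(idx))) {
    y <- w$images[idx[r, 1], idx[r, 2], idx[r, 3], ]
    fit <- lm(y ~ 0 + design$X)
    est <- coef(summary(fit))
    tref <- (est[2, 1] - est[1, 1]) /
      sqrt(t(c(-1, 1, 0, 0, 0)) %*% vcov(fit) %*% c(-1, 1, 0, 0, 0))
    expect_equal(sm$map[idx[r, 1], idx[r, 2], idx[r, 3]], drop(tref),
                 tolerance = 1e-8)
  }
  expect_identical(sm$df, nrow(design$X) - ncol(design$X))
})

test_that("null contrast t values center on zero; planted effect matches the
           closed-form noncentrality", {
  w <- two_group_images(n_per = 20, dims = c(10, 10, 10), effect = 1,
                        noise_sd = 1, seed = 3)
  design <- design_matrix(w$subjects, "svd_class", covariates = character(0))
  sm <- fit_glm(w$images, w$mask, design, contrast_spec("t", weights = c(-1, 1)))
  outside <- sm$map[!w$blob]
  expect_lt(abs(mean(outside)), 3 / sqrt(length(outside)))

  ncp <- 1 / sqrt(1 / 20 + 1 / 20)         # effect / (sd * sqrt(1/n1 + 1/n2))
  inside <- sm$map[w$blob]
  expect_lt(abs(mean(inside) - ncp), 2 * sd(inside) / sqrt(length(inside)) + 0.1)
})

test_that("zero residual variance is flagged, not infinite", {
  dims <- c(5, 5, 5)
  n <- 8
  images <- array(0, c(dims, n))
  for (i in 5:8) images[, , , i] <- 1      # noise-free group difference
  subjects <- data.frame(svd_class = rep(c("control", "type1"), each = 4))
  design <- design_matrix(subjects, "svd_class", covariates = character(0))
  sm <- fit_glm(images, array(TRUE, dims), design,
                contrast_spec("t", weights = c(-1, 1)))
  expect_true(all(is.na(sm$map)))
  tab <- cluster_table(sm$map, threshold = 3.1)
  expect_identical(nrow(tab), 0L)          # flagged voxels never cluster
})

test_that("permutation inference is seeded, monotone and bounded", {
  w <- two_group_images(n_per = 15, dims = c(8, 8, 8), effect = 1.5, seed = 5)
  design <- design_matrix(w$subjects, "svd_class")
  cfg <- permutation_config(n_permutations = 150, seed = 42)
  ct <- contrast_spec("t", weights = c(-1, 1))
  inf1 <- permutation_cluster_inference(w$images, w$mask, design, ct, cfg)
  inf2 <- permutation_cluster_inference(w$images, w$mask, design, ct, cfg)
  expect_identical(inf1$clusters, inf2$clusters)
  expect_false(inf1$exact)
  expect_true(all(inf1$clusters$p_fwe >= 1 / 151))
  expect_true(all(inf1$clusters$p_fwe <= 1))
  ord <- order(inf1$clusters$extent)
  expect_true(all(diff(inf1$clusters$p_fwe[ord]) <= 1e-12))

  # vacuous forming threshold: empty table
  expect_warning(cfg_hi <- permutation_config(n_permutations = 10,
    cluster_forming_t = 1e6, seed = 1), "alpha")
  inf_hi <- permutation_cluster_inference(w$images, w$mask, design, ct, cfg_hi)
  expect_identical(nrow(inf_hi$clusters), 0L)
})

test_that("small samples enumerate the exact permutation group", {
  dims <- c(4, 4, 4)
  set.seed(8)
  n <- 5
  images <- array(rnorm(prod(dims) * n), c(dims, n))
  subjects <- data.frame(svd_class = rep(c("control", "type1"), c(3, 2)))
  design <- design_matrix(subjects, "svd_class", covariates = character(0))
  cfg <- permutation_config(n_permutations = 200, cluster_forming_t = 2,
                            seed = 9)
  inf <- permutation_cluster_inference(images, array(TRUE, dims), design,
                                       contrast_spec("t", c(-1, 1)), cfg)
  expect_true(inf$exact)
  expect_identical(length(inf$null_max), 120L)   # 5! permutations
  if (nrow(inf$clusters))
    expect_true(all(inf$clusters$p_fwe >= 1 / 120))
})

test_that("trend contrast behaves at its limits", {
  dims <- c(6, 6, 6)
  groups <- c("control", "type1", "type2", "type3")
  n_per <- 5
  subjects <- data.frame(svd_class = rep(groups, each = n_per))
  design <- design_matrix(subjects, "svd_class", covariates = character(0))
  weights <- c(-3, -1, 1, 3)
  set.seed(13)
  images <- array(rnorm(prod(dims) * n_per * 4, sd = 1e-6), c(dims, n_per * 4))
  for (i in seq_len(n_per * 4))
    images[, , , i] <- images[, , , i] + weights[ceiling(i / n_per)]
  mask <- array(TRUE, dims)
  cfg <- permutation_config(n_permutations = 50, seed = 2)
  asc <- trend_inference(images, mask, design, "ascending", cfg)
  # perfect ascending trend: every voxel suprathreshold, one full-grid cluster
  expect_identical(sum(asc$clusters$extent), as.integer(prod(dims)))
  expect_true(all(asc$stat_map$map > cfg$cluster_forming_t, na.rm = TRUE))
  # the descending contrast sees nothing
  desc <- trend_inference(images, mask, design, "descending", cfg)
  expect_identical(nrow(desc$clusters), 0L)

  bad_design <- design_matrix(subjects[subjects$svd_class != "type3", ,
                                       drop = FALSE],
                              "svd_class", covariates = character(0))
  expect_error(trend_inference(images[, , , 1:15], mask, bad_design,
                               "ascending", cfg),
               "weights")
})

test_that("significant_voxels maps FWE-significant clusters back to the grid", {
  w <- two_group_images(n_per = 15, dims = c(8, 8, 8), effect = 2, seed = 6)
  design <- design_matrix(w$subjects, "svd_class")
  inf <- permutation_cluster_inference(
    w$images, w$mask, design, contrast_spec("t", c(-1, 1)),
    permutation_config(n_permutations = 100, seed = 3))
  sig <- significant_voxels(inf)
  if (any(inf$clusters$p_fwe <= 0.05)) {
    expect_identical(sum(sig),
                     sum(inf$clusters$extent[inf$clusters$p_fwe <= 0.05]))
    expect_gt(sum(sig & w$blob) / sum(w$blob), 0.5)
  }
})
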