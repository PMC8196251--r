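test_that("cohort generation honors counts, groups and the seed contract", {
  spec <- tiny_spec(10, seed = 55)
  co <- generate_cohort(spec)
  expect_identical(nrow(co), 50L)
  expect_identical(length(unique(co$group)), 5L)
  expect_identical(as.vector(table(co$group)), rep(10L, 5))

  # same spec, same seed: byte-identical tables
  expect_identical(co, generate_cohort(spec))
  # different seed: different draws
  expect_false(identical(co, generate_cohort(tiny_spec(10, seed = 56))))

  expect_error(cohort_spec(n_per_group = rep(0, 5)), "n_per_group")
  expect_error(cohort_spec(lacune_rate = c(0, 0, 1, 2, 0)), "probabilities")
  expect_error(cohort_spec(age_mean = 1:3), "per group")
})

test_that("markers are consistent with the intended group", {
  co <- generate_cohort(tiny_spec(30, seed = 7))
  by_group <- split(co, co$group)
  # bleeding groups
  expect_true(all(by_group$type3$cmb_deep + by_group$type3$cmb_infratentorial >= 1))
  expect_true(all(by_group$type4$cmb_lobar >= 1))
  expect_true(all(by_group$type4$cmb_deep == 0))
  expect_true(all(by_group$type4$cmb_infratentorial == 0))
  # non-bleeding groups carry no CMB
  for (g in c("control", "type1", "type2"))
    expect_true(all(by_group[[g]]$cmb_lobar + by_group[[g]]$cmb_deep +
                    by_group[[g]]$cmb_infratentorial == 0))
  # WMH severity by construction (generative boundary 0.0007)
  expect_true(all(by_group$control$wmh_volume / by_group$control$tiv < 7e-4))
  expect_true(all(by_group$type1$wmh_volume / by_group$type1$tiv > 7e-4))
  expect_true(all(by_group$type2$lacune_count >= 1))
  expect_true(all(by_group$control$lacune_count == 0))
  expect_true(all(co$tiv > 0))
})

test_that("generated marker prevalences converge to the specified rates", {
  # 3 Monte-Carlo SE around the type-4 lacune rate of 11.8% at large n
  n <- 2000
  spec <- cohort_spec(n_per_group = setNames(c(5, 5, 5, n, n), SVD_GROUPS()),
                      seed = 99)
  co <- generate_cohort(spec)
  p4 <- mean(co$lacune_count[co$group == "type4"] >= 1)
  se <- sqrt(0.118 * 0.882 / n)
  expect_lt(abs(p4 - 0.118), 3 * se)
  p3 <- mean(co$lacune_count[co$group == "type3"] >= 1)
  expect_lt(abs(p3 - 0.426), 3 * sqrt(0.426 * 0.574 / n))
  # severe-WMH rates for the bleeding groups
  thr <- spec$wmh_severe_cut
  s4 <- mean(co$wmh_volume[co$group == "type4"] /
             co$tiv[co$group == "type4"] > thr)
  expect_lt(abs(s4 - 0.559), 3 * sqrt(0.559 * 0.441 / n))
})

test_that("image generation: seed determinism and the stated construction", {
  co <- generate_cohort(tiny_spec(6, seed = 3))
  ispec <- tiny_image_spec(seed = 11)
  im1 <- generate_images(co, ispec)
  im2 <- generate_images(co, ispec)
  expect_identical(im1$images, im2$images)
  expect_identical(dim(im1$images), c(16L, 16L, 16L, 30L))
  expect_true(all(im1$atlas[im1$mask] %in% 1:7))
  expect_true(all(im1$atlas[!im1$mask] == 0L))

  # noise-free limit with zero covariates: blob voxel = baseline + effect
  ispec0 <- tiny_image_spec(noise_sd = 1e-12,
                            covariate_betas = c(age = 0, sex = 0, tiv = 0),
                            seed = 12)
  im0 <- generate_images(co, ispec0)
  blob1 <- sphere_center <- ispec0$blob_centers[1, ]
  i_t3 <- which(co$group == "type3")[1]
  expect_equal(im0$images[blob1[1], blob1[2], blob1[3], i_t3],
               unname(ispec0$baseline + ispec0$effect_sizes["type3", 1]),
               tolerance = 1e-6)
  i_ctrl <- which(co$group == "control")[1]
  expect_equal(im0$images[blob1[1], blob1[2], blob1[3], i_ctrl],
               ispec0$baseline, tolerance = 1e-6)

  expect_error(image_effect_spec(grid_shape = c(6, 6, 6)), "too small")
  expect_error(image_effect_spec(noise_sd = 0), "noise_sd")
  expect_error(generate_images(co[0, ], ispec), "empty")
})

test_that("null images: group mean differences are O(noise/sqrt(n)) only", {
  co <- generate_cohort(tiny_spec(25, seed = 21))
  ispec <- tiny_image_spec(
    effect_sizes = matrix(0, 5, 4,
                          dimnames = list(SVD_GROUPS(), NULL)),
    covariate_betas = c(age = 0, sex = 0, tiv = 0), seed = 22)
  im <- generate_images(co, ispec)
  v <- ispec$blob_centers[1, ]
  vals <- im$images[v[1], v[2], v[3], ]
  means <- tapply(vals, co$group, mean)
  # each group mean is within 4 SE of the common baseline
  expect_true(all(abs(means - ispec$baseline) < 4 * 1 / sqrt(25)))
})

test_that("a fitted GLM recovers the planted blob effect within 2 SE", {
  spec <- cohort_spec(n_per_group = setNames(c(30, 30, 2, 2, 2), SVD_GROUPS()),
                      seed = 31)
  co <- generate_cohort(spec)
  ispec <- tiny_image_spec(
    effect_sizes = rbind(control = c(0, 0, 0, 0), type1 = c(1, 0, 0, 0),
                         type2 = 0 * 1:4, type3 = 0 * 1:4, type4 = 0 * 1:4),
    seed = 32)
  im <- generate_images(co, ispec)
  keep <- co$group %in% c("control", "type1")
  design <- design_matrix(co[keep, ], "group")
  sm <- fit_glm(im$images[, , , keep], im$mask, design,
                contrast_spec("t", weights = c(-1, 1)))
  v <- ispec$blob_centers[1, ]
  tval <- sm$map[v[1], v[2], v[3]]
  ncp <- 1 / sqrt(1 / 30 + 1 / 30)
  expect_lt(abs(tval - ncp), 3)   # t ~ noncentral t, sd ~ 1 at this df
})

test_that("Gaussian smoothing matches brute-force separable convolution", {
  set.seed(23)
  img <- array(rnorm(5 * 6 * 7), c(5, 6, 7))
  sigma <- 1.2
  r <- ceiling(3 * sigma)
  k <- dnorm(-r:r, sd = sigma); k <- k / sum(k)
  ref <- array(0, dim(img))
  for (x in 1:5) for (y in 1:6) for (z in 1:7) {
    acc <- 0
    for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
      xx <- x + dx; yy <- y + dy; zz <- z + dz
      if (xx >= 1 && xx <= 5 && yy >= 1 && yy <= 6 && zz >= 1 && zz <= 7)
        acc <- acc + img[xx, yy, zz] * k[dx + r + 1] * k[dy + r + 1] *
          k[dz + r + 1]
    }
    ref[x, y, z] <- acc
  }
  expect_equal(gaussian_smooth_3d(img, sigma), ref, tolerance = 1e-12)
  expect_identical(gaussian_smooth_3d(img, 0), img)
  # smoothing shrinks voxel variance of white noise
  big <- array(rnorm(20^3), c(20, 20, 20))
  expect_lt(sd(gaussian_smooth_3d(big, 1.7)), 0.3 * sd(big))
})
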