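test_that("Kruskal-Wallis H matches the hand computation and base R", {
  kw <- kruskal_wallis(1:9, rep(letters[1:3], each = 3))
  expect_equal(kw$H, 7.2)                 # rank sums 6/15/24, no ties
  expect_identical(kw$df, 2L)

  expect_equal(kruskal_wallis(rep(3, 10), rep(1:2, 5))$H, 0)
  expect_equal(kruskal_wallis(rep(3, 10), rep(1:2, 5))$p.value, 1)

  set.seed(31)
  for (i in 1:25) {                        # oracle sweep with ties, n <= 12
    n <- sample(6:12, 1)
    v <- sample(1:5, n, replace = TRUE)    # heavy ties
    g <- sample(1:3, n, replace = TRUE)
    if (length(unique(g)) < 2) next
    ref <- suppressWarnings(stats::kruskal.test(v, factor(g)))
    kw <- kruskal_wallis(v, g)
    expect_equal(kw$H, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(kw$H, oracle_kw_H(v, factor(g)), tolerance = 1e-12)
    if (kw$H > 0) expect_equal(kw$p.value, ref$p.value, tolerance = 1e-12)
  }
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
})

test_that("Kruskal-Wallis p is calibrated against its chi-square reference", {
  set.seed(77)
  p <- replicate(600, {
    kruskal_wallis(rnorm(18), rep(1:3, each = 6))$p.value
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Dunn post-hoc comparisons behave like a rank test", {
  # two groups: z^2 equals the (tie-corrected) Kruskal-Wallis H
  set.seed(9)
  v <- c(rnorm(12), rnorm(10, 1)); g <- rep(c("ref", "b"), c(12, 10))
  ph <- posthoc_pairwise(v, g, reference = "ref")
  expect_equal(ph$z^2, kruskal_wallis(v, g)$H, tolerance = 1e-10)

  # a +5 SD shifted group is flagged, identical groups are not (usually)
  set.seed(10)
  v <- c(rnorm(30), rnorm(30), rnorm(30, 5))
  g <- rep(c("ref", "same", "far"), each = 30)
  ph <- posthoc_pairwise(v, g, reference = "ref")
  expect_lt(ph$p.adjusted[ph$group == "far"], 0.001)
  expect_gt(ph$p.adjusted[ph$group == "same"], 0.05)
  expect_identical(attr(ph, "adjust"), "bonferroni")
  expect_error(posthoc_pairwise(v, g, reference = "nope"), "not present")
})

test_that("categorical test picks chi-square or Fisher and reports which", {
  balanced <- matrix(10, 2, 2)
  ct <- categorical_test(balanced)
  expect_identical(ct$test, "chi-square")
  expect_equal(ct$statistic, 0)
  expect_equal(ct$p.value, 1)

  prop <- matrix(c(20, 10, 40, 20), 2)     # proportional rows
  expect_equal(categorical_test(prop)$statistic, 0, tolerance = 1e-12)

  sparse <- matrix(c(1, 8, 9, 2), 2)       # expected < 5 -> Fisher
  ct2 <- categorical_test(sparse)
  expect_identical(ct2$test, "fisher")
  expect_equal(ct2$p.value, 0.005477495, tolerance = 1e-6)
  expect_equal(ct2$p.value, oracle_fisher_2x2(sparse), tolerance = 1e-9)

  set.seed(12)
  for (i in 1:20) {                        # enumeration oracle sweep
    tab <- matrix(rpois(4, 3) + c(1, 0, 0, 1), 2)
    res <- categorical_test(tab)
    if (res$test == "fisher")
      expect_equal(res$p.value, oracle_fisher_2x2(tab), tolerance = 1e-9)
  }

  big_sparse <- matrix(c(1, 2, 0, 9, 1, 3, 2, 0, 8), 3)
  expect_identical(categorical_test(big_sparse)$test, "fisher-simulated")
  expect_error(categorical_test(matrix(c(0, 0, 3, 4), 2)), "degenerate")
})

test_that("adjusted linear models recover planted structure", {
  set.seed(21)
  n <- 200
  d <- data.frame(svd_class = sample(SVD_GROUPS(), n, replace = TRUE),
                  age = runif(n, 50, 85),
                  sex = sample(c("male", "female"), n, replace = TRUE))
  code <- match(d$svd_class, SVD_GROUPS())

  # noise-free ordinal outcome is interpolated exactly
  d$y <- 0.1 * code + 0.02 * d$age
  m <- suppressWarnings(fit_adjusted_model(d, "y", covariates = "age",
                          coding = group_coding("linear")))
  expect_equal(m$B[m$term == "group"], 0.1, tolerance = 1e-10)
  expect_true(all(m$ci_low <= m$B & m$B <= m$ci_high))

  # orthogonal covariate leaves the group coefficient unchanged
  d$orth <- stats::residuals(lm(rnorm(n) ~ code))
  m1 <- suppressWarnings(fit_adjusted_model(d, "y",
                           covariates = c("age", "orth"),
                           coding = group_coding("linear")))
  expect_equal(m1$B[m1$term == "group"], m$B[m$term == "group"],
               tolerance = 1e-10)

  # class coding recovers per-type shifts within 2 SE (planted truth from
  # the published frailty model: 0 / 0.02 / 0.35 / 0.38)
  set.seed(22)
  n <- 600
  groups4 <- c("control", "type1", "type2", "type3")
  shifts <- c(control = 0, type1 = 0.02, type2 = 0.35, type3 = 0.38)
  d2 <- data.frame(svd_class = sample(groups4, n, replace = TRUE),
                   age = runif(n, 50, 85),
                   sex = sample(c("male", "female"), n, replace = TRUE))
  d2$y <- shifts[d2$svd_class] + 0.01 * d2$age + rnorm(n, sd = 0.6)
  m2 <- fit_adjusted_model(d2, "y", covariates = c("age", "sex"),
                           coding = group_coding("class", groups4))
  for (g in c("type1", "type2", "type3")) {
    row <- m2[m2$term == paste0("group", g), ]
    se <- (row$ci_high - row$ci_low) / (2 * qt(0.975, attr(m2, "n") - 6))
    expect_lt(abs(row$B - shifts[g]), 2 * se)
  }

  d$dup <- code                            # aliased with the linear code
  expect_error(fit_adjusted_model(d, "y", covariates = c("age", "dup"),
                                  coding = group_coding("linear")),
               "rank")
})

test_that("group summary emits the demographics-table layout", {
  co <- generate_cohort(tiny_spec(15))
  st <- stratify_cohort(co, threshold_policy("fixed"))
  s <- st$subjects
  s$sex_male <- s$sex == "male"
  s$chs_score <- score_chs(s)$chs_score
  tab <- summarize_by_group(s)
  expect_true(all(c("age", "chs_score") %in% tab$variable))
  expect_true(all(grepl("\\(", tab[tab$variable == "age", 2])))
})
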