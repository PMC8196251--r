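# Cohort-level statistics: Kruskal-Wallis omnibus with Dunn post-hoc
# comparisons against a reference group, chi-square / Fisher categorical
# tests, and covariate-adjusted linear models under two group codings
# (ordinal "linear" code and per-type "class" indicators).

#' Kruskal-Wallis rank test
#'
#' H on midranks with the standard tie correction; p from the chi-square
#' reference distribution with k - 1 degrees of freedom.
#'
#' @param values Numeric observations.
#' @param groups Group labels, same length.
#' @return List: `H`, `df`, `p.value`, `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups")
  if (any(tabulate(groups) == 0L)) stop("every group must be nonempty")
  n <- length(values)
  r <- rank(values)                       # midranks
  Rj <- tapply(r, groups, sum)
  nj <- tabulate(groups)
  H <- 12 / (n * (n + 1)) * sum(Rj^2 / nj) - 3 * (n + 1)
  ties <- table(values)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_corr <= 0) {                    # all observations identical
    H <- 0
  } else {
    H <- H / tie_corr
  }
  p <- if (H == 0) 1 else pchisq(H, df = k - 1, lower.tail = FALSE)
  list(H = unname(H), df = k - 1L, p.value = unname(p), n = n)
}

#' Dunn-type post-hoc comparisons against a reference group
#'
#' Each non-reference group is compared with the reference on the pooled
#' midranks, with the tie-corrected Dunn z statistic and (by default)
#' Bonferroni adjustment across the comparisons.
#'
#' @param values Numeric observations.
#' @param groups Group labels.
#' @param reference Reference group label (e.g. `"control"`).
#' @param adjust Multiplicity adjustment, a [stats::p.adjust()] method;
#'   default `"bonferroni"`.
#' @return Data frame: `group`, `z`, `p.value`, `p.adjusted`, with the
#'   adjustment method in attribute `"adjust"`.
#' @export
posthoc_pairwise <- function(values, groups, reference,
                             adjust = "bonferroni") {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (!reference %in% levels(groups))
    stop("reference group '", reference, "' not present")
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  var_unit <- n * (n + 1) / 12 - tie_term
  mean_rank <- tapply(r, groups, mean)
  nj <- tabulate(groups)
  names(nj) <- levels(groups)
  others <- setdiff(levels(groups), reference)
  z <- vapply(others, function(g) {
    se <- sqrt(var_unit * (1 / nj[[g]] + 1 / nj[[reference]]))
    (mean_rank[[g]] - mean_rank[[reference]]) / se
  }, numeric(1))
  p <- 2 * pnorm(-abs(z))
  out <- data.frame(group = others, z = unname(z), p.value = unname(p),
                    p.adjusted = p.adjust(p, method = adjust),
                    stringsAsFactors = FALSE)
  attr(out, "adjust") <- adjust
  out
}

#' Chi-square or Fisher's exact test for a contingency table
#'
#' Chi-square (without continuity correction) when all expected counts are
#' at least 5; otherwise Fisher's exact test (exact for 2x2; simulated
#' exact p for larger tables).  The chosen test is reported.
#'
#' @param tab Matrix of non-negative counts, at least 2x2.
#' @param simulate_B Replicates for the simulated exact p on tables larger
#'   than 2x2 (uses the current RNG state).
#' @return List: `statistic` (NA for Fisher), `p.value`, `test`
#'   (`"chi-square"`, `"fisher"` or `"fisher-simulated"`), `expected`.
#' @export
categorical_test <- function(tab, simulate_B = 10000) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || anyNA(tab)) stop("counts must be non-negative")
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("need at least a 2x2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: zero row or column margin")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(statistic = unname(ct$statistic), p.value = ct$p.value,
         test = "chi-square", expected = expected)
  } else if (nrow(tab) == 2L && ncol(tab) == 2L) {
    ft <- fisher.test(tab)
    list(statistic = NA_real_, p.value = ft$p.value, test = "fisher",
         expected = expected)
  } else {
    ft <- fisher.test(tab, simulate.p.value = TRUE, B = simulate_B)
    list(statistic = NA_real_, p.value = ft$p.value,
         test = "fisher-simulated", expected = expected)
  }
}

#' Group coding for regression models
#'
#' `"linear"` maps the ordered groups to consecutive integers (control = 1,
#' type1 = 2, ...), entering the model as one ordinal slope; `"class"`
#' produces one indicator per SVD type with control as the reference.
#'
#' @param scheme `"linear"` or `"class"`.
#' @param groups Ordered group labels covered by the coding.
#' @return An object of class `"group_coding"`.
#' @export
group_coding <- function(scheme = c("linear", "class"), groups = SVD_GROUPS) {
  scheme <- match.arg(scheme)
  structure(list(scheme = scheme, groups = groups), class = "group_coding")
}

#' Covariate-adjusted linear model of a clinical outcome on SVD group
#'
#' Ordinary least squares with classical standard errors and 95%
#' confidence intervals, under either group coding.  Used for, e.g., the
#' CHS score adjusted for age and sex, or the MMSE adjusted for age, sex
#' and education.
#'
#' @param data Data frame containing the outcome, a group column, and the
#'   covariates.
#' @param outcome Name of the outcome column.
#' @param group_col Name of the group column (values must be in
#'   `coding$groups`; rows with other values are dropped).
#' @param covariates Character vector of covariate column names.
#' @param coding A [group_coding()].
#' @return Data frame of class `"svd_model_result"`: one row per model
#'   term with `B`, `ci_low`, `ci_high`, `p.value`; attribute `n`.
#' @export
fit_adjusted_model <- function(data, outcome, group_col = "svd_class",
                               covariates = c("age", "sex"),
                               coding = group_coding("linear")) {
  stopifnot(inherits(coding, "group_coding"))
  cols <- c(outcome, group_col, covariates)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- data[, cols]
  d <- d[as.character(d[[group_col]]) %in% coding$groups, , drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  if (length(unique(as.character(d[[group_col]]))) < 2L)
    stop("fewer than 2 groups present after filtering")
  d$sex <- if ("sex" %in% names(d) && !is.numeric(d$sex))
    as.integer(d$sex == "male") else d$sex

  if (coding$scheme == "linear") {
    d$.group <- match(as.character(d[[group_col]]), coding$groups)
    rhs <- c(".group", covariates)
  } else {
    d$.group <- factor(as.character(d[[group_col]]), levels = coding$groups)
    d$.group <- droplevels(d$.group)
    rhs <- c(".group", covariates)
  }
  form <- stats::as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
  fit <- lm(form, data = d)
  qr_rank <- fit$qr$rank
  if (qr_rank < length(coef(fit)))
    stop("rank-deficient design; aliased term(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  ci <- confint(fit, level = 0.95)
  sm <- summary(fit)$coefficients
  out <- data.frame(term = rownames(sm), B = sm[, 1],
                    ci_low = ci[, 1], ci_high = ci[, 2],
                    p.value = sm[, 4], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$term <- sub("^\\.group", "group", out$term)
  attr(out, "n") <- nrow(d)
  attr(out, "coding") <- coding$scheme
  class(out) <- c("svd_model_result", "data.frame")
  out
}

#' Demographics-table summary of a stratified cohort
#'
#' Per-group mean (SD) for continuous variables and n (%) for binary
#' variables, with the Kruskal-Wallis (continuous) or chi-square/Fisher
#' (binary) omnibus p-value, in the layout of a cohort demographics table.
#'
#' @param subjects Stratified subject table (with `svd_class`).
#' @param continuous,binary Character vectors of column names.
#' @return Data frame, one row per variable.
#' @export
summarize_by_group <- function(subjects,
                               continuous = c("age", "education_years",
                                              "chs_score", "mmse"),
                               binary = c("sex_male", "hypertension")) {
  g <- factor(subjects$svd_class)
  groups <- levels(g)
  fmt_row <- function(var, type) {
    v <- subjects[[var]]
    cells <- vapply(groups, function(lev) {
      x <- v[g == lev]
      if (type == "continuous")
        sprintf("%.1f (%.1f)", mean(x, na.rm = TRUE), sd(x, na.rm = TRUE))
      else
        sprintf("%d (%.1f%%)", sum(x, na.rm = TRUE),
                100 * mean(x, na.rm = TRUE))
    }, character(1))
    p <- if (type == "continuous") {
      kruskal_wallis(v, g)$p.value
    } else {
      tab <- table(g, factor(v, levels = c(FALSE, TRUE)))
      categorical_test(as.matrix(tab))$p.value
    }
    c(variable = var, cells, p = format.pval(p, digits = 3))
  }
  rows <- c(lapply(intersect(continuous, names(subjects)), fmt_row,
                   type = "continuous"),
            lapply(intersect(binary, names(subjects)), fmt_row,
                   type = "binary"))
  as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
}
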