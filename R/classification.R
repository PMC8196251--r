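# MRI-marker stratification of cerebral small vessel disease.
#
# Three ordered decisions: (i) are cerebral microbleeds (CMB) present;
# (ii) is white-matter hyperintensity (WMH) burden severe, i.e. the
# WMH/TIV ratio exceeds a threshold (cohort median by default); (iii) if
# CMB are present, their topography (mixed vs strictly lobar), otherwise
# whether a lacune accompanies severe WMH.

#' Threshold policy for severe white-matter hyperintensity burden
#'
#' @param mode `"cohort_percentile"` (threshold is a percentile of the
#'   analyzed cohort's WMH/TIV ratios) or `"fixed"` (an absolute ratio).
#' @param percentile Percentile in (0, 100); default 50 (cohort median).
#' @param fixed_ratio Absolute WMH/TIV ratio used in `"fixed"` mode;
#'   default 0.0007 (0.07%).
#' @return An object of class `"threshold_policy"`.
#' @export
threshold_policy <- function(mode = c("cohort_percentile", "fixed"),
                             percentile = 50, fixed_ratio = 0.0007) {
  mode <- match.arg(mode)
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile <= 0 || percentile >= 100)
    stop("'percentile' must be a single number in (0, 100)")
  if (!is.numeric(fixed_ratio) || length(fixed_ratio) != 1L || fixed_ratio <= 0)
    stop("'fixed_ratio' must be a single positive number")
  structure(list(mode = mode, percentile = percentile,
                 fixed_ratio = fixed_ratio),
            class = "threshold_policy")
}

#' Classify cerebral microbleed topography
#'
#' Strictly lobar means CMB exclusively in lobar regions; mixed means any
#' deep and/or infratentorial CMB, with or without lobar CMB.
#'
#' @param lobar,deep,infratentorial Non-negative integer CMB counts
#'   (vectors recycle to a common length).
#' @return Character vector: `"none"`, `"strictly_lobar"` or `"mixed"`.
#' @export
classify_cmb_topography <- function(lobar, deep, infratentorial) {
  counts <- cbind(lobar, deep, infratentorial)
  if (anyNA(counts)) stop("CMB counts must not contain NA")
  if (any(counts < 0)) stop("CMB counts must be non-negative")
  lobar <- counts[, 1]; deep <- counts[, 2]; infra <- counts[, 3]
  unname(ifelse(deep + infra > 0, "mixed",
                ifelse(lobar > 0, "strictly_lobar", "none")))
}

#' WMH/TIV volume ratio
#'
#' @param wmh_volume WMH volume, mm^3 (>= 0).
#' @param tiv Total intracranial volume, mm^3 (> 0).
#' @param id Optional subject identifiers used in error messages.
#' @return Dimensionless ratio(s) in `[0, 1)`.
#' @export
wmh_ratio <- function(wmh_volume, tiv, id = NULL) {
  bad <- !is.finite(tiv) | tiv <= 0
  if (any(bad)) {
    who <- if (is.null(id)) which(bad) else id[bad]
    stop("tiv must be > 0; offending subject(s): ",
         paste(utils::head(who, 5), collapse = ", "))
  }
  if (any(wmh_volume < 0, na.rm = TRUE)) stop("wmh_volume must be >= 0")
  wmh_volume / tiv
}

#' Severe-WMH ratio threshold under a policy
#'
#' @param ratios Cohort WMH/TIV ratios (used in `cohort_percentile` mode).
#' @param policy A [threshold_policy()].
#' @return A single ratio threshold; burden strictly above it is severe.
#' @export
severe_wmh_threshold <- function(ratios, policy = threshold_policy()) {
  stopifnot(inherits(policy, "threshold_policy"))
  if (policy$mode == "fixed") return(policy$fixed_ratio)
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) < 2L)
    stop("cohort_percentile mode needs at least 2 ratios")
  # type-7 linear interpolation: the usual midpoint median convention
  unname(quantile(ratios, policy$percentile / 100, type = 7))
}

#' Stratify marker profiles into SVD subtypes
#'
#' The rule table, applied in order per subject: CMB present and mixed
#' topography -> `type3`; CMB present and strictly lobar -> `type4`;
#' no CMB, severe WMH, no lacune -> `type1`; no CMB, severe WMH, lacune(s)
#' -> `type2`; no CMB, non-severe WMH, no lacune -> `control`.  A lacune
#' with neither CMB nor severe WMH falls outside the scheme and is labeled
#' `unclassified` with a warning rather than silently called robust.
#'
#' @param wmh_ratio WMH/TIV ratios (see [wmh_ratio()]).
#' @param lacune_count Non-negative lacune counts.
#' @param cmb_lobar,cmb_deep,cmb_infratentorial Non-negative CMB counts.
#' @param threshold Severe-WMH ratio threshold; burden strictly greater is
#'   severe.
#' @return Factor with levels `control`, `type1`..`type4`, `unclassified`.
#' @export
stratify <- function(wmh_ratio, lacune_count, cmb_lobar, cmb_deep,
                     cmb_infratentorial, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  if (any(lacune_count < 0)) stop("lacune_count must be non-negative")
  topo <- classify_cmb_topography(cmb_lobar, cmb_deep, cmb_infratentorial)
  n <- length(topo)
  wmh_ratio <- rep_len(wmh_ratio, n)
  lacune_count <- rep_len(lacune_count, n)
  severe <- wmh_ratio > threshold
  lacune <- lacune_count >= 1

  label <- character(n)
  label[topo == "mixed"] <- "type3"
  label[topo == "strictly_lobar"] <- "type4"
  no_cmb <- topo == "none"
  label[no_cmb & severe & !lacune] <- "type1"
  label[no_cmb & severe & lacune] <- "type2"
  label[no_cmb & !severe & !lacune] <- "control"
  orphan <- no_cmb & !severe & lacune
  label[orphan] <- "unclassified"
  if (any(orphan))
    warning(sum(orphan), " subject(s) with lacune(s) but neither CMB nor ",
            "severe WMH fall outside the scheme; labeled 'unclassified'")
  factor(label, levels = c(SVD_GROUPS, "unclassified"))
}

#' Stratify a whole subject table
#'
#' Computes WMH/TIV ratios, resolves the severe-WMH threshold under the
#' policy on the supplied (i.e. post-exclusion, analyzed) cohort, applies
#' [stratify()], and tabulates group counts.
#'
#' @param subjects Data frame with columns `wmh_volume`, `tiv`,
#'   `lacune_count`, `cmb_lobar`, `cmb_deep`, `cmb_infratentorial` and
#'   optionally `subject_id`.
#' @param policy A [threshold_policy()].
#' @return List of class `"svd_stratification"`: `subjects` (input plus
#'   `wmh_ratio` and `svd_class` columns), `threshold`, `policy`, and
#'   `summary` (per-group n and percentage).
#' @export
stratify_cohort <- function(subjects, policy = threshold_policy()) {
  required <- c("wmh_volume", "tiv", "lacune_count",
                "cmb_lobar", "cmb_deep", "cmb_infratentorial")
  missing_cols <- setdiff(required, names(subjects))
  if (length(missing_cols))
    stop("subject table lacks column(s): ", paste(missing_cols, collapse = ", "))
  id <- if ("subject_id" %in% names(subjects)) subjects$subject_id else NULL
  ratio <- wmh_ratio(subjects$wmh_volume, subjects$tiv, id = id)
  thr <- severe_wmh_threshold(ratio, policy)
  cls <- stratify(ratio, subjects$lacune_count, subjects$cmb_lobar,
                  subjects$cmb_deep, subjects$cmb_infratentorial, thr)
  subjects$wmh_ratio <- ratio
  subjects$svd_class <- cls
  counts <- table(cls)
  summary <- data.frame(group = names(counts),
                        n = as.integer(counts),
                        pct = round(100 * as.integer(counts) / length(cls), 1),
                        stringsAsFactors = FALSE)
  structure(list(subjects = subjects, threshold = thr, policy = policy,
                 summary = summary),
            class = "svd_stratification")
}

#' @export
print.svd_stratification <- function(x, ...) {
  cat("SVD stratification of", nrow(x$subjects), "subjects\n")
  cat(sprintf("severe-WMH threshold: %.6g (%s mode)\n",
              x$threshold, x$policy$mode))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Prevalence as a printed percentage
#'
#' @param n_present Count with the marker present.
#' @param n Group size.
#' @param digits Decimal places (default 1, the conventional table format).
#' @return `100 * n_present / n`, rounded.
#' @export
prevalence_pct <- function(n_present, n, digits = 1) {
  if (any(n <= 0)) stop("n must be positive")
  if (any(n_present < 0 | n_present > n)) stop("need 0 <= n_present <= n")
  round(100 * n_present / n, digits)
}

#' Marker prevalence within stratified groups
#'
#' Per-group prevalence (n and %) of a binary marker, as printed in cohort
#' demographics tables, e.g. lacune presence or severe WMH by subtype.
#'
#' @param strat An `"svd_stratification"` from [stratify_cohort()].
#' @param marker One of `"lacune"`, `"severe_wmh"`, `"cmb"`.
#' @return Data frame with columns `group`, `n`, `n_present`, `pct`
#'   (one decimal place, as conventionally printed).
#' @export
marker_prevalence <- function(strat, marker = c("lacune", "severe_wmh", "cmb")) {
  stopifnot(inherits(strat, "svd_stratification"))
  marker <- match.arg(marker)
  s <- strat$subjects
  present <- switch(marker,
    lacune = s$lacune_count >= 1,
    severe_wmh = s$wmh_ratio > strat$threshold,
    cmb = (s$cmb_lobar + s$cmb_deep + s$cmb_infratentorial) >= 1)
  groups <- levels(s$svd_class)
  out <- do.call(rbind, lapply(groups, function(g) {
    in_g <- s$svd_class == g
    data.frame(group = g, n = sum(in_g), n_present = sum(present[in_g]),
               stringsAsFactors = FALSE)
  }))
  out <- out[out$n > 0, , drop = FALSE]
  out$pct <- round(100 * out$n_present / out$n, 1)
  rownames(out) <- NULL
  out
}
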