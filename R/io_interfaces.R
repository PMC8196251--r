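# File formats, configuration and the end-to-end pipeline.
#
# Tables are CSV, maps NIfTI-1 (.nii), configuration and the run
# manifest JSON.  Voxel coordinates in outputs are 0-based NIfTI voxel
# indices.

SUBJECT_COLUMNS <- c("subject_id", "age", "sex", "wmh_volume", "tiv",
                     "lacune_count", "cmb_lobar", "cmb_deep",
                     "cmb_infratentorial")

#' Read and validate a subject table
#'
#' @param path CSV file with at least the marker-profile schema columns
#'   (`subject_id`, `age`, `sex`, `wmh_volume`, `tiv`, `lacune_count`,
#'   `cmb_lobar`, `cmb_deep`, `cmb_infratentorial`); clinical columns are
#'   carried through.
#' @return Validated data frame.  Row-level problems (non-positive TIV,
#'   negative counts, non-numeric markers) are collected and reported
#'   together with their row numbers.
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SUBJECT_COLUMNS, names(d))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows))
      problems <<- c(problems, paste0(what, " (row ",
                                      paste(rows, collapse = ", "), ")"))
  }
  for (col in c("wmh_volume", "tiv", "lacune_count", "cmb_lobar",
                "cmb_deep", "cmb_infratentorial")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    note(which(is.na(v) & !is.na(d[[col]])), paste0("non-numeric ", col))
    d[[col]] <- v
  }
  note(which(!is.na(d$tiv) & d$tiv <= 0), "tiv <= 0")
  for (col in c("lacune_count", "cmb_lobar", "cmb_deep",
                "cmb_infratentorial"))
    note(which(d[[col]] < 0), paste0("negative ", col))
  if (length(problems))
    stop("subject table validation failed:\n  ",
         paste(problems, collapse = "\n  "))
  d
}

#' Write a subject table
#' @param subjects Data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(subjects, path) {
  write.csv(subjects, path, row.names = FALSE)
  invisible(path)
}

#' Read a set of subject maps plus mask on a shared grid
#'
#' @param map_paths Character vector of NIfTI paths, in subject order.
#' @param mask_path NIfTI mask path (nonzero = in mask).
#' @return List: `images` (4D array x-y-z-subject), `mask` (3D logical).
#'   A grid mismatch between any map and the mask is a hard error, as is
#'   a non-finite value inside the mask.
#' @export
read_map_set <- function(map_paths, mask_path) {
  mask <- read_nifti(mask_path) != 0
  maps <- lapply(map_paths, read_nifti)
  for (i in seq_along(maps)) {
    if (!identical(dim(maps[[i]]), dim(mask)))
      stop("grid mismatch: ", map_paths[i], " is ",
           paste(dim(maps[[i]]), collapse = "x"), ", mask is ",
           paste(dim(mask), collapse = "x"))
    if (any(!is.finite(maps[[i]][mask])))
      stop("non-finite values inside the mask: ", map_paths[i])
  }
  images <- array(unlist(maps, use.names = FALSE),
                  dim = c(dim(mask), length(maps)))
  list(images = images, mask = mask)
}

#' Read a pipeline run configuration (JSON)
#'
#' @param path JSON file; recognized top-level fields: `out_dir`,
#'   `threshold_mode`, `threshold_percentile`, `fixed_ratio`,
#'   `frailty_mode`, `coding`, `n_permutations`, `cluster_forming_t`,
#'   `alpha`, `connectivity`, `seed`, and either `subject_table` +
#'   `map_dir` or a `simulate` block for the synthetic module.
#' @return Named list of class `"run_config"` with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- list(threshold_mode = "cohort_percentile",
                   threshold_percentile = 50, fixed_ratio = 0.0007,
                   frailty_mode = "fixed", coding = "class",
                   n_permutations = 10000, cluster_forming_t = 3.1,
                   alpha = 0.05, connectivity = 26, seed = 1L)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: stratification, clinical scoring, group statistics,
#' omnibus voxel-wise F test, post-hoc subtype-vs-control t maps,
#' ascending/descending trend inference, pattern clustering of the
#' unthresholded t maps, and the regional distribution of trend-level
#' significant voxels.  All artifacts plus a manifest (seed, thresholds,
#' package version, file checksums) are written under `out_dir`.
#'
#' @param subjects Subject table (see [read_subject_table()] /
#'   [generate_cohort()]).
#' @param images 4D array of subject maps (x-y-z-subject, matching row
#'   order), e.g. from [generate_images()] or [read_map_set()].
#' @param mask 3D logical analysis mask.
#' @param atlas 3D integer label atlas (1..7, 0 unassigned).
#' @param out_dir Output directory (created if needed).
#' @param policy [threshold_policy()] for severe WMH.
#' @param cutoffs [frailty_cutoffs()]; with mode
#'   `"cohort_percentile_20"` they are re-derived from the cohort.
#' @param config [permutation_config()].
#' @param posthoc_groups Subtypes to contrast against control; default
#'   all present.
#' @return Invisible list with every stage's in-memory results and
#'   `manifest` (also serialized to `manifest.json`).
#' @export
run_pipeline <- function(subjects, images, mask, atlas, out_dir,
                         policy = threshold_policy(),
                         cutoffs = frailty_cutoffs(),
                         config = permutation_config(),
                         posthoc_groups = NULL) {
  stopifnot(inherits(config, "permutation_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)  # one seeded stream
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  strat <- stage("classify", stratify_cohort(subjects, policy))
  s <- strat$subjects
  if (cutoffs$mode == "cohort_percentile_20")
    cutoffs <- stage("classify", derive_percentile_cutoffs(s))
  chs <- stage("clinical", score_chs(s, cutoffs))
  s$chs_score <- chs$chs_score
  s$frail <- chs$frail
  s$cognitive_impairment <- stage("clinical",
    flag_global_cognitive_impairment(s$mmse, s$education_years))
  s$sex_male <- s$sex == "male"
  write_subject_table(s, file.path(out_dir, "subjects_classified.csv"))
  write.csv(strat$summary, file.path(out_dir, "group_counts.csv"),
            row.names = FALSE)

  tab1 <- stage("group_stats", summarize_by_group(s))
  write.csv(tab1, file.path(out_dir, "group_summary.csv"), row.names = FALSE)
  models <- stage("group_stats", list(
    chs_linear = fit_adjusted_model(
      s[as.character(s$svd_class) %in% SVD_GROUPS[1:4], ],
      "chs_score", covariates = c("age", "sex"),
      coding = group_coding("linear", SVD_GROUPS[1:4])),
    chs_class = fit_adjusted_model(
      s[as.character(s$svd_class) %in% SVD_GROUPS[1:4], ],
      "chs_score", covariates = c("age", "sex"),
      coding = group_coding("class", SVD_GROUPS[1:4])),
    mmse_linear = fit_adjusted_model(
      s, "mmse", covariates = c("age", "sex", "education_years"),
      coding = group_coding("linear")),
    mmse_class = fit_adjusted_model(
      s, "mmse", covariates = c("age", "sex", "education_years"),
      coding = group_coding("class"))))
  model_csv <- do.call(rbind, lapply(names(models), function(nm) {
    m <- models[[nm]]
    cbind(model = nm, as.data.frame(m))
  }))
  write.csv(model_csv, file.path(out_dir, "model_results.csv"),
            row.names = FALSE)

  # voxel-wise stages use the classified labels
  present <- SVD_GROUPS[SVD_GROUPS %in% as.character(s$svd_class)]
  design <- stage("voxelwise", design_matrix(s, "svd_class"))
  sub_images <- images[, , , design$keep, drop = FALSE]

  omnibus <- stage("voxelwise", permutation_cluster_inference(
    sub_images, mask, design, contrast_spec("F"), config))
  write_nifti(replace(omnibus$stat_map$map, is.na(omnibus$stat_map$map), 0),
              file.path(out_dir, "omnibus_F.nii"))
  write.csv(omnibus$clusters, file.path(out_dir, "omnibus_clusters.csv"),
            row.names = FALSE)

  if (is.null(posthoc_groups)) posthoc_groups <- setdiff(present, "control")
  posthoc <- list()
  for (g in posthoc_groups) {
    w <- as.numeric(design$groups == g) - as.numeric(design$groups == "control")
    # atrophy direction: control minus subtype (lower values in disease)
    inf_g <- stage("voxelwise", permutation_cluster_inference(
      sub_images, mask, design, contrast_spec("t", weights = -w), config))
    posthoc[[g]] <- inf_g
    write_nifti(replace(inf_g$stat_map$map, is.na(inf_g$stat_map$map), 0),
                file.path(out_dir, paste0("t_", g, "_vs_control.nii")))
    write.csv(inf_g$clusters,
              file.path(out_dir, paste0("clusters_", g, "_vs_control.csv")),
              row.names = FALSE)
  }

  trend <- list()
  trend_design <- stage("trend", design_matrix(
    s, "svd_class", groups = intersect(SVD_GROUPS[1:4], present)))
  trend_images <- images[, , , trend_design$keep, drop = FALSE]
  for (dir_ in c("ascending", "descending")) {
    trend[[dir_]] <- stage("trend", trend_inference(
      trend_images, mask, trend_design, dir_, config))
    write.csv(trend[[dir_]]$clusters,
              file.path(out_dir, paste0("trend_", dir_, "_clusters.csv")),
              row.names = FALSE)
  }

  patterns <- NULL
  if (length(posthoc) >= 3L) {
    vecs <- stage("patterns", vectorize_statmaps(
      lapply(posthoc, function(x) x$stat_map), mask))
    patterns <- stage("patterns", select_k_calinski(vecs))
    write.csv(as.data.frame(patterns$distance),
              file.path(out_dir, "pattern_distance.csv"))
    jsonlite::write_json(
      list(merge = patterns$tree$merge, height = patterns$tree$height,
           labels = patterns$tree$labels, ch = as.list(patterns$ch),
           k = patterns$k, membership = as.list(patterns$membership)),
      file.path(out_dir, "pattern_linkage.json"), auto_unbox = TRUE)
  }

  sig <- stage("regions", significant_voxels(trend$descending))
  regions <- stage("regions", regional_distribution(sig, atlas))
  write.csv(as.data.frame(regions),
            file.path(out_dir, "regional_distribution.csv"),
            row.names = FALSE)

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package = "svdstrat",
    version = as.character(utils::packageVersion("svdstrat")),
    seed = config$seed,
    n_permutations = config$n_permutations,
    cluster_forming_t = config$cluster_forming_t,
    f_threshold = omnibus$threshold,
    alpha = config$alpha,
    connectivity = config$connectivity,
    severe_wmh_threshold = strat$threshold,
    n_subjects = nrow(s),
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(stratification = strat, subjects = s, models = models,
                 omnibus = omnibus, posthoc = posthoc, trend = trend,
                 patterns = patterns, regions = regions,
                 manifest = manifest))
}
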