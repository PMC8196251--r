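# Regional distribution of significant voxels over a seven-region
# cortical-subcortical-cerebellum parcellation (frontal, parietal,
# limbic, subcortical, temporal, occipital, cerebellum).

#' Distribution of significant voxels across atlas regions
#'
#' For each atlas label, counts the significant voxels and reports both
#' normalizations: the share of all significant voxels falling in the
#' region (sums to 100% over occupied regions — the pie-chart reading)
#' and the fraction of the region's voxels that are significant.
#' Significant voxels with atlas label 0 are reported as `unassigned`.
#'
#' @param sig_mask 3D logical array of significant voxels.
#' @param atlas 3D integer array of region labels (0 = unassigned), same
#'   grid.
#' @param region_names Names for labels `1..length(region_names)`;
#'   default the seven-region parcellation.
#' @return Data frame of class `"regional_distribution"`: `label`,
#'   `region`, `n_sig`, `n_region`, `share_pct`, `region_frac_pct`.
#'   With an empty significance mask all counts are 0 and the shares are
#'   `NA` (flagged via attribute `empty`).
#' @export
regional_distribution <- function(sig_mask, atlas,
                                  region_names = SVD_REGIONS) {
  if (!identical(dim(sig_mask), dim(atlas)))
    stop("significance mask and atlas must share one grid")
  sig_mask <- sig_mask & !is.na(sig_mask)
  labels <- as.integer(atlas[sig_mask])
  n_labels <- length(region_names)
  if (length(labels) && any(labels < 0 | labels > n_labels))
    stop("atlas labels outside 0..", n_labels)
  counts <- tabulate(labels + 1L, nbins = n_labels + 1L)  # [0..n_labels]
  region_sizes <- tabulate(as.integer(atlas) + 1L, nbins = n_labels + 1L)
  total <- sum(counts)
  out <- data.frame(
    label = c(seq_len(n_labels), 0L),
    region = c(region_names, "unassigned"),
    n_sig = c(counts[-1], counts[1]),
    n_region = c(region_sizes[-1], region_sizes[1]),
    stringsAsFactors = FALSE)
  out$share_pct <- if (total > 0) round(100 * out$n_sig / total, 1) else NA_real_
  out$region_frac_pct <- ifelse(out$n_region > 0,
                                round(100 * out$n_sig / out$n_region, 1),
                                NA_real_)
  attr(out, "empty") <- total == 0
  class(out) <- c("regional_distribution", "data.frame")
  out
}
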