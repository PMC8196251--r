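---
title: "Methods: stratifying small vessel disease and testing its neuroanatomic signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratifying small vessel disease and testing its neuroanatomic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svdstrat)
```

## The problem

Cerebral small vessel disease (SVD) presents on MRI as a mix of ischaemic
lesions — white-matter hyperintensities (WMH) and lacunes — and
haemorrhagic lesions, the cerebral microbleeds (CMB). These markers
co-occur across at least two distinct microvasculopathies
(arteriosclerosis/lipohyalinosis and cerebral amyloid angiopathy), so
burden scores that merely count markers cannot separate aetiology.
`svdstrat` implements a rule-based stratification that uses the *nature*
of the markers rather than their number, and the downstream statistics
that test whether the resulting subtypes differ clinically and
neuroanatomically.

## The stratification rule

Three ordered decisions per subject:

1. **CMB present?** If yes, topography decides: any deep or
   infratentorial CMB (with or without lobar CMB) is *mixed* → **type 3**
   (suggesting arteriosclerosis at a bleeding stage); CMB exclusively in
   lobar regions is *strictly lobar* → **type 4** (suggesting amyloid
   angiopathy).
2. **Severe WMH?** Without CMB, a WMH/TIV ratio above a threshold — by
   default the cohort 50th percentile, empirically about 0.0007 (0.07%)
   in the emulated population — defines severe WMH. Non-severe WMH
   without lacunes → **control**.
3. **Lacune with severe WMH?** Severe WMH without lacune → **type 1**;
   with at least one lacune → **type 2**.

A lacune with neither CMB nor severe WMH falls outside the scheme. The
source population contained no such individual, so the cell is
unreachable in practice; we deliberately label it `unclassified` with a
warning rather than calling a lesioned subject robust (`stratify()`).

Numerical conventions: the percentile uses type-7 linear interpolation
(the usual midpoint median); the severity comparison is strict
(`ratio > threshold`), mirroring "above the 50th percentile"; the
cohort threshold is computed on the analyzed (post-exclusion) sample.

## Clinical composites

The physical-frailty phenotype follows the Cardiovascular Health Study:
five binary components — weight loss (> 5% of body weight in a year,
strictly), exhaustion (taken as a precomputed boolean because the
underlying two-item depression-scale rule is not standardized),
weakness, slowness, low activity. The latter three are positive when the
measure is *at or below* a sex-specific cutoff: by default the published
fixed values (activity score 7497/6930; gait speed 1.20/1.10 m/s; grip
28.00/17.00 kg for men/women), or cohort-derived 20th percentiles
(`derive_percentile_cutoffs()`). The score is the component count (0–5);
3+ means frail. A missing component propagates as `NA` rather than
counting as absent.

Global cognitive impairment is the education-adjusted MMSE screen:
MMSE < 24 with ≥ 6 years of education, MMSE < 14 below that.

## Group statistics

Continuous cohort variables are compared with the Kruskal–Wallis test on
midranks with the standard tie correction, followed by Dunn-type rank
comparisons of each subtype against the control group. The paper names
no post-hoc method; we chose Dunn's test with Bonferroni adjustment
because it reuses the pooled midranks of the omnibus test (the adjustment
is recorded in the output). Categorical variables use the chi-square test
when all expected counts are ≥ 5 and Fisher's exact test otherwise (the
"when appropriate" rule made concrete; the chosen test is reported).

Adjusted associations are ordinary least squares with two group codings:
the ordinal *linear* code (control = 1, type 1 = 2, …), reading the
coefficient as change per step of subtype severity, and the *class*
coding (one indicator per subtype, control as reference). Education
enters as continuous years.

## Voxel-wise permutation ANCOVA

Per voxel, the model is cell-means group indicators plus mean-centered
nuisance covariates (age, sex, TIV). The omnibus group effect is the
partitioned-model F test; subtype-vs-control and ordered trend effects
are t contrasts on the group columns. Trend weights are
`[-3, -1, +1, +3]` (ascending; negated for descending) across the four
ordered groups control, type 1, type 2, type 3 — the source text lists
four weights while naming three subtypes, and we resolve the ambiguity by
including the control as the lowest rung.

Cluster-level inference is nonparametric. Voxels with statistic above the
cluster-forming threshold (t > 3.1 by default; for F maps, the F value
with the same upper-tail probability at the error df, recorded in the
output) are grouped into connected components (26-neighborhood by
default). The null distribution of the *maximum* cluster extent is built
by Freedman–Lane permutation — residualize the data against the
nuisance-only model, permute those residuals, add back the nuisance fit,
refit — which is the de facto standard scheme of permutation GLM tools
and respects the covariates. Each observed cluster gets
`p = (1 + #{null max ≥ extent}) / (P + 1)`; when the full permutation
group is no larger than the request it is enumerated and the p-value is
the exact fraction. One-sided interest is handled as two separate
one-sided contrasts (as the paired ascending/descending trend contrasts
imply), each corrected within its own null. Voxels with zero residual
variance are flagged `NA` and never enter clustering.

### Why the calibration experiment smooths its noise

Cluster-extent FWE control is exact-but-conservative when the maximum
extent distribution is heavily discrete: with spatially independent
noise and a high forming threshold, suprathreshold voxels are isolated,
extents tie on tiny integers, and the attainable rejection rate sits far
below α (we measured ~0.003–0.03 instead of 0.05). That is a property of
extent ties, not a defect of the permutation engine — and real inputs are
not spatially independent: morphometry maps are smoothed with an 8-mm
FWHM kernel. The calibration and power experiments therefore smooth the
synthetic null fields with a Gaussian of σ = 1.7 voxels (8-mm FWHM at
2-mm voxels, `gaussian_smooth_3d()`), which makes extents
quasi-continuous; the measured family-wise false-positive rate then sits
inside the binomial 95% band around α = 0.05 (0.050 and 0.067 at two
seeds, 300 replicates × 200 permutations on a 16³ grid). The image
generator's default remains white noise (`noise_smooth_sigma = 0`);
smoothing is opt-in.

## Pattern similarity and model selection

Each subtype's unthresholded t map (subtype vs control) is flattened over
the analysis mask to a pattern vector; pairwise Pearson correlation r
gives the distance 1 − r (so anticorrelated patterns are maximally
distant at 2); average-linkage (UPGMA) agglomeration builds the
dendrogram with ties broken deterministically toward the lowest item
index; and the Calinski–Harabasz criterion — between-cluster over
within-cluster dispersion, each per degree of freedom, computed as sums
of squared Euclidean distances to centroids in vector space (the
dispersion form is not specified in the source; this is the standard
one) — selects k over the candidates 2..n−1. With four subtypes the only
candidates are k ∈ {2, 3}. Ties, including numerical ties, go to the
smallest k. If all patterns are identical up to numerical noise
(max 1 − r < 1e−8) the criterion is degenerate and no k is selected,
with a warning. Per-modality dendrograms are the norm (GMV, FA and MD
maps are clustered separately); nothing prevents passing a joint map set.

## Regional distribution

Significant voxels are tallied over a seven-region integer atlas
(frontal, parietal, limbic, subcortical, temporal, occipital,
cerebellum). Two normalizations are reported because "percentage per
sub-region" is ambiguous: the share of all significant voxels falling in
each region (sums to 100%, the pie-chart reading) and the within-region
significant fraction. Voxels with atlas label 0 are reported separately
as unassigned; an empty significance mask yields an explicit flagged
empty result. The original seven-subdivision parcellation is not
redistributable, so the synthetic atlas (seven z-slabs over the mask)
stands in.

## The synthetic cohort: what it does and does not emulate

`generate_cohort()` states a world echoing the published per-group
demographics: sample sizes 312/230/40/54/34 (670 for grey-matter
analyses; 53 more fail diffusion QC, leaving 617), group means and SDs
for age, education and the cognitive instruments (truncated Gaussians
over the instrument ranges), marker prevalences (lacunes in all of
type 2, 42.6% / 11.8% of types 3 / 4; severe WMH in all of types 1–2 and
81.5% / 55.9% of types 3 / 4), and WMH/TIV ratios drawn log-normal —
ratios are positive and right-skewed, consistent with SDs of the same
order as the means — then constrained by inverse-CDF truncation to the
severe or non-severe side of the generative boundary 0.0007. Frailty
component measures are group-shifted Gaussians with shifts chosen once
so that component positivity is rare among controls and graded across
types 1–3 (the published table's CHS means for types 2–3 lost their
integer digit in extraction; we use 1.0, consistent with the text that
frailty peaks there). Two cells of the published table are internally
inconsistent and deliberately not matched (the control frailty
percentage).

`generate_images()` plants spherical group effects on a desk-scale grid
(default 24³, four blobs): graded negative shifts across types 1→3 in
three blobs (the ordered-severity structure the trend contrast targets)
and a type-4-specific blob, plus linear age/sex/TIV effects on
standardized covariates and Gaussian noise. It does **not** emulate
registration error, spatially varying smoothness, skeleton topology of
diffusion analyses, or any segmentation step — so a green test
establishes that the statistics behave as designed on data satisfying
their assumptions, not that the upstream imaging pipeline is valid.

## Known limitations

* Cluster-extent inference on unsmoothed fields is conservative (see
  above); cluster-mass summaries are available but not default.
* The permutation engine supports neither variance smoothing, TFCE, nor
  exchangeability blocks.
* `unclassified` subjects are excluded from the voxel-wise designs.
* The CMB counts-by-category schema cannot express within-category
  topography (e.g. which lobe); the three-category counts are the rule's
  only inputs.
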