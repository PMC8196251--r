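# Synthetic cohort generator.
#
# Emulates a community-based >= 50-year-old cohort stratified into a
# control group and four SVD subtypes.  Defaults echo the published
# per-group demographics: sample sizes 312/230/40/54/34 (N = 670 for the
# grey-matter analyses; 53 further subjects fail diffusion QC, leaving
# 617), group age/education/cognition means and SDs, marker prevalences
# (e.g. lacunes in 100% of type 2, 42.6% of type 3, 11.8% of type 4;
# severe WMH in 81.5% / 55.9% of types 3 / 4), and log-normal WMH/TIV
# ratio distributions on the 10^-3 scale.

#' Cohort specification
#'
#' All defaults state the emulated cohort; change them to simulate other
#' worlds.  Group order is `control, type1, type2, type3, type4`.
#'
#' @param n_per_group Integer count per group (default `c(312, 230, 40,
#'   54, 34)`).
#' @param age_mean,age_sd Per-group age, years.
#' @param sex_male Per-group fraction male.
#' @param hypertension_rate Per-group hypertension prevalence.
#' @param education_mean,education_sd Per-group education, years
#'   (truncated at 0).
#' @param lacune_rate Per-group probability of >= 1 lacune.
#' @param severe_wmh_rate Per-group probability that the WMH/TIV ratio
#'   lies above the severe threshold (`wmh_severe_cut`).
#' @param wmh_mean,wmh_sd Per-group mean/SD of the WMH/TIV ratio
#'   (dimensionless; defaults on the 10^-3 scale).  Sampled log-normal,
#'   then constrained to the severe / non-severe side drawn from
#'   `severe_wmh_rate` by inverse-CDF truncation.
#' @param wmh_severe_cut Generative severe-WMH boundary (ratio); default
#'   0.0007.
#' @param cmb_lobar_mean,cmb_deep_mean,cmb_infra_mean Poisson means for
#'   CMB counts in the bleeding groups (type 3 mixed: >= 1 deep or
#'   infratentorial guaranteed; type 4: >= 1 lobar, no deep/infra).
#' @param mmse_mean,mmse_sd,cvvlt_mean,cvvlt_sd,taylor_mean,taylor_sd,
#'   clock_mean,clock_sd Per-group cognitive scores, truncated to the
#'   instrument ranges (MMSE 0-30, verbal recall 0-9, figure copy 0-36,
#'   clock 0-10).
#' @param grip_shift,speed_shift,ipaq_shift,weight_loss_shift Per-group
#'   downward shifts of the frailty component measures (kg, m/s,
#'   activity units, percent body weight) relative to the robust base.
#' @param exhaustion_rate Per-group probability of exhaustion.
#' @param tiv_mean,tiv_sd Total intracranial volume, mm^3 (+ a fixed
#'   100000 mm^3 male offset).
#' @param diffusion_qc_fail Number of subjects failing diffusion-map QC
#'   (drawn without replacement; default 53).
#' @param seed Integer seed; fixed seed gives byte-identical tables.
#' @return Object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(
    n_per_group = c(control = 312, type1 = 230, type2 = 40,
                    type3 = 54, type4 = 34),
    age_mean = c(57.9, 65.6, 67.8, 67.1, 64.3),
    age_sd = c(5.9, 8.1, 9.2, 10.3, 9.0),
    sex_male = c(0.404, 0.483, 0.500, 0.481, 0.412),
    hypertension_rate = c(0.231, 0.426, 0.525, 0.407, 0.235),
    education_mean = c(8.7, 5.7, 4.9, 5.6, 7.4),
    education_sd = c(4.6, 5.2, 4.3, 5.4, 5.9),
    lacune_rate = c(0, 0, 1, 0.426, 0.118),
    severe_wmh_rate = c(0, 1, 1, 0.815, 0.559),
    wmh_mean = c(0.3, 2.5, 4.1, 4.5, 2.8) * 1e-3,
    wmh_sd = c(0.2, 3.0, 4.4, 4.8, 3.9) * 1e-3,
    wmh_severe_cut = 0.0007,
    cmb_lobar_mean = 0.8, cmb_deep_mean = 1.0, cmb_infra_mean = 0.3,
    mmse_mean = c(27.4, 25.6, 24.6, 25.0, 25.6),
    mmse_sd = c(2.6, 3.3, 5.1, 4.7, 3.9),
    cvvlt_mean = c(7.1, 6.2, 5.8, 5.7, 6.0),
    cvvlt_sd = c(1.6, 2.1, 2.4, 2.2, 2.0),
    taylor_mean = c(32.8, 29.5, 28.5, 28.9, 29.3),
    taylor_sd = c(4.2, 7.0, 8.7, 9.1, 7.0),
    clock_mean = c(8.5, 7.5, 7.0, 7.2, 7.2),
    clock_sd = c(1.8, 2.4, 3.0, 2.6, 2.7),
    grip_shift = c(0, 1.5, 3.5, 3.5, 0.5),
    speed_shift = c(0, 0.05, 0.15, 0.15, 0.02),
    ipaq_shift = c(0, 800, 2000, 2000, 300),
    weight_loss_shift = c(0, 0.5, 1.5, 1.5, 0.3),
    exhaustion_rate = c(0.05, 0.10, 0.20, 0.20, 0.08),
    tiv_mean = 1.40e6, tiv_sd = 1.2e5,
    diffusion_qc_fail = 53,
    seed = 20210520) {
  spec <- as.list(environment())
  probs <- c(spec$sex_male, spec$hypertension_rate, spec$lacune_rate,
             spec$severe_wmh_rate, spec$exhaustion_rate)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (any(spec$n_per_group < 1)) stop("n_per_group must be >= 1 per group")
  for (f in c("age_mean", "age_sd", "sex_male", "hypertension_rate",
              "education_mean", "education_sd", "lacune_rate",
              "severe_wmh_rate", "wmh_mean", "wmh_sd", "mmse_mean",
              "mmse_sd"))
    if (length(spec[[f]]) != 5L)
      stop("'", f, "' must have one value per group (5)")
  structure(spec, class = "cohort_spec")
}

# log-normal meanlog/sdlog matching a target mean and sd
lnorm_params <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

# draw from a log-normal truncated to one side of `cut` (inverse CDF)
rlnorm_side <- function(n, meanlog, sdlog, cut, above) {
  pc <- plnorm(cut, meanlog, sdlog)
  u <- if (above) pc + runif(n) * (1 - pc) else runif(n) * pc
  # clamp away from the exact boundary (severe means strictly above)
  qlnorm(pmin(pmax(u, 1e-12), 1 - 1e-12), meanlog, sdlog)
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

#' Generate a synthetic subject table
#'
#' One row per subject: intended group, demographics, clinical measures,
#' frailty component measures and the MRI marker profile, with marker
#' fields consistent with the intended group (e.g. intended type 4 rows
#' carry strictly lobar CMB only).  Reproducible under the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with one row per subject; column `diffusion_qc`
#'   flags subjects retained for diffusion-map analyses.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
  }
  groups <- SVD_GROUPS
  n <- spec$n_per_group
  gi <- rep(seq_along(groups), n)         # group index per subject
  N <- length(gi)
  per <- function(x) x[gi]                # expand group parameter to rows

  sex <- ifelse(runif(N) < per(spec$sex_male), "male", "female")
  male <- sex == "male"
  age <- pmax(50, rnorm(N, per(spec$age_mean), per(spec$age_sd)))
  tiv <- rnorm(N, spec$tiv_mean + 1e5 * male, spec$tiv_sd)
  tiv <- pmax(tiv, 8e5)

  # WMH/TIV ratio: group log-normal constrained to the severe side drawn
  # from the group's severe-WMH rate
  severe <- runif(N) < per(spec$severe_wmh_rate)
  ratio <- numeric(N)
  for (g in seq_along(groups)) {
    rows <- which(gi == g)
    if (!length(rows)) next
    lp <- lnorm_params(spec$wmh_mean[g], spec$wmh_sd[g])
    up <- severe[rows]
    ratio[rows[up]] <- rlnorm_side(sum(up), lp$meanlog, lp$sdlog,
                                   spec$wmh_severe_cut, above = TRUE)
    ratio[rows[!up]] <- rlnorm_side(sum(!up), lp$meanlog, lp$sdlog,
                                    spec$wmh_severe_cut, above = FALSE)
  }

  lacune_present <- runif(N) < per(spec$lacune_rate)
  lacune_count <- ifelse(lacune_present, 1L + rpois(N, 0.7), 0L)

  cmb_lobar <- integer(N); cmb_deep <- integer(N); cmb_infra <- integer(N)
  t3 <- gi == 4L; t4 <- gi == 5L
  cmb_deep[t3] <- rpois(sum(t3), spec$cmb_deep_mean)
  cmb_infra[t3] <- rpois(sum(t3), spec$cmb_infra_mean)
  none <- t3 & cmb_deep + cmb_infra == 0L   # mixed needs deep/infra >= 1
  cmb_deep[none] <- 1L
  cmb_lobar[t3] <- rpois(sum(t3), spec$cmb_lobar_mean)
  cmb_lobar[t4] <- 1L + rpois(sum(t4), spec$cmb_lobar_mean)

  grip_base <- ifelse(male, rnorm(N, 35, 7), rnorm(N, 22, 5))
  speed_base <- ifelse(male, rnorm(N, 1.45, 0.22), rnorm(N, 1.35, 0.22))
  ipaq_base <- ifelse(male, rlnorm(N, log(11000), 0.45),
                      rlnorm(N, log(10000), 0.45))

  out <- data.frame(
    subject_id = sprintf("S%04d", seq_len(N)),
    group = factor(groups[gi], levels = groups),
    age = round(age, 1),
    sex = sex,
    hypertension = runif(N) < per(spec$hypertension_rate),
    education_years = round(rnorm_trunc(N, per(spec$education_mean),
                                        per(spec$education_sd), 0, 22), 1),
    mmse = round(rnorm_trunc(N, per(spec$mmse_mean), per(spec$mmse_sd),
                             0, 30)),
    cvvlt_recall = round(rnorm_trunc(N, per(spec$cvvlt_mean),
                                     per(spec$cvvlt_sd), 0, 9), 1),
    taylor_score = round(rnorm_trunc(N, per(spec$taylor_mean),
                                     per(spec$taylor_sd), 0, 36), 1),
    clock_score = round(rnorm_trunc(N, per(spec$clock_mean),
                                    per(spec$clock_sd), 0, 10), 1),
    weight_loss_pct = round(pmax(rnorm(N, 1 + per(spec$weight_loss_shift),
                                       2.5), 0), 1),
    exhaustion = runif(N) < per(spec$exhaustion_rate),
    grip_strength = round(pmax(grip_base - per(spec$grip_shift), 2), 1),
    gait_speed = round(pmax(speed_base - per(spec$speed_shift), 0.2), 2),
    ipaq_score = round(pmax(ipaq_base - per(spec$ipaq_shift), 100)),
    tiv = round(tiv),
    wmh_volume = round(ratio * tiv, 1),
    lacune_count = lacune_count,
    cmb_lobar = cmb_lobar,
    cmb_deep = cmb_deep,
    cmb_infratentorial = cmb_infra,
    stringsAsFactors = FALSE)

  qc_fail <- sample.int(N, min(spec$diffusion_qc_fail, N))
  out$diffusion_qc <- TRUE
  out$diffusion_qc[qc_fail] <- FALSE
  out
}
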