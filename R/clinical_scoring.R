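# Composite clinical scores: the Cardiovascular Health Study (CHS)
# physical-frailty phenotype (0-5 components, frail if >= 3) and the
# education-adjusted global-cognitive-impairment screen on the MMSE.

#' Sex-specific frailty cutoffs
#'
#' Defaults are the published fixed cutoffs: a component is positive when
#' the measure is less than or equal to the cutoff (activity score,
#' walking speed, grip strength).
#'
#' @param ipaq_male,ipaq_female Physical-activity score cutoffs (IPAQ
#'   energy-consumption units); defaults 7497 / 6930.
#' @param speed_male,speed_female Walking-speed cutoffs, m/s; defaults
#'   1.20 / 1.10.
#' @param grip_male,grip_female Handgrip-strength cutoffs, kg; defaults
#'   28.00 / 17.00.
#' @param mode `"fixed"` (use these values) or `"cohort_percentile_20"`
#'   (derive per-sex 20th percentiles from the cohort; see
#'   [derive_percentile_cutoffs()]).
#' @return An object of class `"frailty_cutoffs"`.
#' @export
frailty_cutoffs <- function(ipaq_male = 7497, ipaq_female = 6930,
                            speed_male = 1.20, speed_female = 1.10,
                            grip_male = 28.00, grip_female = 17.00,
                            mode = c("fixed", "cohort_percentile_20")) {
  mode <- match.arg(mode)
  vals <- c(ipaq_male, ipaq_female, speed_male, speed_female,
            grip_male, grip_female)
  if (any(!is.finite(vals) | vals <= 0)) stop("all cutoffs must be > 0")
  structure(list(ipaq = c(male = ipaq_male, female = ipaq_female),
                 speed = c(male = speed_male, female = speed_female),
                 grip = c(male = grip_male, female = grip_female),
                 mode = mode),
            class = "frailty_cutoffs")
}

#' Derive per-sex 20th-percentile frailty cutoffs from a cohort
#'
#' Weakness, slowness and low activity refer to performance below the
#' sex-specific lowest 20% of the study population; this computes those
#' cutoffs (type-7 linear interpolation) from the cohort itself.
#'
#' @param subjects Data frame with columns `sex` (`"male"`/`"female"`),
#'   `ipaq_score`, `gait_speed`, `grip_strength`.
#' @return A `"frailty_cutoffs"` object with `mode = "cohort_percentile_20"`.
#' @export
derive_percentile_cutoffs <- function(subjects) {
  need <- c("sex", "ipaq_score", "gait_speed", "grip_strength")
  if (!all(need %in% names(subjects)))
    stop("need columns: ", paste(setdiff(need, names(subjects)), collapse = ", "))
  p20 <- function(col, sx) {
    v <- subjects[[col]][subjects$sex == sx]
    v <- v[!is.na(v)]
    if (length(v) < 5L)
      stop("fewer than 5 ", sx, " subjects with non-missing ", col)
    unname(quantile(v, 0.20, type = 7))
  }
  frailty_cutoffs(ipaq_male = p20("ipaq_score", "male"),
                  ipaq_female = p20("ipaq_score", "female"),
                  speed_male = p20("gait_speed", "male"),
                  speed_female = p20("gait_speed", "female"),
                  grip_male = p20("grip_strength", "male"),
                  grip_female = p20("grip_strength", "female"),
                  mode = "cohort_percentile_20")
}

#' CHS frailty score
#'
#' Counts the five frailty components: unintentional weight loss of more
#' than 5% in the last year; exhaustion; weakness (grip strength at or
#' below the sex-specific cutoff); slowness (walking speed at or below
#' cutoff); low physical activity (activity score at or below cutoff).
#' Frail means three or more components present.  A missing component
#' yields `NA` score and flag for that subject, never a silent 0.
#'
#' @param measures Data frame with columns `weight_loss_pct`, `exhaustion`
#'   (logical), `grip_strength` (kg), `gait_speed` (m/s), `ipaq_score`,
#'   `sex` (`"male"`/`"female"`).
#' @param cutoffs A [frailty_cutoffs()].
#' @return Data frame: component flags (`weight_loss`, `exhaustion`,
#'   `weakness`, `slowness`, `low_activity`), `chs_score` (0-5) and
#'   `frail` (score >= 3); `NA` where a component is missing.
#' @export
score_chs <- function(measures, cutoffs = frailty_cutoffs()) {
  stopifnot(inherits(cutoffs, "frailty_cutoffs"))
  need <- c("weight_loss_pct", "exhaustion", "grip_strength",
            "gait_speed", "ipaq_score", "sex")
  miss <- setdiff(need, names(measures))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  sx <- as.character(measures$sex)
  if (!all(sx %in% c("male", "female") | is.na(sx)))
    stop("sex must be 'male' or 'female'")
  pick <- function(cut) unname(cut[sx])

  comp <- data.frame(
    weight_loss = measures$weight_loss_pct > 5,             # strictly >5%
    exhaustion = as.logical(measures$exhaustion),
    weakness = measures$grip_strength <= pick(cutoffs$grip), # "<=" per criteria
    slowness = measures$gait_speed <= pick(cutoffs$speed),
    low_activity = measures$ipaq_score <= pick(cutoffs$ipaq))
  comp$chs_score <- as.integer(rowSums(comp[1:5]))  # NA if any component NA
  comp$frail <- comp$chs_score >= 3L
  comp
}

#' Global cognitive impairment flag
#'
#' Education-adjusted MMSE screen: impaired when MMSE < 24 with at least
#' 6 years of education, or MMSE < 14 with fewer than 6 years.
#'
#' @param mmse MMSE scores in `[0, 30]`.
#' @param education_years Years of education (>= 0).
#' @return Logical vector.
#' @export
flag_global_cognitive_impairment <- function(mmse, education_years) {
  ok <- is.na(mmse) | (mmse >= 0 & mmse <= 30)
  if (!all(ok)) stop("mmse out of [0, 30] at position(s): ",
                     paste(utils::head(which(!ok), 5), collapse = ", "))
  if (any(education_years < 0, na.rm = TRUE))
    stop("education_years must be >= 0")
  ifelse(education_years >= 6, mmse < 24, mmse < 14)
}
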