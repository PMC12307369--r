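#' Group-level generator configuration
#'
#' Describes one diagnostic group of the synthetic cohort: its size, the
#' between-subject distribution of the true ALPS index, lognormal models for
#' the per-subject EPVS lesion count and per-lesion volume, the BG/CSO
#' placement split, the linear cognition link, and demographics.
#'
#' The cognition link is `score = a + slope * ALPS + N(0, noise_sd)` clamped
#' to \[0, 30\], with the intercept `a` derived internally so the group mean
#' score equals `mmse_mean` (resp. `moca_mean`) at `ALPS = alps_mean`.
#'
#' @param name Group label, e.g. `"AD"`, `"aMCI"`, `"NC"`.
#' @param n_subjects Number of subjects (>= 1).
#' @param alps_mean,alps_between_sd Normal parameters of the true
#'   (generator-level) mean ALPS index; `alps_mean > 0`.
#' @param lesion_count_log_median,lesion_count_log_sigma Lognormal
#'   parameters (log scale) of the per-subject lesion count, rounded and
#'   floored at 1.
#' @param lesion_vol_log_median_mm3,lesion_vol_log_sigma Lognormal
#'   parameters of the per-lesion volume in mm^3.
#' @param bg_share Fraction of lesions placed in the basal ganglia (the rest
#'   go to the centrum semiovale), in \[0, 1\].
#' @param mmse_mean,mmse_slope,mmse_noise_sd,moca_mean,moca_slope,moca_noise_sd
#'   Cognition-link parameters (points, points per ALPS unit, points).
#' @param age_mean,age_sd,p_male,edu_mean,edu_sd Demographic distributions
#'   (years; probability of male; years).
#' @param tbv_mean,tbv_sd Total brain volume covariate distribution (mm^3).
#' @return A `group_config` object.
#' @export
group_config <- function(name, n_subjects,
                         alps_mean, alps_between_sd,
                         lesion_count_log_median, lesion_count_log_sigma,
                         lesion_vol_log_median_mm3, lesion_vol_log_sigma,
                         bg_share = 0.8,
                         mmse_mean = 27, mmse_slope = 3, mmse_noise_sd = 1,
                         moca_mean = 26, moca_slope = 3, moca_noise_sd = 1,
                         age_mean = 67, age_sd = 9, p_male = 0.5,
                         edu_mean = 8, edu_sd = 4,
                         tbv_mean = 1.45e6, tbv_sd = 1.2e5) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (alps_mean <= 0) stop("alps_mean must be > 0")
  if (alps_between_sd < 0 || lesion_count_log_sigma < 0 ||
      lesion_vol_log_sigma < 0)
    stop("sigmas must be >= 0")
  if (bg_share < 0 || bg_share > 1) stop("bg_share must be in [0, 1]")
  structure(as.list(environment()), class = "group_config")
}

#' Lognormal parameters from a printed median and upper quartile
#'
#' `log_median = log(median)`; `sigma = log(q3/median) / qnorm(0.75)`
#' (0.6745), i.e. the lognormal whose quartile ratio matches the printed
#' one.
#'
#' @param median,q3 Printed median and 75th percentile (> 0, q3 >= median).
#' @return List with `log_median` and `sigma`.
#' @export
lognormal_from_quartiles <- function(median, q3) {
  if (median <= 0 || q3 < median) stop("need 0 < median <= q3")
  list(log_median = log(median), sigma = log(q3 / median) / stats::qnorm(0.75))
}

# Per-lesion volume parameters such that E[per-lesion volume] equals
# total_median / count_median: the cohort median *total* volume (sum of a
# median-count number of lesions) then converges to the printed total
# median. The sigma comes from the printed total-volume quartile ratio.
lesion_volume_params <- function(total_median, total_q3, count_median) {
  sig <- lognormal_from_quartiles(total_median, total_q3)$sigma
  mean_lesion <- total_median / count_median
  list(log_median = log(mean_lesion) - sig^2 / 2, sigma = sig)
}

#' Default three-group cohort calibration
#'
#' AD / aMCI / NC configurations calibrated to published clinical-cohort
#' summaries: ALPS means 1.308 / 1.450 / 1.570 with between-subject SD equal
#' to the printed SEM times sqrt(n) (n = 89 / 24 / 32); lesion counts and
#' volumes from lognormal fits to the printed medians and upper quartiles
#' (counts 19 / 14 / 12; total volumes 457.5 / 330.9 / 320.6 mm^3);
#' cognition links reproducing the printed MMSE / MoCA group means with
#' correlation ~0.55 to ALPS; demographics from the printed age / sex /
#' education summaries.
#'
#' @return Named list of three [group_config()]s: `AD`, `aMCI`, `NC`.
#' @export
default_group_configs <- function() {
  r_cog <- 0.55
  mk <- function(name, n, alps_m, alps_sem, cnt_med, cnt_q3,
                 vol_med, vol_q3, mmse_m, mmse_sd, moca_m, moca_sd,
                 age_m, age_sd, p_male, edu_m, edu_sd) {
    sd_alps <- alps_sem * sqrt(n)
    cnt <- lognormal_from_quartiles(cnt_med, cnt_q3)
    vol <- lesion_volume_params(vol_med, vol_q3, cnt_med)
    group_config(
      name = name, n_subjects = n,
      alps_mean = alps_m, alps_between_sd = sd_alps,
      lesion_count_log_median = cnt$log_median,
      lesion_count_log_sigma = cnt$sigma,
      lesion_vol_log_median_mm3 = vol$log_median,
      lesion_vol_log_sigma = vol$sigma,
      bg_share = 0.8,
      mmse_mean = mmse_m, mmse_slope = r_cog * mmse_sd / sd_alps,
      mmse_noise_sd = mmse_sd * sqrt(1 - r_cog^2),
      moca_mean = moca_m, moca_slope = r_cog * moca_sd / sd_alps,
      moca_noise_sd = moca_sd * sqrt(1 - r_cog^2),
      age_mean = age_m, age_sd = age_sd, p_male = p_male,
      edu_mean = edu_m, edu_sd = edu_sd)
  }
  list(
    AD   = mk("AD", 89, 1.308, 0.015, 19, 29, 457.5, 735.4,
              17.27, 5.670, 13.38, 6.173, 68.75, 9.292, 40 / 89, 7.83, 4.360),
    aMCI = mk("aMCI", 24, 1.450, 0.040, 14, 20.5, 330.9, 512.4,
              25.92, 0.974, 20.88, 3.982, 67.25, 9.317, 12 / 24, 8.25, 4.173),
    NC   = mk("NC", 32, 1.570, 0.027, 12, 17.5, 320.6, 473.7,
              28.59, 0.798, 27.28, 1.420, 65.41, 7.551, 12 / 32, 8.72, 2.543))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# One subject's scalar ground truth, drawn from the current RNG stream.
draw_subject_truth <- function(group) {
  g <- stats::rnorm(1, group$alps_mean, group$alps_between_sd)
  g <- max(g, 0.2)   # guard: ALPS is a positive ratio
  # count floored at 1 and capped at the phantom regions' placement
  # capacity; the cap truncates < 2% of the lognormal's upper tail and
  # leaves cohort medians unaffected
  n_lesions <- min(60L, max(1L, as.integer(round(stats::rlnorm(
    1, group$lesion_count_log_median, group$lesion_count_log_sigma)))))
  lesion_vols <- stats::rlnorm(n_lesions, group$lesion_vol_log_median_mm3,
                               group$lesion_vol_log_sigma)
  in_bg <- stats::runif(n_lesions) < group$bg_share
  age <- stats::rnorm(1, group$age_mean, group$age_sd)
  sex <- stats::rbinom(1, 1, group$p_male)            # 1 = male
  edu <- max(0, stats::rnorm(1, group$edu_mean, group$edu_sd))
  tbv <- stats::rnorm(1, group$tbv_mean, group$tbv_sd)
  mmse_a <- group$mmse_mean - group$mmse_slope * group$alps_mean
  moca_a <- group$moca_mean - group$moca_slope * group$alps_mean
  mmse <- clamp(mmse_a + group$mmse_slope * g +
                  stats::rnorm(1, 0, group$mmse_noise_sd), 0, 30)
  moca <- clamp(moca_a + group$moca_slope * g +
                  stats::rnorm(1, 0, group$moca_noise_sd), 0, 30)
  list(group = group$name, alps = g, n_lesions = n_lesions,
       lesion_vols_mm3 = lesion_vols, in_bg = in_bg,
       age = age, sex = sex, education = edu, total_brain_volume = tbv,
       mmse = mmse, moca = moca)
}

truth_row <- function(tr) {
  data.frame(group = tr$group, alps_true = tr$alps,
             epvs_count_true = tr$n_lesions,
             epvs_volume_true_mm3 = sum(tr$lesion_vols_mm3),
             age = tr$age, sex = tr$sex, education = tr$education,
             total_brain_volume = tr$total_brain_volume,
             mmse = tr$mmse, moca = tr$moca,
             stringsAsFactors = FALSE)
}

derive_subject_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Draw a cohort-level scalar truth table (no image rendering)
#'
#' Draws the per-subject ground-truth scalars (true ALPS, lesion count and
#' volumes, demographics, cognition) for every subject of every group,
#' using exactly the per-subject seed derivation of [synth_cohort()], so the
#' scalar truths of the fast table and of the fully rendered cohort agree.
#' Used for distribution-level calibration checks and statistical power
#' studies where rendering image volumes would add nothing.
#'
#' @param groups List of [group_config()]s with distinct names.
#' @param seed Master seed.
#' @return Data frame, one row per subject: `subject_id`, `group`,
#'   `alps_true`, `epvs_count_true`, `epvs_volume_true_mm3`, demographics,
#'   `mmse`, `moca`.
#' @export
synth_cohort_table <- function(groups, seed) {
  nms <- vapply(groups, function(g) g$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate group names: ",
                               paste(nms[duplicated(nms)], collapse = ", "))
  if (length(groups) < 1) stop("need at least one group")
  ntot <- sum(vapply(groups, function(g) g$n_subjects, numeric(1)))
  seeds <- derive_subject_seeds(seed, ntot)
  rows <- vector("list", ntot)
  k <- 0L
  for (g in groups) for (i in seq_len(g$n_subjects)) {
    k <- k + 1L
    set.seed(seeds[k])
    rows[[k]] <- truth_row(draw_subject_truth(g))
  }
  out <- do.call(rbind, rows)
  out <- cbind(subject_id = sprintf("S%03d", seq_len(ntot)), out)
  rownames(out) <- NULL
  out
}
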