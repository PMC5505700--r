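# Synthetic clinical and survival tables.  These are labelled synthetic
# stand-ins for patient-level source data: they are calibrated to the reported
# study designs (group sizes, target correlations, group medians) so the
# association statistics can be exercised and their recovery of the planted
# values tested.

#' Simulate a LAM clinical table (serum Gal-3, %FEV1, AML status, BMI)
#'
#' Draws (gal3, fev1, bmi) from a trivariate Gaussian with the requested
#' pairwise correlations, then adds `aml_effect` to serum Gal-3 for
#' AML-positive patients in the mild stratum (%FEV1 > 80), matching the
#' design in which angiomyolipomas are an additional Gal-3 source mainly
#' visible when lung involvement is mild.
#'
#' @param n_patients number of patients.
#' @param corr_gal3_fev1 target correlation between Gal-3 and %FEV1
#'   (|r| < 1; default -0.32).
#' @param corr_gal3_bmi,corr_fev1_bmi remaining pairwise correlations
#'   (defaults 0.315 and 0.083, jointly consistent with a BMI-adjusted
#'   partial correlation of about -0.366 at the defaults).
#' @param aml_effect additive Gal-3 shift (pg/mL) for AML-positive patients
#'   with %FEV1 > 80.
#' @param frac_aml fraction of patients with a confirmed AML.
#' @param gal3_mean,gal3_sd,fev1_mean,fev1_sd,bmi_mean,bmi_sd marginal
#'   moments; Gal-3 defaults follow the reported serum summary
#'   (4649 +/- 1980 pg/mL).
#' @param seed integer seed.
#' @return data.frame with columns `patient_id`, `gal3`, `fev1`,
#'   `aml_status` (0/1) and `bmi`.
#' @export
simulate_clinical_tables <- function(n_patients = 64,
                                     corr_gal3_fev1 = -0.32,
                                     corr_gal3_bmi = 0.315,
                                     corr_fev1_bmi = 0.083,
                                     aml_effect = 0,
                                     frac_aml = 0.5,
                                     gal3_mean = 4649, gal3_sd = 1980,
                                     fev1_mean = 75, fev1_sd = 20,
                                     bmi_mean = 26, bmi_sd = 4,
                                     seed = 1) {
  for (r in c(corr_gal3_fev1, corr_gal3_bmi, corr_fev1_bmi))
    if (abs(r) >= 1) stop_tsc("correlations must satisfy |r| < 1")
  R <- matrix(c(1, corr_gal3_fev1, corr_gal3_bmi,
                corr_gal3_fev1, 1, corr_fev1_bmi,
                corr_gal3_bmi, corr_fev1_bmi, 1), 3, 3)
  ch <- tryCatch(chol(R), error = function(e)
    stop_tsc("requested correlation matrix is not positive definite"))
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(n_patients * 3), n_patients, 3) %*% ch
  gal3 <- gal3_mean + gal3_sd * z[, 1]
  fev1 <- fev1_mean + fev1_sd * z[, 2]
  bmi <- bmi_mean + bmi_sd * z[, 3]
  aml <- stats::rbinom(n_patients, 1, frac_aml)
  gal3 <- gal3 + aml_effect * aml * (fev1 > 80)
  data.frame(patient_id = sprintf("P%03d", seq_len(n_patients)),
             gal3 = gal3, fev1 = fev1, aml_status = aml, bmi = bmi,
             stringsAsFactors = FALSE)
}

#' Simulate a mouse survival table
#'
#' Control animals are followed without events (all censored at the follow-up
#' horizon); knockout animals of each sex have exponential survival and are
#' administratively censored at the horizon.
#'
#' `median_male` / `median_female` are the target *Kaplan-Meier* medians:
#' with the smallest-time-with-`S <= 0.5` convention the product-limit
#' median equals the `ceiling(n/2)`-th order statistic, whose sampling
#' median sits below the true exponential median at these group sizes.  The
#' exponential rate is therefore set so that the KM median estimator is
#' median-unbiased for the target (via the Beta median of that order
#' statistic), making the generated arms reproduce the target medians under
#' the same estimator that analyses them.
#'
#' @param n_control,n_ko_male,n_ko_female group sizes (defaults 28/22/24,
#'   the study design).
#' @param median_male,median_female target KM median survival in weeks for
#'   knockout males and females (defaults 28 and 24).
#' @param followup_weeks administrative censoring time.
#' @param seed integer seed.
#' @return data.frame with columns `animal_id`, `time_weeks`, `event_flag`
#'   (1 = death), `group` (`control`/`cKO`) and `sex`.
#' @export
simulate_survival_table <- function(n_control = 28,
                                    n_ko_male = 22,
                                    n_ko_female = 24,
                                    median_male = 28,
                                    median_female = 24,
                                    followup_weeks = 41,
                                    seed = 1) {
  if (min(n_control, n_ko_male, n_ko_female) < 1)
    stop_tsc("all group sizes must be >= 1")
  set.seed(as.integer(seed))
  # rate such that the median of the ceiling(n/2)-th order statistic equals
  # the target: for exp(rate), t_(k) has cdf quantile q = Beta(k, n-k+1)
  km_rate <- function(target, n) {
    k <- ceiling(n / 2)
    -log1p(-stats::qbeta(0.5, k, n - k + 1)) / target
  }
  tm <- stats::rexp(n_ko_male, rate = km_rate(median_male, n_ko_male))
  tf <- stats::rexp(n_ko_female, rate = km_rate(median_female, n_ko_female))
  ko_times <- pmin(c(tm, tf), followup_weeks)
  ko_event <- as.integer(c(tm, tf) < followup_weeks)
  df <- data.frame(
    animal_id = sprintf("M%03d", seq_len(n_control + n_ko_male + n_ko_female)),
    time_weeks = c(rep(followup_weeks, n_control), ko_times),
    event_flag = c(rep(0L, n_control), ko_event),
    group = c(rep("control", n_control), rep("cKO", n_ko_male + n_ko_female)),
    sex = c(rep(NA_character_, n_control),
            rep("M", n_ko_male), rep("F", n_ko_female)),
    stringsAsFactors = FALSE)
  df
}

#' Simulate two measurement groups differing by a planted percent change
#'
#' Lognormal-free simple Gaussian groups on the measurement scale: the
#' alternative group mean is `mean_ref * (1 + pct_change / 100)`.  Used for
#' serum ELISA and thickness style contrasts.
#'
#' @param n_ref,n_alt group sizes.
#' @param mean_ref reference group mean (must be nonzero).
#' @param pct_change planted percent change of the alternative group mean.
#' @param cv coefficient of variation shared by both groups.
#' @param seed integer seed.
#' @return list with numeric vectors `ref` and `alt`.
#' @export
simulate_group_measurements <- function(n_ref, n_alt, mean_ref, pct_change,
                                        cv = 0.25, seed = 1) {
  if (mean_ref == 0) stop_tsc("mean_ref must be nonzero")
  set.seed(as.integer(seed))
  mean_alt <- mean_ref * (1 + pct_change / 100)
  list(ref = stats::rnorm(n_ref, mean_ref, abs(cv * mean_ref)),
       alt = stats::rnorm(n_alt, mean_alt, abs(cv * mean_alt)))
}
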