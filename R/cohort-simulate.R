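#' Configuration for the synthetic SEER-like cohort generator
#'
#' Builds a validated configuration for [simulate_cohort()]. The defaults
#' emulate a registry extract of resected esophageal-cancer patients:
#' marginal moments (age, sex, race, tumor size) match the published cohort
#' summaries, nodal counts follow overdispersed count distributions typical
#' of lymphadenectomy yields, and survival times are drawn from a Weibull
#' (default exponential) proportional-hazards model whose log-hazard carries
#' a per-positive-node and a per-negative-node effect. Loss to follow-up is
#' calibrated at generation time so the observed event fraction matches
#' `target_event_frac`.
#'
#' @param n_patients Number of patients to generate.
#' @param seed Default integer seed used by [simulate_cohort()].
#' @param mean_age,sd_age Age distribution (years), normal.
#' @param prop_male Fraction of male patients.
#' @param race_props Named or unnamed length-3 fractions for white/black/other;
#'   must sum to 1 (renormalised if within 1e-6).
#' @param mean_tumor_size,sd_tumor_size Tumor size distribution (registry
#'   size units), normal truncated at 1.
#' @param nln_mean,nln_dispersion Negative binomial mean and size for the
#'   count of negative (tumor-free) nodes examined.
#' @param pln_zero_prob,pln_mean,pln_dispersion Zero-inflated negative
#'   binomial parameters for the count of positive nodes: probability of a
#'   structural zero (node-negative patient), and NB mean/size otherwise.
#' @param log_hr_per_pln,log_hr_per_nln Ground-truth log hazard ratio per
#'   positive / negative node; defaults `log(1.064)` and `log(0.962)`.
#' @param log_hr_age,log_hr_male,log_hr_tumor_size Optional covariate log
#'   hazard ratios (age centred at `mean_age`, tumor size per unit); default 0.
#' @param hazard_model `"nodes"` (log-hazard linear in the two node counts)
#'   or `"ratio"` (log-hazard driven by `log1p` of the hazard-weighted node
#'   ratio itself, with weight coefficient implied by the per-node HRs).
#' @param log_hr_per_ratio Slope on `log1p(re-adjusted N ratio)` when
#'   `hazard_model = "ratio"`.
#' @param baseline_median_months Baseline median survival (months) for a
#'   patient with linear predictor 0.
#' @param weibull_shape Weibull shape of the baseline hazard (1 = exponential).
#' @param admin_censor_months Administrative censoring horizon (months).
#' @param target_event_frac Observed event (death) fraction the censoring
#'   process is calibrated to; uniform loss-to-follow-up is tuned by
#'   root-finding on the generated sample.
#' @param ajcc_bins Lower edges of the positive-node-count bins for the
#'   count-based comparator N stage (defaults to the 7th-edition convention
#'   0 / 1-2 / 3-6 / >=7).
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @seealso [simulate_cohort()], [summarize_cohort()]
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 500, seed = 7)
#' cohort <- simulate_cohort(cfg)
cohort_config <- function(n_patients = 13491,
                          seed = 1L,
                          mean_age = 66.70,
                          sd_age = 11.12,
                          prop_male = 0.799,
                          race_props = c(white = 0.849, black = 0.101, other = 0.047) / 0.997,
                          mean_tumor_size = 366.58,
                          sd_tumor_size = 179.92,
                          nln_mean = 12,
                          nln_dispersion = 2,
                          pln_zero_prob = 0.45,
                          pln_mean = 2.8,
                          pln_dispersion = 1.2,
                          log_hr_per_pln = log(1.064),
                          log_hr_per_nln = log(0.962),
                          log_hr_age = 0,
                          log_hr_male = 0,
                          log_hr_tumor_size = 0,
                          hazard_model = c("nodes", "ratio"),
                          log_hr_per_ratio = log(2),
                          baseline_median_months = 10,
                          weibull_shape = 1,
                          admin_censor_months = 96,
                          target_event_frac = 0.605,
                          ajcc_bins = c(1L, 3L, 7L)) {
  hazard_model <- match.arg(hazard_model)
  assert_that(is_whole(n_patients) && n_patients >= 1, "n_patients must be a positive integer")
  assert_that(is.numeric(seed) && length(seed) == 1, "seed must be a single integer")
  for (fr in list(prop_male = prop_male, pln_zero_prob = pln_zero_prob,
                  target_event_frac = target_event_frac)) {
    assert_that(is.numeric(fr) && fr >= 0 && fr <= 1, "fractions must lie in [0, 1]")
  }
  assert_that(length(race_props) == 3 && all(race_props >= 0),
              "race_props must be three non-negative fractions")
  assert_that(abs(sum(race_props) - 1) < 1e-6, "race_props must sum to 1")
  race_props <- race_props / sum(race_props)
  if (is.null(names(race_props))) names(race_props) <- c("white", "black", "other")
  assert_that(sd_age >= 0 && sd_tumor_size >= 0, "sd terms must be >= 0")
  assert_that(nln_mean >= 0 && nln_dispersion > 0 && pln_mean >= 0 && pln_dispersion > 0,
              "count-distribution parameters must be positive")
  assert_that(baseline_median_months > 0 && weibull_shape > 0 && admin_censor_months > 0,
              "survival-model parameters must be positive")
  assert_that(length(ajcc_bins) == 3 && all(diff(ajcc_bins) > 0) && all(ajcc_bins >= 1),
              "ajcc_bins must be three increasing positive integers")

  structure(
    list(
      n_patients = as.integer(n_patients), seed = as.integer(seed),
      mean_age = mean_age, sd_age = sd_age, prop_male = prop_male,
      race_props = race_props,
      mean_tumor_size = mean_tumor_size, sd_tumor_size = sd_tumor_size,
      nln_mean = nln_mean, nln_dispersion = nln_dispersion,
      pln_zero_prob = pln_zero_prob, pln_mean = pln_mean,
      pln_dispersion = pln_dispersion,
      log_hr_per_pln = log_hr_per_pln, log_hr_per_nln = log_hr_per_nln,
      log_hr_age = log_hr_age, log_hr_male = log_hr_male,
      log_hr_tumor_size = log_hr_tumor_size,
      hazard_model = hazard_model, log_hr_per_ratio = log_hr_per_ratio,
      baseline_median_months = baseline_median_months,
      weibull_shape = weibull_shape,
      admin_censor_months = admin_censor_months,
      target_event_frac = target_event_frac,
      ajcc_bins = as.integer(ajcc_bins)
    ),
    class = "cohort_config"
  )
}

#' Simulate a SEER-like esophageal-cancer cohort
#'
#' Generates a patient-level cohort with known ground-truth per-node hazard
#' effects, so every downstream stage of the ratio-staging pipeline can be
#' tested without external registry data. Identical `config` and `seed`
#' yield an identical cohort.
#'
#' Survival is drawn from a Weibull proportional-hazards model; observation
#' time is the minimum of the survival time, the administrative horizon, and
#' a uniform loss-to-follow-up time whose scale is calibrated by
#' root-finding so the realised event fraction matches
#' `config$target_event_frac`. Times are recorded as whole months (SEER
#' convention; minimum 1), so tied event times are expected.
#'
#' @param config A [cohort_config()] object.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A tibble with one row per patient: `id`, `survival_months`,
#'   `event`, `n_pln`, `n_nln`, `ajcc_n` (count-based comparator stage 0-3),
#'   demographic and tumor covariates, metastasis flags, `surgery_flag`,
#'   and `cause_specific`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed) {
  assert_that(inherits(config, "cohort_config"), "config must be created by cohort_config()")
  withr::with_seed(as.integer(seed), simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- config$n_patients

  age <- rnorm(n, config$mean_age, config$sd_age)
  sex <- ifelse(runif(n) < config$prop_male, "male", "female")
  race <- sample(names(config$race_props), n, replace = TRUE, prob = config$race_props)
  tumor_size <- pmax(1, rnorm(n, config$mean_tumor_size, config$sd_tumor_size))
  tumor_site <- sample(c("cervical", "thoracic", "abdominal", "overlapping"), n,
                       replace = TRUE, prob = c(0.10, 0.60, 0.25, 0.05))
  grade <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                  prob = c(0.08, 0.35, 0.45, 0.12))
  ajcc_group <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                       prob = c(0.12, 0.30, 0.38, 0.20))
  radiation_sequence <- sample(
    c("none", "prior_to_surgery", "after_surgery", "before_and_after",
      "surgery_both", "sequence_unknown"),
    n, replace = TRUE, prob = c(0.55, 0.25, 0.12, 0.04, 0.01, 0.03)
  )
  met_bone <- rbinom(n, 1, 0.040)
  met_brain <- rbinom(n, 1, 0.015)
  met_liver <- rbinom(n, 1, 0.080)
  met_lung <- rbinom(n, 1, 0.070)

  n_nln <- rnbinom(n, size = config$nln_dispersion, mu = config$nln_mean)
  n_pln <- ifelse(runif(n) < config$pln_zero_prob, 0L,
                  rnbinom(n, size = config$pln_dispersion, mu = config$pln_mean))

  lp <- config$log_hr_age * (age - config$mean_age) +
    config$log_hr_male * (sex == "male") +
    config$log_hr_tumor_size * (tumor_size - config$mean_tumor_size)
  if (config$hazard_model == "nodes") {
    lp <- lp + config$log_hr_per_pln * n_pln + config$log_hr_per_nln * n_nln
  } else {
    w <- nratio_weights(exp(config$log_hr_per_pln), exp(config$log_hr_per_nln))
    true_ratio <- readjusted_n_ratio(n_pln, n_nln, w)
    lp <- lp + config$log_hr_per_ratio * log1p(true_ratio)
  }

  # Weibull PH: S(t) = exp(-lambda0 * exp(lp) * t^shape)
  shape <- config$weibull_shape
  lambda0 <- log(2) / config$baseline_median_months^shape
  t_death <- (rexp(n) / (lambda0 * exp(lp)))^(1 / shape)

  censor <- calibrate_censoring(t_death, config$admin_censor_months,
                                config$target_event_frac, runif(n))
  event <- as.integer(t_death <= censor)
  obs <- pmin(t_death, censor)
  survival_months <- pmax(1, ceiling(obs))

  tibble::tibble(
    id = sprintf("P%06d", seq_len(n)),
    survival_months = as.numeric(survival_months),
    event = event,
    n_pln = as.integer(n_pln),
    n_nln = as.integer(n_nln),
    ajcc_n = ajcc_stage_from_pln(n_pln, config$ajcc_bins),
    age = age,
    sex = sex,
    race = race,
    tumor_site = tumor_site,
    tumor_size = tumor_size,
    grade = grade,
    ajcc_group = ajcc_group,
    radiation_sequence = radiation_sequence,
    met_bone = met_bone,
    met_brain = met_brain,
    met_liver = met_liver,
    met_lung = met_lung,
    surgery_flag = 1L,
    cause_specific = 1L
  )
}

# Uniform loss-to-follow-up scale b such that, with censoring time
# min(admin, b * u), the realised event fraction matches the target.
# u are pre-drawn U(0,1); the calibration is deterministic given the draws.
calibrate_censoring <- function(t_death, admin, target, u) {
  frac_max <- mean(t_death <= admin)
  if (frac_max <= target) {
    return(rep(admin, length(t_death)))
  }
  f <- function(b) mean(t_death <= pmin(admin, b * u)) - target
  b <- uniroot(f, lower = 1e-9, upper = 1e9, tol = 1e-10)$root
  pmin(admin, b * u)
}

#' Count-based (AJCC 7th-edition style) N stage from the positive-node count
#'
#' @param n_pln Integer vector of positive regional node counts.
#' @param bins Lower edges of stages 1-3 (default 0 / 1-2 / 3-6 / >=7).
#' @return Integer stage 0-3.
#' @export
ajcc_stage_from_pln <- function(n_pln, bins = c(1L, 3L, 7L)) {
  assert_that(all(is_whole(n_pln) & n_pln >= 0), "n_pln must be non-negative integers")
  findInterval(n_pln, bins)
}

#' Baseline summary of a cohort
#'
#' One-row tibble of the marginal summaries used to check generator
#' calibration and to describe a study population: mean/SD of age, tumor
#' size and observed survival months, sex and race proportions, the event
#' fraction, and node-count summaries.
#'
#' @param cohort A cohort tibble (as from [simulate_cohort()] or [read_cohort()]).
#' @return A one-row tibble.
#' @export
summarize_cohort <- function(cohort) {
  assert_that(is.data.frame(cohort) && nrow(cohort) > 0, "empty input: cohort has no records")
  sd0 <- function(x) if (length(x) < 2) 0 else sd(x)
  tibble::tibble(
    n = nrow(cohort),
    age_mean = mean(cohort$age), age_sd = sd0(cohort$age),
    tumor_size_mean = mean(cohort$tumor_size), tumor_size_sd = sd0(cohort$tumor_size),
    survival_mean = mean(cohort$survival_months), survival_sd = sd0(cohort$survival_months),
    prop_male = mean(cohort$sex == "male"),
    prop_white = mean(cohort$race == "white"),
    prop_black = mean(cohort$race == "black"),
    prop_other = mean(!cohort$race %in% c("white", "black")),
    event_frac = mean(cohort$event),
    pln_mean = mean(cohort$n_pln, na.rm = TRUE),
    pln_median = median(cohort$n_pln, na.rm = TRUE),
    nln_mean = mean(cohort$n_nln, na.rm = TRUE),
    nln_median = median(cohort$n_nln, na.rm = TRUE)
  )
}
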