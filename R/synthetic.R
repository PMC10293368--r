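## Synthetic cohort generator.
##
## Emulates the marginal covariate structure of a surgically treated
## elderly hip-fracture population (prevalences configurable; defaults set
## to a published validation cohort of 344 patients) and an outcome
## mechanism producing the study's 30-day / 1-year / 8-year mortality
## pattern. Covariates are drawn independently by default, with two
## documented dependence knobs. Age is drawn from a piecewise-uniform
## distribution over integer years whose segment masses reproduce every
## age-band prevalence used by the three models simultaneously.

#' Default covariate prevalences of the synthetic cohort
#'
#' Marginal prevalences for every scored variable, plus the piecewise
#' age-segment table (`lo`, `hi` in completed years, `p` the segment mass).
#' Categorical vectors (`asa`, `residence`, `mobility`, `fracture`) sum to
#' one; the residence baseline absorbs patients whose residence would be
#' unrecorded in practice (missing scores as own home).
#'
#' @return Named list of prevalences; see [cohort_config()].
#' @export
default_prevalences <- function() {
  list(
    male = 0.297,
    haemoglobin_le10 = 0.070,
    cognitive_impairment = 0.186,
    institutional_residence = 0.198,
    comorbidities_ge2 = 0.337,
    malignancy = 0.172,
    asa = c("1" = 0.160, "2" = 0.529, "3" = 0.282, "4" = 0.029, "5" = 0),
    residence = c(own_home = 0.799, long_term_care = 0.169,
                  rehabilitation = 0.020, acute_hospital_ward = 0.012),
    mobility = c(no_aids = 0.759, one_aid = 0.023, two_aids_frame = 0.180,
                 requires_accompaniment = 0.026, unable_to_walk = 0.012),
    fracture = c(intracapsular = 0.334, extracapsular = 0.587,
                 subtrochanteric = 0.067, pathological = 0.012),
    in_hospital_fracture = 0.012,
    malnutrition = 0.006,
    myocardial_infarction = 0.049,
    congestive_heart_failure = 0.058,
    pneumonia = 0.006,
    renal_disease = 0.058,
    serum_urea_gt9 = 0.087,
    # Segment masses jointly reproduce: <66 .212 / 66-85 .456 / >=86 .331
    # (NHFS), <60 .125 / 60-69 .140 / 70-79 .189 / 80-89 .372 / >=90 .174
    # (Holt) and >=85 .372 (HEMA). Implied median age is 81.
    age_segments = data.frame(
      lo = c(50, 60, 66, 70, 80, 85, 86, 90),
      hi = c(59, 65, 69, 79, 84, 85, 89, 99),
      p = c(0.125, 0.087, 0.053, 0.189, 0.174, 0.041, 0.157, 0.174))
  )
}

#' Outcome mechanisms for the synthetic cohort
#'
#' `mechanism_marginal_rate()` gives every patient the same piecewise-
#' exponential hazard, calibrated so that the marginal probabilities of
#' death by 30 days, 1 year and 8 years equal `p30`, `p1y`, `p8y`.
#'
#' `mechanism_logistic()` makes the named model the true model: each
#' patient's 30-day death is Bernoulli with the model's own predicted
#' probability, and the post-30-day hazard of each patient is multiplied by
#' `exp(beta * z)` with `z` the within-cohort standardised score, so higher
#' scoring patients die earlier (producing separated risk-group survival
#' curves). The baseline post-30-day rates are calibrated numerically so
#' the marginal 1-year and 8-year mortality still hit `p1y` and `p8y`.
#'
#' @param p30,p1y,p8y Target marginal mortality at 30 days, 1 year,
#'   8 years; must be non-decreasing.
#' @param model_id Which model generates the true 30-day risk.
#' @param beta Log-hazard-ratio per standard deviation of score for the
#'   post-30-day period.
#' @return Object of class `hip_mechanism`.
#' @examples
#' mechanism_marginal_rate()
#' mechanism_logistic("NHFS")
#' @export
mechanism_marginal_rate <- function(p30 = 0.061, p1y = 0.191, p8y = 0.686) {
  .check_targets(p30, p1y, p8y)
  structure(list(type = "marginal_rate", p30 = p30, p1y = p1y, p8y = p8y),
            class = "hip_mechanism")
}

#' @rdname mechanism_marginal_rate
#' @export
mechanism_logistic <- function(model_id = "NHFS", p1y = 0.191, p8y = 0.686,
                               beta = 0.6) {
  model_id <- match.arg(model_id, MODEL_IDS)
  if (!(p1y <= p8y) || p1y < 0 || p8y >= 1)
    stop("invalid config: need 0 <= p1y <= p8y < 1")
  structure(list(type = "logistic_true_model", model_id = model_id,
                 p1y = p1y, p8y = p8y, beta = beta),
            class = "hip_mechanism")
}

.check_targets <- function(p30, p1y, p8y) {
  if (!(p30 <= p1y && p1y <= p8y) || p30 < 0 || p8y >= 1)
    stop("invalid config: mortality targets must satisfy 0 <= p30 <= p1y <= p8y < 1")
  invisible(TRUE)
}

#' Configuration of a synthetic cohort
#'
#' @param n Cohort size (default 344, the size of the validation study this
#'   generator emulates).
#' @param seed Integer seed; the whole cohort is reproducible given
#'   (config, seed).
#' @param prevalences Marginal prevalences, see [default_prevalences()].
#' @param outcome_mechanism A mechanism from [mechanism_marginal_rate()] or
#'   [mechanism_logistic()].
#' @param censoring_rate Probability that a patient is lost to follow-up at
#'   a uniform time before 8 years (default 0.076).
#' @param residence_follows_institution Dependence knob: when `TRUE`,
#'   institutionalised patients receive the long-term-care residence
#'   category and the remaining residence categories are renormalised over
#'   the non-institutionalised (residence marginals then derive from the
#'   institution prevalence rather than being set independently).
#' @param impairment_institution_or Dependence knob: odds ratio of
#'   cognitive impairment for institutionalised versus non-institutionalised
#'   patients; the marginal impairment prevalence is preserved. 1 = off.
#' @return Object of class `cohort_config`.
#' @examples
#' cohort_config(n = 100, seed = 42)
#' @export
cohort_config <- function(n = 344, seed = 1L,
                          prevalences = default_prevalences(),
                          outcome_mechanism = mechanism_marginal_rate(),
                          censoring_rate = 0.076,
                          residence_follows_institution = FALSE,
                          impairment_institution_or = 1) {
  if (n < 1) stop("invalid config: n must be a positive integer")
  stopifnot(inherits(outcome_mechanism, "hip_mechanism"))
  if (censoring_rate < 0 || censoring_rate > 1)
    stop("invalid config: censoring_rate must be a probability")
  pr <- utils::modifyList(default_prevalences(), prevalences)
  scalars <- setdiff(names(pr), "age_segments")
  for (nm in scalars)
    if (any(pr[[nm]] < 0) || any(pr[[nm]] > 1))
      stop(sprintf("invalid config: prevalence '%s' outside [0, 1]", nm))
  for (nm in c("asa", "residence", "mobility", "fracture"))
    if (abs(sum(pr[[nm]]) - 1) > 1e-8)
      stop(sprintf("invalid config: '%s' category probabilities must sum to 1", nm))
  if (abs(sum(pr$age_segments$p) - 1) > 1e-8)
    stop("invalid config: age segment masses must sum to 1")
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    stopifnot(abs(seed) < 2^30)
  }
  structure(list(n = as.integer(n), seed = seed, prevalences = pr,
                 outcome_mechanism = outcome_mechanism,
                 censoring_rate = censoring_rate,
                 residence_follows_institution = residence_follows_institution,
                 impairment_institution_or = impairment_institution_or),
            class = "cohort_config")
}

# Solve impairment probabilities by institution status so that the odds
# ratio is `or` and the marginal prevalence is preserved.
.impairment_by_institution <- function(p_marginal, p_inst, or) {
  if (or == 1 || p_inst == 0 || p_inst == 1)
    return(c(p0 = p_marginal, p1 = p_marginal))
  f <- function(p0) {
    odds1 <- or * p0 / (1 - p0)
    p1 <- odds1 / (1 + odds1)
    (1 - p_inst) * p0 + p_inst * p1 - p_marginal
  }
  p0 <- stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  odds1 <- or * p0 / (1 - p0)
  c(p0 = p0, p1 = odds1 / (1 + odds1))
}

#' Draw a synthetic covariate table
#'
#' Independent draws per variable at the configured prevalences (plus the
#' two optional dependence knobs). Laboratory values are drawn uniformly
#' within the band implied by their threshold flag, and a surgery date is
#' drawn uniformly over an 18-month inclusion window.
#'
#' @param config A [cohort_config()].
#' @param seed Optional override of `config$seed`; `NULL` with a `NULL`
#'   config seed leaves the RNG state untouched.
#' @return Data frame in the documented cohort schema (without follow-up
#'   columns); includes `patient_id` and `surgery_date`.
#' @export
sample_covariates <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  pr <- config$prevalences
  seg <- pr$age_segments
  si <- sample.int(nrow(seg), n, replace = TRUE, prob = seg$p)
  age <- seg$lo[si] + floor(stats::runif(n) * (seg$hi[si] - seg$lo[si] + 1))
  sex <- ifelse(stats::runif(n) < pr$male, "male", "female")
  hb_low <- stats::runif(n) < pr$haemoglobin_le10
  haemoglobin <- round(ifelse(hb_low, stats::runif(n, 8.2, 10.0),
                              stats::runif(n, 10.3, 15.5)), 1)
  institutional <- stats::runif(n) < pr$institutional_residence
  p_imp <- .impairment_by_institution(pr$cognitive_impairment,
                                      pr$institutional_residence,
                                      config$impairment_institution_or)
  cognitive <- stats::runif(n) < ifelse(institutional, p_imp[["p1"]],
                                        p_imp[["p0"]])
  ge2 <- stats::runif(n) < pr$comorbidities_ge2
  n_comorbidities <- ifelse(ge2, 2L + stats::rpois(n, 0.7),
                            stats::rbinom(n, 1L, 0.45))
  malignancy <- stats::runif(n) < pr$malignancy
  asa <- as.integer(sample(names(pr$asa), n, replace = TRUE, prob = pr$asa))
  if (config$residence_follows_institution) {
    other <- pr$residence[c("rehabilitation", "acute_hospital_ward")]
    rest <- c(own_home = 1 - sum(other), other)
    residence <- ifelse(institutional, "long_term_care",
                        sample(names(rest), n, replace = TRUE, prob = rest))
  } else {
    residence <- sample(names(pr$residence), n, replace = TRUE,
                        prob = pr$residence)
  }
  mobility <- sample(names(pr$mobility), n, replace = TRUE, prob = pr$mobility)
  fracture <- sample(names(pr$fracture), n, replace = TRUE, prob = pr$fracture)
  urea_high <- stats::runif(n) < pr$serum_urea_gt9
  serum_urea <- round(ifelse(urea_high, stats::runif(n, 9.1, 20.0),
                             stats::runif(n, 2.5, 9.0)), 1)
  surgery_date <- as.Date("2012-01-01") +
    floor(stats::runif(n) * 547)  # 18-month inclusion window
  data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = as.integer(age), sex = sex, haemoglobin = haemoglobin,
    cognitive_impairment = cognitive, institutional_residence = institutional,
    n_comorbidities = as.integer(n_comorbidities), malignancy = malignancy,
    asa = asa, prefracture_residence = residence,
    prefracture_mobility = mobility, fracture_type = fracture,
    in_hospital_fracture = stats::runif(n) < pr$in_hospital_fracture,
    malnutrition = stats::runif(n) < pr$malnutrition,
    myocardial_infarction = stats::runif(n) < pr$myocardial_infarction,
    congestive_heart_failure = stats::runif(n) < pr$congestive_heart_failure,
    pneumonia = stats::runif(n) < pr$pneumonia,
    renal_disease = stats::runif(n) < pr$renal_disease,
    serum_urea = serum_urea,
    surgery_date = surgery_date)
}

# Expected crude mortality rate at horizon h under the piecewise death
# model (30-day probability p30_i with a uniform day of death, exponential
# hazards l2*mult and l3*mult on days 30-365 and 365+) overlaid with
# independent loss to follow-up (probability cens, time uniform on (0, H]).
# The crude rate excludes patients lost alive before h from the
# denominator, exactly as the pipeline's observed_mortality_rate does; the
# selection it induces is accounted for analytically so the configured
# targets are recovered by the *observed* rates, not just the latent ones.
.expected_crude_rate <- function(h, p30_i, l2, l3, mult, cens, H = 2922) {
  a <- l2 * mult
  b <- l3 * mult
  t1 <- pmin(h, 30)
  I <- t1 - p30_i * t1^2 / 60           # integral of S(u) = 1 - p30*u/30
  S_h <- 1 - p30_i * t1 / 30
  if (h > 30) {
    t2 <- pmin(h, 365) - 30
    S30 <- 1 - p30_i
    I <- I + ifelse(a > 0, S30 * (1 - exp(-a * t2)) / a, S30 * t2)
    S_h <- S30 * exp(-a * t2)
  }
  if (h > 365) {
    t3 <- h - 365
    S1y <- (1 - p30_i) * exp(-a * 335)
    I <- I + ifelse(b > 0, S1y * (1 - exp(-b * t3)) / b, S1y * t3)
    S_h <- S1y * exp(-b * t3)
  }
  obs_death <- (1 - S_h) - (cens / H) * (I - h * S_h)
  unknown <- (cens / H) * I
  mean(obs_death) / (1 - mean(unknown))
}

# Calibrate the post-30-day baseline rates so the expected crude mortality
# rates at 1 year and 8 years hit the targets. p30_i: per-patient 30-day
# death probability; mult: per-patient hazard multiplier.
.calibrate_rates <- function(p30_i, p1y, p8y, mult, cens) {
  if (mean(p30_i) > p1y + 1e-12)
    stop("invalid config: mean 30-day mortality exceeds the 1-year target")
  f1 <- function(l2)
    .expected_crude_rate(365, p30_i, l2, 0, mult, cens) - p1y
  lambda2 <- if (abs(f1(0)) < 1e-12) 0 else
    stats::uniroot(f1, c(0, 1), extendInt = "upX", tol = 1e-14)$root
  f8 <- function(l3)
    .expected_crude_rate(2922, p30_i, lambda2, l3, mult, cens) - p8y
  lambda3 <- if (abs(f8(0)) < 1e-12) 0 else
    stats::uniroot(f8, c(0, 1), extendInt = "upX", tol = 1e-14)$root
  list(lambda2 = lambda2, lambda3 = lambda3)
}

#' Draw follow-up records for a covariate table
#'
#' Simulates each patient's death time from the mechanism (30-day death as
#' a Bernoulli draw with a uniform day of death in days 1-30; later deaths
#' from piecewise-exponential hazards on days 30-365 and beyond 365), then
#' overlays independent loss to follow-up: a configured fraction of
#' patients draws a censoring time uniform over the 8-year window, and a
#' death is recorded only if it precedes censoring. Survivors past the
#' window are recorded alive at the administrative close-out.
#'
#' @param covariates Covariate table from [sample_covariates()].
#' @param mechanism A `hip_mechanism`.
#' @param censoring_rate Probability of loss to follow-up before 8 years.
#' @param seed Optional seed (`NULL` = use current RNG state).
#' @return Data frame with `surgery_date`, `death_date`,
#'   `last_known_alive_date`.
#' @export
sample_outcomes <- function(covariates, mechanism, censoring_rate = 0.076,
                            seed = NULL) {
  stopifnot(inherits(mechanism, "hip_mechanism"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(covariates)
  if (n == 0L) stop("invalid input: empty covariate table")
  if (mechanism$type == "marginal_rate") {
    p30_i <- rep(mechanism$p30, n)
    mult <- rep(1, n)
  } else {
    scorer <- list(NHFS = score_nhfs, HOLT = score_holt, HEMA = score_hema)
    score <- scorer[[mechanism$model_id]](apply_missing_policy(covariates,
                                                               quiet = TRUE))
    p30_i <- predicted_mortality(mechanism$model_id, score)
    z <- if (stats::sd(score) > 0) (score - mean(score)) / stats::sd(score)
         else rep(0, n)
    mult <- exp(mechanism$beta * z)
  }
  rates <- .calibrate_rates(p30_i, mechanism$p1y, mechanism$p8y, mult,
                            cens = censoring_rate)
  die30 <- stats::runif(n) < p30_i
  death_day <- rep(NA_real_, n)
  death_day[die30] <- ceiling(stats::runif(sum(die30)) * 30)
  surv <- which(!die30)
  if (length(surv)) {
    e2 <- stats::rexp(length(surv)) / pmax(rates$lambda2 * mult[surv], 1e-300)
    mid <- surv[e2 <= 335]
    death_day[mid] <- 30 + ceiling(e2[e2 <= 335])
    late <- surv[e2 > 335]
    if (length(late)) {
      e3 <- stats::rexp(length(late)) / pmax(rates$lambda3 * mult[late], 1e-300)
      death_day[late] <- 365 + ceiling(e3)
    }
  }
  lost <- stats::runif(n) < censoring_rate
  censor_day <- ifelse(lost, ceiling(stats::runif(n) * 2922), 2923)
  observed_death <- !is.na(death_day) & death_day <= censor_day
  surgery <- as.Date(covariates$surgery_date)
  death_date <- as.Date(ifelse(observed_death, surgery + death_day, NA),
                        origin = "1970-01-01")
  last_alive <- as.Date(ifelse(observed_death, NA, surgery + censor_day),
                        origin = "1970-01-01")
  data.frame(surgery_date = surgery, death_date = death_date,
             last_known_alive_date = last_alive)
}

#' Generate a complete synthetic cohort
#'
#' Composes [sample_covariates()] and [sample_outcomes()] under the
#' config's seed and optionally writes the cohort CSV (schema identical to
#' real-data input, so the pipeline cannot distinguish the two).
#'
#' @param config A [cohort_config()].
#' @param path Optional CSV output path.
#' @return The cohort data frame, with the config attached as attribute
#'   `provenance`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 50, seed = 7))
#' nrow(cohort)
#' @export
generate_cohort <- function(config, path = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  cov <- sample_covariates(config, seed = config$seed)
  fu <- sample_outcomes(cov, config$outcome_mechanism,
                        censoring_rate = config$censoring_rate,
                        seed = if (is.null(config$seed)) NULL
                               else config$seed + 500009L)
  cohort <- cbind(cov, fu[c("death_date", "last_known_alive_date")])
  attr(cohort, "provenance") <- config
  if (!is.null(path)) write_cohort(cohort, path)
  cohort
}
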