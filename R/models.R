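#' @section Models:
#' Three published prognostic models for mortality after hip fracture surgery
#' are encoded: the Nottingham Hip Fracture Score (NHFS, seven variables,
#' integer points, maximum 10), the model of Holt and colleagues developed on
#' the Scottish Hip Fracture Audit (six variables with 23 subdivisions,
#' signed coefficients to two decimals), and the Hip fracture Estimator of
#' Mortality Amsterdam (HEMA, nine variables, points in half-point steps).
#' Each model maps a cumulative score to a predicted 30-day mortality
#' probability through a logistic link, and to a low/intermediate/high risk
#' group through published cut-offs.
#'
#' @keywords internal
"_PACKAGE"

## Canonical identifiers and categorical levels used throughout the package.

#' Model identifiers and categorical level sets
#'
#' Canonical vocabulary of the cohort schema: the three model identifiers,
#' the ordered risk levels, and the admissible categories for sex,
#' pre-fracture residence, pre-fracture mobility and fracture type.
#'
#' @name hipmort-vocabulary
#' @export
MODEL_IDS <- c("NHFS", "HOLT", "HEMA")

#' @rdname hipmort-vocabulary
#' @export
RISK_LEVELS <- c("low", "intermediate", "high")

#' @rdname hipmort-vocabulary
#' @export
SEX_LEVELS <- c("male", "female")

#' @rdname hipmort-vocabulary
#' @export
RESIDENCE_LEVELS <- c("own_home", "long_term_care", "rehabilitation",
                      "acute_hospital_ward")

#' @rdname hipmort-vocabulary
#' @export
MOBILITY_LEVELS <- c("no_aids", "one_aid", "two_aids_frame",
                     "requires_accompaniment", "unable_to_walk")

#' @rdname hipmort-vocabulary
#' @export
FRACTURE_LEVELS <- c("intracapsular", "extracapsular", "subtrochanteric",
                     "pathological")

# Logistic link: P(death by 30 d) = 1 / (1 + exp(intercept - slope * score)).
.link_constants <- list(
  NHFS = list(intercept = 5.0122, slope = 0.481),
  HOLT = list(intercept = 4.79,   slope = 1),
  HEMA = list(intercept = 3.823,  slope = 1)
)

# Holt et al. regression coefficients per subdivision (baseline = 0).
.holt_coef <- list(
  age = c("<60" = 0, "60-69" = 0.58, "70-79" = 1.24, "80-89" = 1.74,
          ">=90" = 1.96),
  asa = c("1-2" = 0, "3" = 0.80, "4-5" = 1.62),
  sex = c(male = 0, female = -0.65),
  residence = c(own_home = 0, long_term_care = 0.53, rehabilitation = 0.53,
                acute_hospital_ward = 0.59),
  mobility = c(no_aids = 0, one_aid = -0.02, two_aids_frame = 0.07,
               requires_accompaniment = 0.24, unable_to_walk = 0.45),
  fracture = c(intracapsular = 0, extracapsular = 0.12,
               subtrochanteric = 0.28, pathological = 1.32)
)

# HEMA points per positive variable.
.hema_points <- c(age_ge85 = 1, in_hospital_fracture = 2, malnutrition = 2,
                  myocardial_infarction = 1, congestive_heart_failure = 1,
                  pneumonia = 2, renal_disease = 1, malignancy = 1.5,
                  serum_urea_gt9 = 0.5)

#' Definition of one risk model
#'
#' Returns the scoring table and logistic link constants of one of the three
#' models as a structured object. The same tables ship as human-readable JSON
#' under `inst/extdata/models/`, so the code-embedded constants can be
#' diffed against the versioned files.
#'
#' @param model_id One of `"NHFS"`, `"HOLT"`, `"HEMA"`.
#' @return An object of class `hip_model`: a list with `model_id`,
#'   `intercept`, `slope` and `rules`, a data frame with columns `variable`,
#'   `condition` and `points`.
#' @examples
#' model_definition("NHFS")
#' @export
model_definition <- function(model_id) {
  model_id <- match.arg(model_id, MODEL_IDS)
  rules <- switch(model_id,
    NHFS = data.frame(
      variable = c("age", "age", "age", "sex", "haemoglobin",
                   "cognitive_impairment", "institutional_residence",
                   "n_comorbidities", "malignancy"),
      condition = c("<66", "66-85", ">=86", "male", "<=10 g/dL", "yes",
                    "yes", ">=2", "yes"),
      points = c(0, 3, 4, 1, 1, 1, 1, 1, 1)),
    HOLT = data.frame(
      variable = c(rep("age", 5), rep("asa", 3), rep("sex", 2),
                   rep("prefracture_residence", 4),
                   rep("prefracture_mobility", 5),
                   rep("fracture_type", 4)),
      condition = c(names(.holt_coef$age), names(.holt_coef$asa),
                    names(.holt_coef$sex), names(.holt_coef$residence),
                    names(.holt_coef$mobility), names(.holt_coef$fracture)),
      points = unname(c(.holt_coef$age, .holt_coef$asa, .holt_coef$sex,
                        .holt_coef$residence, .holt_coef$mobility,
                        .holt_coef$fracture))),
    HEMA = data.frame(
      variable = c("age", "in_hospital_fracture", "malnutrition",
                   "myocardial_infarction", "congestive_heart_failure",
                   "pneumonia", "renal_disease", "malignancy", "serum_urea"),
      condition = c(">=85", "yes", "yes", "yes", "yes", "yes", "yes", "yes",
                    ">9 mmol/L"),
      points = unname(.hema_points)))
  structure(list(model_id = model_id,
                 intercept = .link_constants[[model_id]]$intercept,
                 slope = .link_constants[[model_id]]$slope,
                 rules = rules),
            class = "hip_model")
}

#' @export
print.hip_model <- function(x, ...) {
  cat(sprintf("<hip_model> %s: P(30-day death) = 1/(1 + exp(%g - %g * score))\n",
              x$model_id, x$intercept, x$slope))
  print(x$rules, row.names = FALSE)
  invisible(x)
}

# TRUE where x is present and true; missing values never fire a rule
# (missing-scored-as-negative policy).
.flag <- function(x) !is.na(x) & x

# Ensure the covariate table has every scoring column (absent ones become
# NA), and check hard invariants on the fields that are present.
.prepare_covariates <- function(cov) {
  cov <- as.data.frame(cov)
  needed <- c("age", "sex", "haemoglobin", "cognitive_impairment",
              "institutional_residence", "n_comorbidities", "malignancy",
              "asa", "prefracture_residence", "prefracture_mobility",
              "fracture_type", "in_hospital_fracture", "malnutrition",
              "myocardial_infarction", "congestive_heart_failure",
              "pneumonia", "renal_disease", "serum_urea")
  for (col in setdiff(needed, names(cov))) cov[[col]] <- NA
  if (any(is.na(cov$age))) stop("invalid input: age is required for scoring")
  if (any(cov$age < 0)) stop("invalid input: negative age")
  .check_levels(cov$sex, SEX_LEVELS, "sex")
  .check_levels(cov$prefracture_residence, RESIDENCE_LEVELS,
                "prefracture_residence")
  .check_levels(cov$prefracture_mobility, MOBILITY_LEVELS,
                "prefracture_mobility")
  .check_levels(cov$fracture_type, FRACTURE_LEVELS, "fracture_type")
  if (any(!is.na(cov$asa) & !(cov$asa %in% 1:5)))
    stop("invalid input: asa must be an integer in 1..5")
  if (any(.flag(cov$haemoglobin < 0)))
    stop("invalid input: negative haemoglobin")
  if (any(.flag(cov$serum_urea < 0)))
    stop("invalid input: negative serum urea")
  if (any(.flag(cov$n_comorbidities < 0)))
    stop("invalid input: negative comorbidity count")
  cov
}

.check_levels <- function(x, levels, what) {
  bad <- !is.na(x) & !(as.character(x) %in% levels)
  if (any(bad))
    stop(sprintf("invalid input: unknown %s category: %s", what,
                 paste(unique(as.character(x)[bad]), collapse = ", ")))
  invisible(TRUE)
}

#' Nottingham Hip Fracture Score
#'
#' Sums the seven NHFS items: age band (<66: 0, 66--85: 3, >=86: 4), male
#' sex (1), admission haemoglobin <=10 g/dL (1), cognitive impairment (1,
#' standing in for an Abbreviated Mental Test Score <=6), living in an
#' institution (1), two or more comorbidities (1) and a history of
#' malignancy (1). Missing optional fields score zero points.
#'
#' @param cov A data frame of patient covariates (see [apply_missing_policy]
#'   for the column dictionary); one row per patient.
#' @return Integer vector of scores in 0..10.
#' @examples
#' score_nhfs(data.frame(age = 70, sex = "female", haemoglobin = 11))
#' @export
score_nhfs <- function(cov) {
  cov <- .prepare_covariates(cov)
  age <- trunc(cov$age)
  pts <- ifelse(age >= 86, 4L, ifelse(age >= 66, 3L, 0L))
  as.integer(pts +
    (!is.na(cov$sex) & cov$sex == "male") +
    .flag(cov$haemoglobin <= 10) +
    .flag(cov$cognitive_impairment) +
    .flag(cov$institutional_residence) +
    .flag(cov$n_comorbidities >= 2) +
    .flag(cov$malignancy))
}

.holt_age_band <- function(age) {
  ifelse(age >= 90, ">=90",
    ifelse(age >= 80, "80-89",
      ifelse(age >= 70, "70-79",
        ifelse(age >= 60, "60-69", "<60"))))
}

#' Holt et al. risk score
#'
#' Sums the published logistic-regression coefficients for age band, ASA
#' class, sex, pre-fracture residence, pre-fracture mobility and fracture
#' type. Coefficients may be negative (female sex, one walking aid), so the
#' cumulative score is a real number. Missing categorical fields contribute
#' the baseline coefficient of zero.
#'
#' @inheritParams score_nhfs
#' @return Numeric vector of scores.
#' @examples
#' score_holt(data.frame(age = 82, sex = "female", asa = 3,
#'                       prefracture_residence = "long_term_care",
#'                       prefracture_mobility = "two_aids_frame",
#'                       fracture_type = "extracapsular"))
#' @export
score_holt <- function(cov) {
  cov <- .prepare_covariates(cov)
  age <- trunc(cov$age)
  asa_band <- ifelse(is.na(cov$asa), "1-2",
                     ifelse(cov$asa >= 4, "4-5",
                            ifelse(cov$asa == 3, "3", "1-2")))
  pick <- function(coefs, key, baseline) {
    key <- as.character(key)
    key[is.na(key)] <- baseline
    unname(coefs[key])
  }
  s <- unname(.holt_coef$age[.holt_age_band(age)]) +
    unname(.holt_coef$asa[asa_band]) +
    pick(.holt_coef$sex, cov$sex, "male") +
    pick(.holt_coef$residence, cov$prefracture_residence, "own_home") +
    pick(.holt_coef$mobility, cov$prefracture_mobility, "no_aids") +
    pick(.holt_coef$fracture, cov$fracture_type, "intracapsular")
  # canonicalise the floating-point sum: coefficients have two decimals, so
  # mathematically equal scores must compare equal
  round(s, 10)
}

#' Hip fracture Estimator of Mortality Amsterdam score
#'
#' Sums the nine HEMA items: age >=85 (1), in-hospital fracture (2), signs
#' of malnutrition (2), history of myocardial infarction (1), congestive
#' heart failure (1), current pneumonia (2), renal disease (1), malignancy
#' (1.5) and serum urea >9 mmol/L (0.5). Scores therefore move in steps of
#' 0.5, with a maximum of 12. Missing fields score zero.
#'
#' @inheritParams score_nhfs
#' @return Numeric vector of scores (multiples of 0.5).
#' @examples
#' score_hema(data.frame(age = 86, sex = "female", malignancy = TRUE,
#'                       serum_urea = 10))
#' @export
score_hema <- function(cov) {
  cov <- .prepare_covariates(cov)
  age <- trunc(cov$age)
  (age >= 85) * .hema_points[["age_ge85"]] +
    .flag(cov$in_hospital_fracture) * .hema_points[["in_hospital_fracture"]] +
    .flag(cov$malnutrition) * .hema_points[["malnutrition"]] +
    .flag(cov$myocardial_infarction) * .hema_points[["myocardial_infarction"]] +
    .flag(cov$congestive_heart_failure) * .hema_points[["congestive_heart_failure"]] +
    .flag(cov$pneumonia) * .hema_points[["pneumonia"]] +
    .flag(cov$renal_disease) * .hema_points[["renal_disease"]] +
    .flag(cov$malignancy) * .hema_points[["malignancy"]] +
    .flag(cov$serum_urea > 9) * .hema_points[["serum_urea_gt9"]]
}

#' Predicted 30-day mortality from a cumulative score
#'
#' Applies a model's logistic link: `1 / (1 + exp(intercept - slope *
#' score))`. The published formulas print the risk as a percentage
#' (`100 / (1 + e^[...])`); this function returns the probability.
#'
#' @param model_id One of `"NHFS"`, `"HOLT"`, `"HEMA"`, or a `hip_model`.
#' @param score Numeric vector of cumulative scores.
#' @return Probabilities in (0, 1), strictly increasing in `score`.
#' @examples
#' predicted_mortality("NHFS", 0:10)
#' @export
predicted_mortality <- function(model_id, score) {
  if (inherits(model_id, "hip_model")) model_id <- model_id$model_id
  model_id <- match.arg(model_id, MODEL_IDS)
  k <- .link_constants[[model_id]]
  stats::plogis(k$slope * score - k$intercept)
}

#' Risk-group classification from a cumulative score
#'
#' Published cut-offs: NHFS `<=3` low, `4--5` intermediate, `>=6` high;
#' Holt `<1` low, `1--2` intermediate (both boundaries included), `>2`
#' high; HEMA `<=1` low, `1.5--2` intermediate, `>=2.5` high. HEMA scores
#' strictly inside (1, 1.5) or (2, 2.5) are unreachable under half-point
#' scoring and raise an error, since they indicate an upstream scoring bug.
#'
#' @inheritParams predicted_mortality
#' @return Factor with ordered levels `low < intermediate < high`.
#' @examples
#' classify_risk("NHFS", c(0, 4, 6))
#' @export
classify_risk <- function(model_id, score) {
  if (inherits(model_id, "hip_model")) model_id <- model_id$model_id
  model_id <- match.arg(model_id, MODEL_IDS)
  eps <- 1e-9
  grp <- switch(model_id,
    NHFS = ifelse(score <= 3, "low",
                  ifelse(score <= 5, "intermediate", "high")),
    HOLT = ifelse(score < 1, "low",
                  ifelse(score <= 2, "intermediate", "high")),
    HEMA = {
      bad <- (score > 1 + eps & score < 1.5 - eps) |
             (score > 2 + eps & score < 2.5 - eps)
      if (any(bad))
        stop(sprintf(
          "invalid input: HEMA score %s is unreachable under 0.5-point granularity",
          paste(unique(score[bad]), collapse = ", ")))
      ifelse(score <= 1 + eps, "low",
             ifelse(score <= 2 + eps, "intermediate", "high"))
    })
  factor(grp, levels = RISK_LEVELS, ordered = TRUE)
}

#' Apply the missing-data policy to a raw cohort table
#'
#' Missing values are not imputed but scored as negative, mirroring use of
#' the models at the bedside: an absent boolean flag becomes `FALSE`, an
#' absent comorbidity count 0, absent ASA the baseline class 1, absent
#' residence/mobility the baseline category, and absent laboratory values
#' are retained as `NA` (their threshold rules never fire). Age, sex and
#' fracture type have no defensible baseline and must be present.
#'
#' The cohort column dictionary: `age` (integer years), `sex`
#' (`male`/`female`), `haemoglobin` (g/dL), `cognitive_impairment`,
#' `institutional_residence`, `n_comorbidities`, `malignancy`, `asa` (1-5),
#' `prefracture_residence` (`own_home`, `long_term_care`, `rehabilitation`,
#' `acute_hospital_ward`), `prefracture_mobility` (`no_aids`, `one_aid`,
#' `two_aids_frame`, `requires_accompaniment`, `unable_to_walk`),
#' `fracture_type` (`intracapsular`, `extracapsular`, `subtrochanteric`,
#' `pathological`), `in_hospital_fracture`, `malnutrition`,
#' `myocardial_infarction`, `congestive_heart_failure`, `pneumonia`,
#' `renal_disease` (logicals), `serum_urea` (mmol/L).
#'
#' @param records Data frame with at least `age`, `sex` and `fracture_type`.
#' @param quiet Suppress the per-field absence message.
#' @return The completed covariate data frame, with an `absences` attribute
#'   listing (row, field) pairs that were filled by the policy.
#' @examples
#' apply_missing_policy(data.frame(age = 60, sex = "female",
#'                                 fracture_type = "intracapsular"))
#' @export
apply_missing_policy <- function(records, quiet = FALSE) {
  records <- as.data.frame(records)
  for (col in c("age", "sex", "fracture_type")) {
    if (is.null(records[[col]]) || any(is.na(records[[col]])))
      stop(sprintf("invalid input: '%s' is required for every patient (rows: %s)",
                   col,
                   if (is.null(records[[col]])) "all"
                   else paste(which(is.na(records[[col]])), collapse = ", ")))
  }
  cov <- .prepare_covariates(records)
  bool_fields <- c("cognitive_impairment", "institutional_residence",
                   "malignancy", "in_hospital_fracture", "malnutrition",
                   "myocardial_infarction", "congestive_heart_failure",
                   "pneumonia", "renal_disease")
  absences <- list()
  note <- function(field, rows) {
    if (length(rows))
      absences[[length(absences) + 1L]] <<- data.frame(row = rows,
                                                       field = field)
  }
  for (f in bool_fields) {
    miss <- which(is.na(cov[[f]]))
    note(f, miss)
    cov[[f]] <- .flag(cov[[f]])
  }
  miss <- which(is.na(cov$n_comorbidities))
  note("n_comorbidities", miss)
  cov$n_comorbidities[miss] <- 0L
  miss <- which(is.na(cov$asa))
  note("asa", miss)
  cov$asa[miss] <- 1L
  miss <- which(is.na(cov$prefracture_residence))
  note("prefracture_residence", miss)
  cov$prefracture_residence <- as.character(cov$prefracture_residence)
  cov$prefracture_residence[miss] <- "own_home"
  miss <- which(is.na(cov$prefracture_mobility))
  note("prefracture_mobility", miss)
  cov$prefracture_mobility <- as.character(cov$prefracture_mobility)
  cov$prefracture_mobility[miss] <- "no_aids"
  note("haemoglobin", which(is.na(cov$haemoglobin)))
  note("serum_urea", which(is.na(cov$serum_urea)))
  absences <- if (length(absences)) do.call(rbind, absences)
              else data.frame(row = integer(), field = character())
  if (!quiet && nrow(absences) > 0) {
    tab <- table(absences$field)
    message("missing-data policy applied (scored as negative): ",
            paste(sprintf("%s x%d", names(tab), as.integer(tab)),
                  collapse = ", "))
  }
  attr(cov, "absences") <- absences
  cov
}

#' Score a cohort under one or more models
#'
#' Convenience wrapper: applies the missing-data policy, then for each
#' requested model computes the cumulative score, the predicted 30-day
#' mortality and the risk group.
#'
#' @param cohort Raw cohort data frame (see [apply_missing_policy]).
#' @param models Character vector of model identifiers.
#' @param quiet Suppress the missing-data message.
#' @return A data frame with, per model `m`, columns `<m>_score`,
#'   `<m>_prob` and `<m>_group`.
#' @examples
#' score_patients(data.frame(age = 90, sex = "male",
#'                           fracture_type = "extracapsular"))
#' @export
score_patients <- function(cohort, models = MODEL_IDS, quiet = FALSE) {
  models <- match.arg(models, MODEL_IDS, several.ok = TRUE)
  cov <- apply_missing_policy(cohort, quiet = quiet)
  out <- data.frame(row.names = seq_len(nrow(cov)))
  scorers <- list(NHFS = score_nhfs, HOLT = score_holt, HEMA = score_hema)
  for (m in models) {
    s <- scorers[[m]](cov)
    key <- tolower(m)
    out[[paste0(key, "_score")]] <- s
    out[[paste0(key, "_prob")]]  <- predicted_mortality(m, s)
    out[[paste0(key, "_group")]] <- classify_risk(m, s)
  }
  attr(out, "absences") <- attr(cov, "absences")
  out
}
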