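test_that("NHFS scoring reproduces the published point table", {
  expect_identical(score_nhfs(make_patient()), 0L)
  expect_identical(score_nhfs(make_patient(age = 70, haemoglobin = 11)), 3L)
  expect_identical(
    score_nhfs(make_patient(age = 90, sex = "male", haemoglobin = 9.5,
                            cognitive_impairment = TRUE,
                            institutional_residence = TRUE,
                            n_comorbidities = 3L, malignancy = TRUE)),
    10L)
  # boundary ages: 66-85 band is inclusive; age truncated to whole years
  expect_identical(score_nhfs(make_patient(age = 65)), 0L)
  expect_identical(score_nhfs(make_patient(age = 66)), 3L)
  expect_identical(score_nhfs(make_patient(age = 85)), 3L)
  expect_identical(score_nhfs(make_patient(age = 86)), 4L)
  expect_identical(score_nhfs(make_patient(age = 85.9)), 3L)
  # haemoglobin threshold is <= 10
  expect_identical(score_nhfs(make_patient(haemoglobin = 10)), 1L)
  expect_identical(score_nhfs(make_patient(haemoglobin = 10.1)), 0L)
  expect_error(score_nhfs(make_patient(age = -1)), "negative age")
})

test_that("exhaustive NHFS enumeration yields every score 0..10 and matches a rule-walk oracle", {
  grid <- expand.grid(age = c(60, 70, 90), male = c(FALSE, TRUE),
                      hb_low = c(FALSE, TRUE), impaired = c(FALSE, TRUE),
                      inst = c(FALSE, TRUE), ge2 = c(FALSE, TRUE),
                      malig = c(FALSE, TRUE))
  cov <- data.frame(
    age = grid$age, sex = ifelse(grid$male, "male", "female"),
    haemoglobin = ifelse(grid$hb_low, 9, 12),
    cognitive_impairment = grid$impaired,
    institutional_residence = grid$inst,
    n_comorbidities = ifelse(grid$ge2, 2L, 1L),
    malignancy = grid$malig)
  got <- score_nhfs(cov)
  oracle <- ifelse(grid$age >= 86, 4, ifelse(grid$age >= 66, 3, 0)) +
    grid$male + grid$hb_low + grid$impaired + grid$inst + grid$ge2 + grid$malig
  expect_identical(got, as.integer(oracle))
  expect_identical(sort(unique(got)), 0:10)
})

test_that("Holt scoring sums the published coefficients", {
  expect_equal(score_holt(make_patient(age = 55, sex = "male")), 0)
  expect_equal(
    score_holt(make_patient(age = 82, sex = "female", asa = 3,
                            prefracture_residence = "long_term_care",
                            prefracture_mobility = "two_aids_frame",
                            fracture_type = "extracapsular")),
    1.74 + 0.80 - 0.65 + 0.53 + 0.07 + 0.12)
  expect_equal(
    score_holt(make_patient(age = 95, sex = "male", asa = 4,
                            prefracture_residence = "acute_hospital_ward",
                            prefracture_mobility = "unable_to_walk",
                            fracture_type = "pathological")),
    1.96 + 1.62 + 0 + 0.59 + 0.45 + 1.32)
  # negative coefficients can drag the score below zero
  expect_equal(score_holt(make_patient(age = 55, sex = "female",
                                       prefracture_mobility = "one_aid")),
               -0.67)
  # age bands at their integer boundaries
  for (case in list(c(59, 0), c(60, 0.58), c(69, 0.58), c(70, 1.24),
                    c(79, 1.24), c(80, 1.74), c(89, 1.74), c(90, 1.96)))
    expect_equal(score_holt(make_patient(age = case[1], sex = "male")),
                 case[2])
  # rehabilitation shares the long-term-care coefficient
  expect_equal(
    score_holt(make_patient(sex = "male",
                            prefracture_residence = "rehabilitation")),
    score_holt(make_patient(sex = "male",
                            prefracture_residence = "long_term_care")))
  expect_error(score_holt(make_patient(fracture_type = "unknown_type")),
               "unknown fracture_type")
  expect_error(score_holt(make_patient(asa = 7)), "asa")
})

test_that("HEMA scoring sums the published half-point table", {
  expect_equal(score_hema(make_patient(age = 70)), 0)
  expect_equal(score_hema(make_patient(age = 86, malignancy = TRUE,
                                       serum_urea = 10)), 3.0)
  all_pos <- make_patient(age = 86, in_hospital_fracture = TRUE,
                          malnutrition = TRUE, myocardial_infarction = TRUE,
                          congestive_heart_failure = TRUE, pneumonia = TRUE,
                          renal_disease = TRUE, malignancy = TRUE,
                          serum_urea = 10)
  expect_equal(score_hema(all_pos), 12.0)
  # age threshold 85, urea threshold strictly > 9
  expect_equal(score_hema(make_patient(age = 85)), 1)
  expect_equal(score_hema(make_patient(age = 84)), 0)
  expect_equal(score_hema(make_patient(serum_urea = 9)), 0)
  expect_equal(score_hema(make_patient(serum_urea = 9.1)), 0.5)
})

test_that("logistic link reproduces every published risk-band edge at one decimal", {
  edges <- rbind(
    data.frame(model = "NHFS", score = 3:6, pct = c(2.7, 4.4, 6.9, 10.7)),
    data.frame(model = "HOLT", score = 1:2, pct = c(2.2, 5.8)),
    data.frame(model = "HEMA", score = c(1, 1.5, 2, 2.5),
               pct = c(5.6, 8.9, 13.9, 21.0)))
  for (i in seq_len(nrow(edges)))
    expect_equal(
      round(100 * predicted_mortality(edges$model[i], edges$score[i]), 1),
      edges$pct[i])
})

test_that("predicted mortality is a strictly increasing probability of the score", {
  for (m in MODEL_IDS) {
    s <- seq(-1, 12, by = 0.5)
    p <- predicted_mortality(m, s)
    expect_true(all(p > 0 & p < 1))
    expect_true(all(diff(p) > 0))
  }
  # monotone in score implies AUC on scores equals AUC on probabilities
})

test_that("risk-group classification follows the published cut-offs and is monotone", {
  expect_equal(as.character(classify_risk("NHFS", c(0, 3, 4, 5, 6, 10))),
               c("low", "low", "intermediate", "intermediate", "high", "high"))
  # Holt boundary ownership: exactly 1 and exactly 2 are intermediate
  expect_equal(as.character(classify_risk("HOLT", c(-0.67, 0.99, 1, 2, 2.01))),
               c("low", "low", "intermediate", "intermediate", "high"))
  expect_equal(as.character(classify_risk("HEMA", c(0, 1, 1.5, 2, 2.5, 12))),
               c("low", "low", "intermediate", "intermediate", "high", "high"))
  # HEMA scores unreachable under half-point granularity signal a bug
  expect_error(classify_risk("HEMA", 1.2), "unreachable")
  expect_error(classify_risk("HEMA", 2.3), "unreachable")
  # monotone with no gaps across attainable scores
  for (m in MODEL_IDS) {
    s <- if (m == "NHFS") 0:10 else if (m == "HEMA") seq(0, 12, 0.5)
         else seq(-0.67, 5.94, 0.01)
    g <- as.integer(classify_risk(m, s))
    expect_true(all(diff(g) >= 0))
    expect_setequal(unique(g), 1:3)
  }
})

test_that("missing-data policy scores absences as negative and logs them", {
  rec <- data.frame(age = 60, sex = "female", fracture_type = "intracapsular")
  cov <- suppressMessages(apply_missing_policy(rec))
  expect_identical(score_nhfs(cov), 0L)
  expect_true(nrow(attr(cov, "absences")) > 0)
  rec2 <- data.frame(age = 86, sex = "female", fracture_type = "intracapsular")
  expect_equal(score_hema(suppressMessages(apply_missing_policy(rec2))), 1.0)
  # complete record passes through unchanged
  full <- make_patient()
  cov_full <- apply_missing_policy(full)
  expect_equal(nrow(attr(cov_full, "absences")), 0)
  for (col in names(full)) expect_equal(cov_full[[col]], full[[col]])
  # no defensible baseline for the anchor variables
  expect_error(apply_missing_policy(data.frame(sex = "male",
                                               fracture_type = "intracapsular")),
               "age")
  expect_error(apply_missing_policy(data.frame(age = 70, sex = NA,
                                               fracture_type = "intracapsular")),
               "sex")
  expect_error(apply_missing_policy(data.frame(age = 70, sex = "male")),
               "fracture_type")
})

test_that("scoring a policy-filled absence never exceeds the present-and-positive score", {
  positive <- make_patient(age = 87, sex = "male", haemoglobin = 9,
                           cognitive_impairment = TRUE,
                           institutional_residence = TRUE,
                           n_comorbidities = 3L, malignancy = TRUE, asa = 4L,
                           prefracture_residence = "long_term_care",
                           prefracture_mobility = "unable_to_walk",
                           fracture_type = "pathological",
                           in_hospital_fracture = TRUE, malnutrition = TRUE,
                           myocardial_infarction = TRUE,
                           congestive_heart_failure = TRUE, pneumonia = TRUE,
                           renal_disease = TRUE, serum_urea = 12)
  droppable <- setdiff(names(positive), c("age", "sex", "fracture_type"))
  for (field in droppable) {
    dropped <- positive
    dropped[[field]] <- NA
    cov <- suppressMessages(apply_missing_policy(dropped))
    expect_lte(score_nhfs(cov), score_nhfs(positive))
    expect_lte(score_holt(cov), score_holt(positive))
    expect_lte(score_hema(cov), score_hema(positive))
  }
})

test_that("shipped model-definition files mirror the code-embedded constants", {
  for (m in MODEL_IDS) {
    def <- model_definition(m)
    shipped <- jsonlite::fromJSON(system.file("extdata", "models",
                                              paste0(tolower(m), ".json"),
                                              package = "hipmort"))
    expect_identical(shipped$model_id, def$model_id)
    expect_equal(shipped$intercept, def$intercept)
    expect_equal(shipped$slope, def$slope)
    expect_equal(shipped$rules$variable, def$rules$variable)
    expect_equal(shipped$rules$condition, def$rules$condition)
    expect_equal(shipped$rules$points, def$rules$points)
  }
})

test_that("score_patients returns scores, probabilities and groups per model", {
  cohort <- rbind(make_patient(), make_patient(age = 90, sex = "male"))
  out <- score_patients(cohort, quiet = TRUE)
  expect_setequal(names(out),
                  c(t(outer(c("nhfs", "holt", "hema"),
                            c("_score", "_prob", "_group"), paste0))))
  expect_equal(out$nhfs_prob, predicted_mortality("NHFS", out$nhfs_score))
  expect_equal(out$hema_group, classify_risk("HEMA", out$hema_score))
})
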