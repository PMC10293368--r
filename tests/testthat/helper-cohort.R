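# Shared fixtures, built in code.

# One patient with every scoring field at its baseline; override by name.
make_patient <- function(...) {
  base <- list(
    age = 60, sex = "female", haemoglobin = 12,
    cognitive_impairment = FALSE, institutional_residence = FALSE,
    n_comorbidities = 0L, malignancy = FALSE, asa = 1L,
    prefracture_residence = "own_home", prefracture_mobility = "no_aids",
    fracture_type = "intracapsular", in_hospital_fracture = FALSE,
    malnutrition = FALSE, myocardial_infarction = FALSE,
    congestive_heart_failure = FALSE, pneumonia = FALSE,
    renal_disease = FALSE, serum_urea = 5)
  as.data.frame(utils::modifyList(base, list(...)))
}

# Follow-up table from day offsets relative to a fixed surgery date.
make_followup <- function(death_day = NA, alive_day = NA,
                          surgery = as.Date("2012-06-01")) {
  n <- max(length(death_day), length(alive_day))
  death_day <- rep_len(death_day, n)
  alive_day <- rep_len(alive_day, n)
  data.frame(
    surgery_date = rep(surgery, n),
    death_date = surgery + ifelse(is.na(death_day), NA, death_day),
    last_known_alive_date = surgery + ifelse(is.na(alive_day), NA, alive_day))
}

# Independent AUC oracle: brute-force enumeration of all positive-negative
# pairs, ties counted one half.
auc_brute <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Independent product-limit oracle: loop over distinct event times.
km_brute <- function(time, event) {
  s <- 1
  out <- numeric(0)
  times <- sort(unique(time[event == 1]))
  for (t in times) {
    at_risk <- sum(time >= t)
    deaths <- sum(time == t & event == 1)
    s <- s * (1 - deaths / at_risk)
    out <- c(out, s)
  }
  data.frame(time = times, survival = out)
}

# A follow-up table that reproduces the published mortality block: 344
# patients, 21 deaths by day 30, 65 by 1 year (3 lost between), 218 by 8
# years (26 lost in total), remainder alive past 8 years.
published_mortality_followup <- function() {
  make_followup(
    death_day = c(rep(15, 21), rep(200, 44), rep(1500, 153), rep(NA, 126)),
    alive_day = c(rep(NA, 218), rep(100, 3), rep(1000, 23), rep(2930, 100)))
}
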