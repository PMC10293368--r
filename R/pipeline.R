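## One-command reproduction of the validation study on any cohort file:
## scoring, outcome labelling, discrimination / calibration / usefulness,
## risk-group tables and Kaplan-Meier exports.

.cohort_columns <- list(
  patient_id = "character", age = "numeric", sex = "character",
  haemoglobin = "numeric", cognitive_impairment = "logical",
  institutional_residence = "logical", n_comorbidities = "numeric",
  malignancy = "logical", asa = "numeric",
  prefracture_residence = "character", prefracture_mobility = "character",
  fracture_type = "character", in_hospital_fracture = "logical",
  malnutrition = "logical", myocardial_infarction = "logical",
  congestive_heart_failure = "logical", pneumonia = "logical",
  renal_disease = "logical", serum_urea = "numeric",
  surgery_date = "date", death_date = "date",
  last_known_alive_date = "date")

.parse_date_col <- function(x, col) {
  parsed <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(!is.na(x) & x != "" & is.na(parsed))
  if (length(bad))
    stop(sprintf("unparseable %s (expected ISO-8601 YYYY-MM-DD) in row(s): %s",
                 col, paste(bad, collapse = ", ")))
  parsed
}

.parse_logical_col <- function(x, col) {
  if (is.logical(x)) return(x)
  chr <- trimws(tolower(as.character(x)))
  out <- rep(NA, length(chr))
  out[chr %in% c("true", "t", "1", "yes")] <- TRUE
  out[chr %in% c("false", "f", "0", "no")] <- FALSE
  bad <- which(!is.na(chr) & chr != "" & is.na(out))
  if (length(bad))
    stop(sprintf("unparseable logical value in column '%s', row(s): %s",
                 col, paste(bad, collapse = ", ")))
  out
}

#' Read a cohort CSV
#'
#' Expects the documented cohort dialect: UTF-8, header row, ISO-8601
#' dates, empty cells for missing values. Unknown columns are dropped with
#' a warning; malformed dates, logicals or categorical levels raise errors
#' naming the offending rows.
#'
#' @param path Path to the cohort CSV.
#' @return Cohort data frame with typed columns.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("cohort file not found: %s", path))
  if (file.size(path) == 0) stop("empty input: cohort file has no content")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), colClasses = "character")
  if (nrow(df) == 0L) stop("empty input: cohort file has a header but no rows")
  unknown <- setdiff(names(df), names(.cohort_columns))
  if (length(unknown)) {
    warning(sprintf("ignoring unknown column(s): %s",
                    paste(unknown, collapse = ", ")))
    df <- df[setdiff(names(df), unknown)]
  }
  for (col in names(df)) {
    type <- .cohort_columns[[col]]
    df[[col]] <- switch(type,
      numeric = suppressWarnings(as.numeric(df[[col]])),
      logical = .parse_logical_col(df[[col]], col),
      date = .parse_date_col(df[[col]], col),
      character = df[[col]])
  }
  df
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: ISO dates, empty cells for `NA`.
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (col in names(out))
    if (inherits(out[[col]], "Date")) out[[col]] <- format(out[[col]], "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Run the full validation battery on a cohort
#'
#' For every model and horizon: rank-based AUC with DeLong confidence
#' interval, Hosmer-Lemeshow calibration of the predicted 30-day
#' probabilities against the horizon's observed deaths, and PPV/NPV of the
#' published risk groups. Also computes paired DeLong comparisons for every
#' model pair at every horizon, observed mortality rates with
#' lost-to-follow-up-adjusted denominators, risk-group proportion tables
#' and Kaplan-Meier curves per model's risk groups. Patients with unknown
#' status at a horizon are excluded from that horizon's metrics; a horizon
#' with a single outcome class has its discrimination skipped with a
#' warning.
#'
#' @param cohort Cohort data frame or path to a cohort CSV.
#' @param horizons Named integer vector of horizons in days.
#' @param models Models to validate.
#' @param hl_groups Number of Hosmer-Lemeshow groups.
#' @param hl_dof Degrees-of-freedom convention passed to
#'   [hosmer_lemeshow()] (`NULL` = groups minus 2).
#' @param km_max_days Administrative censoring limit for the survival
#'   curves.
#' @param quiet Suppress progress messages.
#' @return Object of class `hip_validation_report`: list with `metrics`,
#'   `auc_comparisons`, `risk_groups`, `mortality`, `km`, `warnings` and
#'   `meta`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 250, seed = 11))
#' rep <- run_validation(cohort, quiet = TRUE)
#' rep$metrics[rep$metrics$horizon == "30-day", ]
#' @export
run_validation <- function(cohort, horizons = HORIZON_DAYS,
                           models = MODEL_IDS, hl_groups = 10,
                           hl_dof = NULL,
                           km_max_days = max(horizons), quiet = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  models <- match.arg(models, MODEL_IDS, several.ok = TRUE)
  if (is.null(names(horizons)) || any(!nzchar(names(horizons))))
    names(horizons) <- paste0(horizons, "-day")
  if (any(diff(as.numeric(horizons)) <= 0))
    stop("invalid config: horizons must be strictly increasing")
  log_lines <- character()
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  scored <- withCallingHandlers(
    score_patients(cohort, models = models, quiet = TRUE),
    warning = function(w) { note("warning: %s", conditionMessage(w))
                            invokeRestart("muffleWarning") })
  absences <- attr(scored, "absences")
  if (nrow(absences) > 0) {
    tab <- table(absences$field)
    note("missing-data policy: %s",
         paste(sprintf("%s x%d", names(tab), as.integer(tab)), collapse = ", "))
  }
  status <- lapply(horizons, function(h) outcome_at_horizon(cohort, h))
  mortality <- do.call(rbind, lapply(names(horizons), function(hl) {
    r <- observed_mortality_rate(cohort, horizons[[hl]])
    data.frame(horizon = hl, horizon_days = r$horizon_days,
               deaths = r$deaths, denominator = r$denominator,
               unknown = r$unknown, rate = r$rate)
  }))
  metrics <- list()
  comparisons <- list()
  for (hl in names(horizons)) {
    st <- status[[hl]]
    known <- st != "unknown"
    died <- st[known] == "died"
    single_class <- length(unique(died)) < 2L
    if (single_class)
      note("warning: single outcome class at %s; discrimination and calibration skipped", hl)
    for (m in models) {
      key <- tolower(m)
      prob <- scored[[paste0(key, "_prob")]][known]
      group <- scored[[paste0(key, "_group")]][known]
      row <- data.frame(model = m, horizon = hl,
                        n = sum(known), deaths = sum(died),
                        auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        hl_chi_square = NA_real_, hl_dof = NA_integer_,
                        hl_p = NA_real_, ppv = NA_real_, npv = NA_real_,
                        n_high = NA_integer_, n_low = NA_integer_)
      if (!single_class) {
        a <- auc_rank(prob, died)
        row$auc <- a$auc; row$ci_low <- a$ci_low; row$ci_high <- a$ci_high
        hlres <- tryCatch(
          withCallingHandlers(
            hosmer_lemeshow(prob, died, n_groups = hl_groups, dof = hl_dof),
            warning = function(w) { note("warning [%s %s]: %s", m, hl,
                                         conditionMessage(w))
                                    invokeRestart("muffleWarning") }),
          error = function(e) { note("warning [%s %s]: calibration skipped: %s",
                                     m, hl, conditionMessage(e))
                                NULL })
        if (!is.null(hlres)) {
          row$hl_chi_square <- hlres$chi_square
          row$hl_dof <- hlres$dof
          row$hl_p <- hlres$p_value
        }
      }
      pv <- withCallingHandlers(
        predictive_values(group, died),
        warning = function(w) { note("warning [%s %s]: %s", m, hl,
                                     conditionMessage(w))
                                invokeRestart("muffleWarning") })
      row$ppv <- pv$ppv; row$npv <- pv$npv
      row$n_high <- pv$n_high; row$n_low <- pv$n_low
      metrics[[length(metrics) + 1L]] <- row
    }
    if (!single_class && length(models) > 1L) {
      pairs <- utils::combn(models, 2, simplify = FALSE)
      for (pr in pairs) {
        sa <- scored[[paste0(tolower(pr[1]), "_prob")]][known]
        sb <- scored[[paste0(tolower(pr[2]), "_prob")]][known]
        cmp <- compare_auc_paired(sa, sb, died)
        comparisons[[length(comparisons) + 1L]] <-
          data.frame(horizon = hl, model_a = pr[1], model_b = pr[2],
                     auc_a = cmp$auc_a, auc_b = cmp$auc_b,
                     p_value = cmp$p_value)
      }
    }
  }
  risk_groups <- do.call(rbind, lapply(models, function(m) {
    g <- scored[[paste0(tolower(m), "_group")]]
    tab <- table(g)
    data.frame(model = m, group = names(tab), n = as.integer(tab),
               proportion = as.integer(tab) / length(g))
  }))
  km <- lapply(stats::setNames(models, models), function(m)
    withCallingHandlers(
      km_by_risk_group(cohort, m, max_days = km_max_days),
      warning = function(w) { note("warning [%s KM]: %s", m,
                                   conditionMessage(w))
                              invokeRestart("muffleWarning") }))
  structure(list(metrics = do.call(rbind, metrics),
                 auc_comparisons = if (length(comparisons))
                   do.call(rbind, comparisons) else NULL,
                 risk_groups = risk_groups,
                 mortality = mortality,
                 km = km,
                 warnings = log_lines,
                 meta = list(n = nrow(cohort),
                             horizons = as.list(horizons),
                             models = models, hl_groups = hl_groups,
                             km_max_days = km_max_days,
                             schema_version = "1.0",
                             package_version =
                               as.character(utils::packageVersion("hipmort")))),
            class = "hip_validation_report")
}

# Presentation rounding: one decimal, half-up (4.45 -> 4.5).
round_half_up <- function(x, digits = 1) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}

#' @export
print.hip_validation_report <- function(x, ...) {
  cat(sprintf("Hip-fracture mortality model validation (n = %d)\n\n",
              x$meta$n))
  m <- x$metrics
  for (hl in unique(m$horizon)) {
    cat(sprintf("%s mortality (%d/%d deaths, %d lost)\n", hl,
                x$mortality$deaths[x$mortality$horizon == hl],
                x$mortality$denominator[x$mortality$horizon == hl],
                x$mortality$unknown[x$mortality$horizon == hl]))
    sub <- m[m$horizon == hl, ]
    for (i in seq_len(nrow(sub)))
      cat(sprintf("  %-5s AUC %.2f (%.2f-%.2f)  H-L p = %.3f  PPV %s%%  NPV %s%%\n",
                  sub$model[i], sub$auc[i], sub$ci_low[i], sub$ci_high[i],
                  sub$hl_p[i],
                  format(round_half_up(100 * sub$ppv[i])),
                  format(round_half_up(100 * sub$npv[i]))))
  }
  invisible(x)
}

#' Write a validation report to disk
#'
#' Emits `report.json` (the full structured report), `metrics.csv` (the
#' flat model-by-horizon table), `risk_groups.csv`, `mortality.csv`,
#' `km_curves.csv` (tidy survival curves per model and risk group) and
#' `log.txt` (missing-data substitutions and warnings).
#'
#' @param report A `hip_validation_report`.
#' @param dir Output directory (created if absent).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "hip_validation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  add <- function(p) { paths <<- c(paths, p); p }
  km_flat <- do.call(rbind, lapply(names(report$km), function(m)
    cbind(model = m, km_table(report$km[[m]]))))
  json <- list(meta = report$meta,
               mortality = report$mortality,
               metrics = report$metrics,
               auc_comparisons = report$auc_comparisons,
               risk_groups = report$risk_groups,
               warnings = report$warnings)
  jsonlite::write_json(json, add(file.path(dir, "report.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  utils::write.csv(report$metrics, add(file.path(dir, "metrics.csv")),
                   row.names = FALSE)
  utils::write.csv(report$risk_groups, add(file.path(dir, "risk_groups.csv")),
                   row.names = FALSE)
  utils::write.csv(report$mortality, add(file.path(dir, "mortality.csv")),
                   row.names = FALSE)
  utils::write.csv(km_flat, add(file.path(dir, "km_curves.csv")),
                   row.names = FALSE)
  writeLines(report$warnings, add(file.path(dir, "log.txt")))
  invisible(paths)
}
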