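## Outcome labelling at fixed horizons and Kaplan-Meier survival.
##
## Horizons follow the study design: 30 days, 1 year (365 d) and 8 years,
## operationalised as 2922 d (365.25 * 8; the source gives no day count).

#' Default prediction horizons (days)
#' @export
HORIZON_DAYS <- c("30-day" = 30L, "1-year" = 365L, "8-year" = 2922L)

# Days from surgery to death / last known alive; validates date logic.
.followup_days <- function(followup) {
  followup <- as.data.frame(followup)
  for (col in c("surgery_date", "death_date", "last_known_alive_date"))
    if (is.null(followup[[col]]))
      stop(sprintf("invalid input: follow-up table lacks '%s'", col))
  surgery <- as.Date(followup$surgery_date)
  death <- as.Date(followup$death_date)
  alive <- as.Date(followup$last_known_alive_date)
  if (any(is.na(surgery)))
    stop("invalid input: surgery_date is required for every patient")
  if (any(is.na(death) & is.na(alive)))
    stop("invalid input: each patient needs a death date or a last-known-alive date")
  t_death <- as.numeric(death - surgery)
  t_alive <- as.numeric(alive - surgery)
  if (any(!is.na(t_death) & t_death < 0))
    stop("invalid input: death before surgery")
  if (any(!is.na(t_alive) & t_alive < 0))
    stop("invalid input: last-known-alive date before surgery")
  list(t_death = t_death, t_alive = t_alive)
}

#' Vital status at a fixed horizon
#'
#' A patient counts as `died` when death occurred within the horizon
#' (inclusive: death on day 30 is a 30-day death), `survived` when known
#' alive at or beyond the horizon (a recorded death after the horizon also
#' proves survival to it), and `unknown` when follow-up ends before the
#' horizon with no death recorded.
#'
#' @param followup Data frame with `surgery_date`, `death_date`,
#'   `last_known_alive_date` (ISO dates; the latter two may be `NA` but not
#'   both).
#' @param horizon_days Single horizon in days after surgery.
#' @return Factor with levels `died`, `survived`, `unknown`.
#' @examples
#' outcome_at_horizon(data.frame(surgery_date = "2012-03-01",
#'                               death_date = "2012-03-31",
#'                               last_known_alive_date = NA), 30)
#' @export
outcome_at_horizon <- function(followup, horizon_days) {
  stopifnot(length(horizon_days) == 1L, horizon_days > 0)
  ft <- .followup_days(followup)
  died <- !is.na(ft$t_death) & ft$t_death <= horizon_days
  alive_at <- (!is.na(ft$t_alive) & ft$t_alive >= horizon_days) |
              (!is.na(ft$t_death) & ft$t_death > horizon_days)
  status <- ifelse(died, "died", ifelse(alive_at, "survived", "unknown"))
  factor(status, levels = c("died", "survived", "unknown"))
}

#' Observed mortality rate at a horizon
#'
#' Deaths within the horizon divided by the number of patients whose status
#' at that horizon is known; patients lost to follow-up before the horizon
#' are excluded from the denominator.
#'
#' @inheritParams outcome_at_horizon
#' @return List with `deaths`, `denominator`, `rate` and `unknown`.
#' @examples
#' fu <- data.frame(surgery_date = as.Date("2012-01-01"),
#'                  death_date = as.Date(c("2012-01-20", NA)),
#'                  last_known_alive_date = as.Date(c(NA, "2013-06-01")))
#' observed_mortality_rate(fu, 30)
#' @export
observed_mortality_rate <- function(followup, horizon_days) {
  status <- outcome_at_horizon(followup, horizon_days)
  deaths <- sum(status == "died")
  unknown <- sum(status == "unknown")
  denominator <- length(status) - unknown
  if (denominator == 0L)
    stop("undefined rate: no patient has known status at this horizon")
  list(deaths = deaths, denominator = denominator,
       rate = deaths / denominator, unknown = unknown,
       horizon_days = horizon_days)
}

#' Time-at-risk and event indicator for survival analysis
#'
#' Deaths within the observation window are events at their day of death;
#' everyone else contributes censored time at the last-known-alive date or
#' at `max_days`, whichever comes first. Patients lost before a horizon are
#' thereby excluded from that horizon's rate denominator yet still
#' contribute censored time to Kaplan-Meier estimation.
#'
#' @inheritParams outcome_at_horizon
#' @param max_days Administrative end of the observation window (default 8
#'   years).
#' @return Data frame with `time` (days) and `event` (1 = death).
#' @export
followup_time <- function(followup, max_days = HORIZON_DAYS[["8-year"]]) {
  ft <- .followup_days(followup)
  event <- !is.na(ft$t_death) & ft$t_death <= max_days
  time <- ifelse(event, ft$t_death,
                 pmin(ifelse(is.na(ft$t_alive), max_days, ft$t_alive),
                      max_days))
  data.frame(time = time, event = as.integer(event))
}

#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around [survival::survfit()] returning the curve as a tidy
#' step table (including the implicit point S(0) = 1).
#'
#' @param time Non-negative follow-up times in days.
#' @param event Event indicator (1/TRUE = death, 0/FALSE = censored).
#' @return Object of class `hip_km`: a data frame with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`; attributes `n` and `n_events`.
#' @examples
#' km_fit(c(5, 10, 15, 20), c(0, 1, 0, 1))
#' @export
km_fit <- function(time, event) {
  if (length(time) == 0L) stop("invalid input: empty survival input")
  stopifnot(length(time) == length(event))
  if (any(is.na(time)) || any(time < 0))
    stop("invalid input: survival times must be non-negative and non-missing")
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1,
                           conf.type = "none")
  out <- data.frame(time = c(0, fit$time),
                    n_risk = c(length(time), fit$n.risk),
                    n_event = c(0, fit$n.event),
                    n_censor = c(0, fit$n.censor),
                    survival = c(1, fit$surv))
  structure(out, class = c("hip_km", "data.frame"),
            n = length(time), n_events = sum(as.integer(event)))
}

#' Kaplan-Meier curves by risk group
#'
#' Scores the cohort under one model, classifies each patient into the
#' published low/intermediate/high groups, and estimates one survival curve
#' per group. The groups partition the cohort; an empty group is omitted
#' with a warning.
#'
#' @param cohort Cohort data frame holding both covariates and follow-up
#'   dates (see [apply_missing_policy] and [followup_time]).
#' @param model_id One of `"NHFS"`, `"HOLT"`, `"HEMA"`.
#' @param max_days Administrative censoring limit, passed to
#'   [followup_time()].
#' @return Named list of `hip_km` curves (class `hip_km_list`) with
#'   attributes `model_id` and `group_n`.
#' @export
km_by_risk_group <- function(cohort, model_id,
                             max_days = HORIZON_DAYS[["8-year"]]) {
  model_id <- match.arg(model_id, MODEL_IDS)
  cov <- apply_missing_policy(cohort, quiet = TRUE)
  scorer <- list(NHFS = score_nhfs, HOLT = score_holt, HEMA = score_hema)
  group <- classify_risk(model_id, scorer[[model_id]](cov))
  ft <- followup_time(cohort, max_days = max_days)
  curves <- list()
  for (g in RISK_LEVELS) {
    idx <- which(group == g)
    if (length(idx) == 0L) {
      warning(sprintf("risk group '%s' is empty under %s; curve omitted",
                      g, model_id))
      next
    }
    curves[[g]] <- km_fit(ft$time[idx], ft$event[idx])
  }
  structure(curves, class = "hip_km_list", model_id = model_id,
            group_n = table(group))
}

#' Flatten Kaplan-Meier curves to a tidy table
#'
#' @param km A `hip_km` curve or a `hip_km_list` of curves.
#' @return Data frame with columns `group`, `time`, `survival`, `n_risk`,
#'   `n_event`, `n_censor`, ready for delimited-text export or plotting.
#' @export
km_table <- function(km) {
  if (inherits(km, "hip_km"))
    return(cbind(group = "all", as.data.frame(km)))
  stopifnot(inherits(km, "hip_km_list"))
  do.call(rbind, lapply(names(km), function(g)
    cbind(group = g, as.data.frame(km[[g]]))))
}

#' @export
plot.hip_km_list <- function(x, main = attr(x, "model_id"),
                             col = c(low = "#1b9e77", intermediate = "#d95f02",
                                     high = "#7570b3"), ...) {
  plot(NA, xlim = c(0, max(vapply(x, function(k) max(k$time), 0))),
       ylim = c(0, 1), xlab = "Days since surgery",
       ylab = "Survival probability", main = main, ...)
  for (g in names(x))
    graphics::lines(x[[g]]$time, x[[g]]$survival, type = "s", col = col[[g]],
                    lwd = 2)
  graphics::legend("bottomleft", legend = names(x), col = col[names(x)],
                   lwd = 2, bty = "n")
  invisible(x)
}
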