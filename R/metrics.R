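## Discrimination, calibration and clinical-usefulness measures,
## implemented from first principles (rank-based AUC, DeLong variance and
## paired test, Hosmer-Lemeshow chi-square, PPV/NPV).

# DeLong placement values. For each positive, the fraction of negatives
# ranked below it (ties count one half), and symmetrically for negatives.
# Computed from midranks in O(n log n).
.placements <- function(scores, labels) {
  labels <- as.logical(labels)
  if (any(is.na(scores)) || any(is.na(labels)))
    stop("invalid input: scores and labels must not contain NA")
  m <- sum(labels)
  n <- sum(!labels)
  if (m == 0L || n == 0L)
    stop("undefined AUC: both outcome classes must be present")
  r_all <- rank(scores, ties.method = "average")
  v10 <- (r_all[labels] - rank(scores[labels], ties.method = "average")) / n
  v01 <- 1 - (r_all[!labels] - rank(scores[!labels], ties.method = "average")) / m
  list(v10 = v10, v01 = v01, m = m, n = n, auc = mean(v10))
}

#' Rank-based AUC with DeLong confidence interval
#'
#' Computes the area under the ROC curve by the Mann-Whitney formulation
#' (probability that a randomly chosen case outranks a randomly chosen
#' non-case, ties counted one half) and a confidence interval from the
#' DeLong placement-value variance with a normal approximation, clipped to
#' \[0, 1\]. An AUC of 0.5 is chance-level ranking, 1.0 perfect.
#'
#' @param scores Numeric risk scores or predicted probabilities (AUC is
#'   invariant under strictly monotone transforms, so either gives the same
#'   value).
#' @param labels Outcome indicator (logical or 0/1; `TRUE`/1 = died).
#' @param conf_level Confidence level for the interval.
#' @return Object of class `hip_auc`: list with `auc`, `ci_low`, `ci_high`,
#'   `se`, `n_pos`, `n_neg`.
#' @examples
#' auc_rank(c(1, 2, 3, 4), c(0, 1, 0, 1))
#' @export
auc_rank <- function(scores, labels, conf_level = 0.95) {
  p <- .placements(scores, labels)
  v <- if (p$m > 1L) stats::var(p$v10) / p$m else 0
  v <- v + if (p$n > 1L) stats::var(p$v01) / p$n else 0
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(auc = p$auc,
                 ci_low = max(0, p$auc - z * se),
                 ci_high = min(1, p$auc + z * se),
                 se = se, n_pos = p$m, n_neg = p$n,
                 conf_level = conf_level),
            class = "hip_auc")
}

#' @export
print.hip_auc <- function(x, ...) {
  cat(sprintf("AUC %.3f (%d%% CI %.3f-%.3f; %d events, %d non-events)\n",
              x$auc, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two risk scores evaluated on the same patients,
#' accounting for their correlation through the covariance of the DeLong
#' placement values. Returns the two-sided p-value of the normal test on
#' the AUC difference. Identical scores give p = 1.
#'
#' @param scores_a,scores_b Scores of the two models on the same patients.
#' @inheritParams auc_rank
#' @return List with `p_value`, `auc_a`, `auc_b`, `auc_diff`, `z`.
#' @examples
#' set.seed(1)
#' y <- rbinom(100, 1, 0.3)
#' compare_auc_paired(rnorm(100) + y, rnorm(100), y)
#' @export
compare_auc_paired <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b))
  pa <- .placements(scores_a, labels)
  pb <- .placements(scores_b, labels)
  d10 <- pa$v10 - pb$v10
  d01 <- pa$v01 - pb$v01
  v <- if (pa$m > 1L) stats::var(d10) / pa$m else 0
  v <- v + if (pa$n > 1L) stats::var(d01) / pa$n else 0
  diff <- pa$auc - pb$auc
  if (v <= .Machine$double.eps) {
    z <- if (abs(diff) <= .Machine$double.eps) 0 else sign(diff) * Inf
  } else {
    z <- diff / sqrt(v)
  }
  list(p_value = 2 * stats::pnorm(-abs(z)), auc_a = pa$auc, auc_b = pb$auc,
       auc_diff = diff, z = z)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Sorts patients by predicted probability, splits them into `n_groups`
#' near-equal groups at the quantiles of the predictions (ties are never
#' split across groups), and sums `(observed - expected)^2 / (n p (1 - p))`
#' over the groups, where `p` is the mean predicted risk in the group — the
#' classical chi-square over both the death and survival cells. A
#' significant result indicates lack of fit.
#'
#' When the predictions take fewer distinct values than requested groups
#' (integer scores under a logistic link, for instance), groups are merged
#' and the degrees of freedom adjusted, with a warning.
#'
#' @param probs Predicted probabilities in (0, 1).
#' @param labels Outcome indicator (logical or 0/1).
#' @param n_groups Number of groups (default 10, i.e. deciles of risk).
#' @param dof Degrees of freedom for the reference chi-square
#'   distribution. Default `NULL` uses `g - 2` (with `g` the number of
#'   groups actually formed), the convention of the original test.
#'   When externally fixed predictions are evaluated (no coefficient was
#'   refitted on the validation data) the statistic is asymptotically
#'   chi-square with `g` degrees of freedom, so `dof = g` is the better
#'   calibrated reference; it is exposed for that reason.
#' @return Object of class `hip_hl`: list with `chi_square`, `dof`,
#'   `p_value`, `n_groups_used` and `table` (per group: `n`, `observed`,
#'   `expected`, `mean_prob`).
#' @examples
#' set.seed(1)
#' p <- runif(200, 0.05, 0.6)
#' hosmer_lemeshow(p, rbinom(200, 1, p))
#' @export
hosmer_lemeshow <- function(probs, labels, n_groups = 10, dof = NULL) {
  labels <- as.numeric(as.logical(labels))
  if (any(is.na(probs)) || any(probs <= 0) || any(probs >= 1))
    stop("invalid input: predicted probabilities must lie strictly in (0, 1)")
  n <- length(probs)
  stopifnot(length(labels) == n)
  if (n < 2 * n_groups)
    stop("invalid input: need at least 2 observations per group")
  breaks <- unique(stats::quantile(probs, seq(0, 1, length.out = n_groups + 1)))
  if (length(breaks) < 2L) {
    grp <- factor(rep(1L, n))
  } else {
    grp <- cut(probs, breaks, include.lowest = TRUE)
  }
  grp <- droplevels(grp)
  g <- nlevels(grp)
  if (g < n_groups)
    warning(sprintf(
      "tied predictions: %d groups formed instead of %d; dof adjusted",
      g, n_groups))
  nk <- as.vector(tapply(labels, grp, length))
  ok <- as.vector(tapply(labels, grp, sum))
  ek <- as.vector(tapply(probs, grp, sum))
  pk <- ek / nk
  chi_square <- sum((ok - ek)^2 / (nk * pk * (1 - pk)))
  if (is.null(dof)) dof <- max(1L, g - 2L)
  list_out <- list(chi_square = chi_square, dof = dof,
                   p_value = stats::pchisq(chi_square, dof, lower.tail = FALSE),
                   n_groups_used = g,
                   table = data.frame(group = levels(grp), n = nk,
                                      observed = ok, expected = ek,
                                      mean_prob = pk))
  structure(list_out, class = "hip_hl")
}

#' @export
print.hip_hl <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow chi-square = %.3f on %d df, p = %.3f (%d groups)\n",
              x$chi_square, x$dof, x$p_value, x$n_groups_used))
  invisible(x)
}

#' Positive and negative predictive values of the risk groups
#'
#' PPV is the probability of death for a patient in the high-risk group;
#' NPV the probability of survival for a patient in the low-risk group.
#' Patients with unknown outcome at the horizon are excluded.
#'
#' @param risk_group Factor with levels `low`, `intermediate`, `high`.
#' @param died Outcome at the horizon: logical, with `NA` for unknown.
#' @return List with `ppv`, `npv`, `n_high`, `n_low` (known-outcome group
#'   sizes), `deaths_high`, `survivors_low`. An empty (or fully unknown)
#'   high or low group yields `NA` for the affected value, with a warning.
#' @examples
#' predictive_values(factor(c("high", "high", "low"),
#'                          levels = c("low", "intermediate", "high")),
#'                   c(TRUE, FALSE, FALSE))
#' @export
predictive_values <- function(risk_group, died) {
  stopifnot(length(risk_group) == length(died))
  risk_group <- factor(risk_group, levels = RISK_LEVELS)
  known <- !is.na(died)
  high <- known & risk_group == "high"
  low <- known & risk_group == "low"
  n_high <- sum(high)
  n_low <- sum(low)
  if (n_high == 0L) warning("no high-risk patient with known outcome; PPV undefined")
  if (n_low == 0L) warning("no low-risk patient with known outcome; NPV undefined")
  list(ppv = if (n_high > 0L) sum(died[high]) / n_high else NA_real_,
       npv = if (n_low > 0L) sum(!died[low]) / n_low else NA_real_,
       n_high = n_high, n_low = n_low,
       deaths_high = sum(died[high]),
       survivors_low = sum(!died[low]))
}
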