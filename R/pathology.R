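# IHC H-score, Tim-3 dichotomization, Kaplan-Meier / log-rank machinery and
# survival-optimal cutpoint scanning.

#' Construct an IHC staining field
#'
#' Percentages of tumor cells per staining category in one field of view.
#'
#' @param high_positive,positive,low_positive,negative percentages in
#'   \[0, 100\] summing to 100 (tolerance 1e-6).
#' @return An object of class `ihc_field`.
#' @export
ihc_field <- function(high_positive, positive, low_positive, negative) {
  p <- c(high_positive = high_positive, positive = positive,
         low_positive = low_positive, negative = negative)
  if (any(p < 0) || any(p > 100)) stop("percentages must lie in [0, 100]")
  if (abs(sum(p) - 100) > 1e-6) {
    stop("IHC percentages must sum to 100 (got ", format(sum(p)), ")")
  }
  structure(as.list(p), class = "ihc_field")
}

#' IHC H-score
#'
#' H-score = 3 x \%High Positive + 2 x \%Positive + 1 x \%Low Positive +
#' 0 x \%Negative, giving a score in \[0, 300\]; 300 means every tumor cell
#' in the field is strongly stained. When several replicate fields are
#' supplied (staining is typically repeated per patient) their scores are
#' averaged.
#'
#' @param f an [ihc_field()] or a list of replicate fields.
#' @return Numeric scalar in \[0, 300\].
#' @export
h_score <- function(f) {
  if (inherits(f, "ihc_field")) f <- list(f)
  stopifnot(all(vapply(f, inherits, TRUE, "ihc_field")))
  scores <- vapply(f, function(x) {
    3 * x$high_positive + 2 * x$positive + 1 * x$low_positive + 0 * x$negative
  }, 0)
  mean(scores)
}

#' Dichotomize Tim-3 expression by H-score
#'
#' Low iff score <= cutoff (boundary inclusive on low); the default cutoff of
#' 92.3 is the survival-optimal cutpoint of the source cohort.
#'
#' @param score H-score(s) in \[0, 300\].
#' @param cutoff dichotomization threshold.
#' @return Character vector of `"low"` / `"high"`.
#' @export
dichotomize <- function(score, cutoff = 92.3) {
  if (any(score < 0 | score > 300)) stop("H-scores must lie in [0, 300]")
  ifelse(score <= cutoff, "low", "high")
}

#' Two-group log-rank test
#'
#' @param time follow-up times (> 0).
#' @param event event indicators (1 = event, 0 = censored).
#' @param group two-level group labels.
#' @return `list(statistic = , df = 1, p = )`.
#' @export
logrank <- function(time, event, group) {
  if (any(time <= 0)) stop("times must be positive")
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) stop("exactly 2 groups required")
  if (sum(event) < 1) stop("log-rank test requires at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- sd$chisq
  list(statistic = stat, df = 1L, p = pchisq(stat, 1L, lower.tail = FALSE))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate as a right-continuous step function. With no
#' censoring it coincides with the empirical survival function.
#'
#' @inheritParams logrank
#' @return `data.frame(time = , n_risk = , n_event = , survival = )`,
#'   starting at time 0 with survival 1.
#' @export
km_curve <- function(time, event) {
  if (length(time) < 1L) stop("need at least one record")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = c(0, fit$time),
             n_risk = c(length(time), fit$n.risk),
             n_event = c(0, fit$n.event),
             survival = c(1, fit$surv))
}

#' Survival-optimal biomarker cutoff
#'
#' Re-implements the X-tile-style criterion: scans candidate cutoffs at the
#' midpoints between adjacent observed scores, keeps those where both groups
#' contain at least `min_group_frac` of the cohort, and returns the cutoff
#' maximizing the two-group log-rank chi-square. The reported p-value is
#' unadjusted for the scan's multiple looks and is flagged accordingly.
#'
#' @param scores biomarker values (e.g. H-scores), one per patient.
#' @param time,event survival data aligned with `scores`.
#' @param min_group_frac minimum fraction of patients per group.
#' @return `list(cutoff = , statistic = , p_unadjusted = , n_candidates = ,
#'   scan = )` where `scan` tabulates every admissible cutoff.
#' @export
optimal_cutoff <- function(scores, time, event, min_group_frac = 0.1) {
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n)
  if (n < 10L) stop("need at least 10 patients")
  s <- sort(unique(scores))
  if (length(s) < 2L) stop("no admissible cutoff: scores are constant")
  cand <- (head(s, -1) + s[-1]) / 2
  min_n <- ceiling(min_group_frac * n)
  chis <- vapply(cand, function(ct) {
    g <- scores > ct
    if (sum(g) < min_n || sum(!g) < min_n) return(NA_real_)
    if (sum(event) < 1) return(NA_real_)
    survival::survdiff(survival::Surv(time, event) ~ g)$chisq
  }, 0)
  ok <- which(!is.na(chis))
  if (!length(ok)) stop("no admissible cutoff under min_group_frac")
  best <- ok[which.max(chis[ok])]
  stat <- chis[best]
  list(cutoff = cand[best], statistic = stat,
       p_unadjusted = pchisq(stat, 1L, lower.tail = FALSE),
       n_candidates = length(ok),
       scan = data.frame(cutoff = cand[ok], statistic = chis[ok]))
}

#' Crude follow-up rate
#'
#' Crude event proportion (or its survival complement) as a percentage,
#' rounded to one decimal — the in-paper arithmetic for end-of-follow-up
#' rates (e.g. 61 recurrences of 102 -> 59.8\%).
#'
#' @param n_total cohort size (> 0).
#' @param n_events number of events, `0 <= n_events <= n_total`.
#' @param type `"event"` for the event rate, `"survival"` for its complement.
#' @return Percentage rounded to one decimal.
#' @export
followup_rates <- function(n_total, n_events, type = c("event", "survival")) {
  type <- match.arg(type)
  if (n_total <= 0) stop("n_total must be positive")
  if (n_events < 0 || n_events > n_total) stop("n_events out of range")
  p <- 100 * n_events / n_total
  if (type == "survival") p <- 100 - p
  round(p, 1)
}
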