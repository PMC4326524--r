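#' Time-to-deterioration event definitions
#'
#' The four study definitions cross the reference score (baseline vs best
#' previous observed score) with whether the deterioration must be definitive
#' (time until definitive deterioration, TUDD) or not (TTD), at a fixed
#' minimal clinically important difference of 5 points on the 0-100 scale.
#'
#' @param reference `"baseline"` or `"best_previous"`.
#' @param definitive logical; `TRUE` for TUDD.
#' @param mcid minimal clinically important difference in score points.
#' @param direction `"symptomatic"` (deterioration = score increase) or
#'   `"functional"` (deterioration = score decrease).
#' @return A `qol_ttd_definition` list.
#' @export
ttd_definition <- function(reference = c("baseline", "best_previous"),
                           definitive = FALSE, mcid = 5,
                           direction = c("symptomatic", "functional")) {
  structure(list(reference = match.arg(reference),
                 definitive = isTRUE(definitive),
                 mcid = mcid,
                 direction = match.arg(direction)),
            class = "qol_ttd_definition")
}

#' The four study TTD/TUDD definitions
#' @param mcid,direction passed to [ttd_definition()].
#' @return Named list of the four `qol_ttd_definition`s: `TTD_baseline`,
#'   `TUDD_baseline`, `TTD_best`, `TUDD_best`.
#' @export
ttd_study_definitions <- function(mcid = 5, direction = "symptomatic") {
  list(TTD_baseline = ttd_definition("baseline", FALSE, mcid, direction),
       TUDD_baseline = ttd_definition("baseline", TRUE, mcid, direction),
       TTD_best = ttd_definition("best_previous", FALSE, mcid, direction),
       TUDD_best = ttd_definition("best_previous", TRUE, mcid, direction))
}

#' Derive a deterioration event from one score trajectory
#'
#' Walks the observed scores of one patient (occasions `1..T`, `NA` for
#' missing; the baseline score must be observed) and applies one TTD/TUDD
#' definition. The reference is the baseline score, or the best score
#' observed before the current occasion (minimum for a symptomatic scale,
#' maximum for a functional one). Deterioration at an observed occasion t
#' means the score is worse than the reference by at least the MCID;
#' intermittent missing occasions are skipped (the HRQoL level is taken as
#' unchanged since the last available assessment). Under a definitive
#' definition the deterioration must not be followed by any later observed
#' score improved by at least the MCID relative to the reference in force at
#' the deterioration (drop-out right after deterioration also qualifies).
#' Patients with no (definitive) deterioration are censored at the last
#' occasion with an observed score.
#'
#' @param trajectory numeric vector of length T of scores with `NA`s.
#' @param definition a [ttd_definition()].
#' @return List `(time, event)`: event time in occasion units and 0/1
#'   indicator.
#' @examples
#' derive_event(c(20, 30, 25, 40), ttd_definition("baseline"))
#' @export
derive_event <- function(trajectory, definition) {
  stopifnot(inherits(definition, "qol_ttd_definition"))
  y <- as.numeric(trajectory)
  if (is.na(y[1L]))
    stop("baseline score must be observed")
  # orient so that deterioration is always an increase
  if (definition$direction == "functional") y <- -y
  obs <- which(!is.na(y))
  if (length(obs) == 1L) {
    warning("no observed follow-up scores; censored at baseline")
    return(list(time = 1, event = 0L))
  }
  mcid <- definition$mcid
  last_obs <- max(obs)
  for (t in obs[-1L]) {
    ref <- if (definition$reference == "baseline") {
      y[1L]
    } else {
      min(y[obs[obs < t]])
    }
    if (y[t] - ref >= mcid) {
      if (!definition$definitive)
        return(list(time = t, event = 1L))
      later <- obs[obs > t]
      if (length(later) == 0L || !any(ref - y[later] >= mcid))
        return(list(time = t, event = 1L))
    }
  }
  list(time = last_obs, event = 0L)
}

#' Survival records for a score panel under one definition
#'
#' @param scores a `qol_scores` panel.
#' @param definition a [ttd_definition()].
#' @return Data frame with columns `patient_id`, `arm`, `time`, `event`.
#' @export
derive_survival_records <- function(scores, definition) {
  stopifnot(inherits(scores, "qol_scores"))
  n <- nrow(scores$score)
  time <- numeric(n)
  event <- integer(n)
  for (i in seq_len(n)) {
    te <- suppressWarnings(derive_event(scores$score[i, ], definition))
    time[i] <- te$time
    event[i] <- te$event
  }
  data.frame(patient_id = seq_len(n), arm = scores$arm,
             time = time, event = event)
}

#' Kaplan-Meier estimate of the deterioration-free curve
#'
#' Product-limit estimator over the discrete occasion times, with ties
#' handled as simultaneous events.
#'
#' @param records data frame with columns `time`, `event` (and optionally
#'   `arm`, ignored here).
#' @return Data frame step table: `time`, `n_risk`, `n_event`, `survival`.
#' @export
kaplan_meier <- function(records) {
  stopifnot(nrow(records) >= 1)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  data.frame(time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square comparing the arms, ties handled via the
#' hypergeometric variance.
#'
#' @param records data frame with columns `arm`, `time`, `event`, both arms
#'   represented.
#' @return List `(statistic, p_value)`.
#' @export
logrank_test <- function(records) {
  stopifnot(length(unique(records$arm)) == 2)
  if (sum(records$event) == 0) {
    warning("no events in either arm; log-rank undefined, p = 1")
    return(list(statistic = 0, p_value = 1))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ arm, data = records)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}
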