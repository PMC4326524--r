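#' Missing-data schedule for a scenario
#'
#' The study injects intermittent missing data early in follow-up and monotone
#' drop-out late, never at baseline: for T = 5 occasions, intermittent at
#' occasions 2-3 and monotone at 4-5; for T = 10, intermittent at 2-6 and
#' monotone at 7-10.
#'
#' @param scenario a [qol_scenario()] with `n_times` 5 or 10.
#' @return A `qol_missing_plan`: list with `intermittent_occasions`,
#'   `monotone_occasions`, `proportion`, `mode`, `severity_weight`.
#' @export
default_missing_plan <- function(scenario) {
  stopifnot(inherits(scenario, "qol_scenario"))
  tt <- scenario$n_times
  if (tt == 5L) {
    intermittent <- 2:3; monotone <- 4:5
  } else if (tt == 10L) {
    intermittent <- 2:6; monotone <- 7:10
  } else {
    stop("no default missing-data schedule for T = ", tt)
  }
  structure(list(intermittent_occasions = intermittent,
                 monotone_occasions = monotone,
                 proportion = scenario$missing_proportion,
                 mode = scenario$missing_mode,
                 severity_weight = scenario$mnar_strength),
            class = "qol_missing_plan")
}

#' Inject MNAR intermittent and monotone missing data
#'
#' Implements an informative (MNAR) mechanism: at each scheduled occasion t,
#' `floor(pi * n_at_risk)` of the patients still in the study are selected
#' without replacement with probability proportional to
#' `exp(kappa * severity[n, t])`, where severity is the current latent trait
#' for a symptomatic scale (higher latent burden = worse HRQoL = more likely
#' missing) and its negative for a functional scale. Selection at a monotone
#' occasion removes all responses from t through T (drop-out); at an
#' intermittent occasion it removes the whole form (`mode = "forms"`) or a
#' uniform number of uniformly chosen items (`mode = "items"`) at t only.
#' Dropped-out patients leave the risk set and are never re-selected.
#'
#' @param items complete `qol_items` panel (no missing baseline).
#' @param latent the aligned `qol_latent` panel that generated `items`.
#' @param plan a `qol_missing_plan`; default [default_missing_plan()].
#' @param scenario the [qol_scenario()].
#' @param seed optional integer seed.
#' @return A `qol_items` object with `NA` responses where data were deleted.
#' @export
apply_missingness <- function(items, latent, plan = NULL, scenario,
                              seed = NULL) {
  stopifnot(inherits(items, "qol_items"), inherits(latent, "qol_latent"))
  if (is.null(plan)) plan <- default_missing_plan(scenario)
  stopifnot(inherits(plan, "qol_missing_plan"))
  if (!is.null(seed)) set.seed(seed)
  pi_t <- plan$proportion
  if (pi_t == 0) return(items)

  resp <- items$responses
  n <- dim(resp)[1L]
  tt <- dim(resp)[2L]
  I <- dim(resp)[3L]
  kappa <- plan$severity_weight
  severity <- latent$theta
  if (scenario$scale_direction == "functional") severity <- -severity

  if (pi_t * n / 2 < 1) {
    warning("missing_proportion too small for the cohort; no selections made")
    return(items)
  }

  dropped <- rep(FALSE, n)
  occasions <- sort(unique(c(plan$intermittent_occasions,
                             plan$monotone_occasions)))
  for (t in occasions) {
    at_risk <- which(!dropped)
    n_sel <- floor(pi_t * length(at_risk))
    if (n_sel < 1) next
    w <- exp(kappa * severity[at_risk, t])
    sel <- at_risk[weighted_sample(length(at_risk), n_sel, w)]
    if (t %in% plan$monotone_occasions) {
      resp[sel, t:tt, ] <- NA_integer_
      dropped[sel] <- TRUE
    } else if (plan$mode == "forms") {
      resp[sel, t, ] <- NA_integer_
    } else {
      for (s in sel) {
        m <- sample.int(I, 1L)
        resp[s, t, sample.int(I, m)] <- NA_integer_
      }
    }
  }
  structure(list(responses = resp, arm = items$arm,
                 n_categories = items$n_categories),
            class = "qol_items")
}

# Weighted sampling without replacement of k indices from 1..n with weights w
# (successive draws, probability proportional to remaining weight).
weighted_sample <- function(n, k, w) {
  sample.int(n, k, replace = FALSE, prob = w)
}
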