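#' Define one simulation scenario
#'
#' A scenario bundles the full parameterization of one cell of the simulation
#' grid: trial size, questionnaire structure (items and response categories),
#' measurement schedule, latent-trait dynamics, treatment-arm effect and the
#' missing-data regime. Defaults reproduce the study grid: a latent trait with
#' unit variance and AR(1) correlation, category difficulties at standard
#' normal quantiles, a linear control-arm time trend, and a step arm effect of
#' 0.4 latent units from the second occasion onwards.
#'
#' @param n_patients total number of patients N; split equally between the two
#'   arms, so must be even. Study values: 100, 200, 300.
#' @param n_items number of items I in the dimension (1, 2 or 4 in the study).
#' @param n_categories number of response categories J per item (4 or 7).
#' @param n_times number of measurement occasions T (5 or 10).
#' @param correlation AR(1) correlation rho between consecutive latent
#'   measures, in (-1, 1). Study values: 0.4, 0.7, 0.9.
#' @param latent_variance latent-trait variance sigma^2 (> 0, study value 1).
#' @param time_means control-arm latent means mu0, length `n_times`. Default:
#'   `(-0.4,-0.2,0,0.2,0.4)` for T=5 and `(-0.4,-0.3,...,0.4,0.5)` for T=10;
#'   required explicitly for other T.
#' @param arm_effect treatment-arm latent shift Delta. Either a vector of
#'   length `n_times` with first element 0, or a single number d expanded to
#'   the study's step effect `c(0, d, d, ...)`. Default 0 (null scenario).
#' @param difficulties category difficulty vector delta of length
#'   `n_categories - 1`, shared by all items. Defaults: `(-0.7, 0, 0.7)` for
#'   J=4, `(-1,-0.6,-0.2,0.2,0.6,1)` for J=7, standard normal quantiles
#'   `qnorm(k/J)` otherwise.
#' @param missing_proportion target proportion pi of missing data injected at
#'   each follow-up occasion (0, 0.1, 0.2 or 0.3 in the study).
#' @param missing_mode `"none"`, `"forms"` (intermittent missing forms) or
#'   `"items"` (intermittent missing items); monotone drop-out occasions are
#'   part of the schedule in either non-none mode.
#' @param mnar_strength exponential-tilt coefficient kappa (> 0) controlling
#'   how strongly selection for missingness follows the current latent trait.
#' @param mcid minimal clinically important difference on the 0-100 score
#'   scale, used by the deterioration endpoints (study value 5).
#' @param scale_direction `"symptomatic"` (higher score = worse, the study's
#'   generated direction) or `"functional"` (higher = better).
#' @param alpha nominal two-sided level of the interaction test.
#'
#' @return An object of class `qol_scenario` (a validated list of the above).
#' @examples
#' sc <- qol_scenario(n_patients = 300, n_items = 1, correlation = 0.4,
#'                    arm_effect = 0.4)
#' sc$arm_effect
#' @export
qol_scenario <- function(n_patients = 200,
                         n_items = 2,
                         n_categories = 4,
                         n_times = 5,
                         correlation = 0.7,
                         latent_variance = 1,
                         time_means = NULL,
                         arm_effect = 0,
                         difficulties = NULL,
                         missing_proportion = 0,
                         missing_mode = c("none", "forms", "items"),
                         mnar_strength = 1,
                         mcid = 5,
                         scale_direction = c("symptomatic", "functional"),
                         alpha = 0.05) {
  missing_mode <- match.arg(missing_mode)
  scale_direction <- match.arg(scale_direction)

  stopifnot(length(n_patients) == 1, n_patients >= 2)
  if (n_patients %% 2 != 0)
    stop("n_patients must be even (N/2 patients per arm)")
  stopifnot(n_items >= 1, n_categories >= 2, n_times >= 1)
  if (!is.finite(latent_variance) || latent_variance <= 0)
    stop("latent_variance must be positive")
  if (!is.finite(correlation) || abs(correlation) >= 1)
    stop("correlation must lie in (-1, 1)")
  if (missing_proportion < 0 || missing_proportion >= 1)
    stop("missing_proportion must lie in [0, 1)")
  if (missing_proportion > 0 && missing_mode == "none")
    stop("missing_proportion > 0 requires missing_mode 'forms' or 'items'")
  if (!is.finite(mnar_strength) || mnar_strength < 0)
    stop("mnar_strength must be a nonnegative number")
  stopifnot(alpha > 0, alpha < 1)

  if (is.null(time_means)) {
    time_means <- default_time_means(n_times)
  }
  if (length(time_means) != n_times)
    stop("time_means must have length n_times")

  if (length(arm_effect) == 1L) {
    arm_effect <- c(0, rep(arm_effect, n_times - 1L))
  }
  if (length(arm_effect) != n_times)
    stop("arm_effect must be a scalar or a vector of length n_times")
  if (arm_effect[1L] != 0)
    stop("arm_effect must be 0 at baseline (arms equal at randomization)")

  if (is.null(difficulties)) {
    difficulties <- default_difficulties(n_categories)
  }
  if (length(difficulties) != n_categories - 1L)
    stop("difficulties must have length n_categories - 1")

  structure(
    list(n_patients = as.integer(n_patients),
         n_items = as.integer(n_items),
         n_categories = as.integer(n_categories),
         n_times = as.integer(n_times),
         correlation = correlation,
         latent_variance = latent_variance,
         time_means = as.numeric(time_means),
         arm_effect = as.numeric(arm_effect),
         difficulties = as.numeric(difficulties),
         missing_proportion = missing_proportion,
         missing_mode = missing_mode,
         mnar_strength = mnar_strength,
         mcid = mcid,
         scale_direction = scale_direction,
         alpha = alpha),
    class = "qol_scenario")
}

#' @export
print.qol_scenario <- function(x, ...) {
  cat("HRQoL simulation scenario\n")
  cat(sprintf("  N = %d patients (2 arms), I = %d item(s), J = %d categories, T = %d occasions\n",
              x$n_patients, x$n_items, x$n_categories, x$n_times))
  cat(sprintf("  latent: AR(1) rho = %g, sigma2 = %g, mu0 = (%s)\n",
              x$correlation, x$latent_variance,
              paste(format(x$time_means), collapse = ", ")))
  cat(sprintf("  arm effect Delta = (%s)\n",
              paste(format(x$arm_effect), collapse = ", ")))
  cat(sprintf("  missing: mode = %s, pi = %g per follow-up occasion\n",
              x$missing_mode, x$missing_proportion))
  invisible(x)
}

default_time_means <- function(n_times) {
  if (n_times == 5L) return(seq(-0.4, 0.4, by = 0.2))
  if (n_times == 10L) return(seq(-0.4, 0.5, by = 0.1))
  stop("no default time_means for T = ", n_times,
       "; supply time_means explicitly")
}

default_difficulties <- function(n_categories) {
  if (n_categories == 4L) return(c(-0.7, 0, 0.7))
  if (n_categories == 7L) return(c(-1, -0.6, -0.2, 0.2, 0.6, 1))
  stats::qnorm(seq_len(n_categories - 1L) / n_categories)
}

#' Serialize / restore a scenario as YAML
#'
#' @param scenario a [qol_scenario()] object.
#' @param path file to write to / read from.
#' @return `read_scenario` returns a `qol_scenario`; `write_scenario` returns
#'   `path` invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "qol_scenario"))
  yaml::write_yaml(unclass(scenario), path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(qol_scenario, x[setdiff(names(x), character())])
}
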