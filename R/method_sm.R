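#' Linear mixed model on HRQoL scores (score-and-mixed-model, SM)
#'
#' Fits, by maximum likelihood, the classical-test-theory analysis model
#' `Y[n,t] = b0 + b1 * time + g * arm * time + u_n + v_n * time + e[n,t]`
#' with time coded `0..T-1`, correlated patient-level random intercept and
#' slope `(u_n, v_n)` with unstructured 2 x 2 covariance, and iid residuals.
#' The treatment-arm by time interaction `g` is tested by a two-sided Wald
#' z-test. Missing scores are simply omitted (observed-data likelihood).
#'
#' @param scores a `qol_scores` panel, or a long data frame with columns
#'   `patient_id`, `arm`, `occasion`, `score`.
#' @param alpha nominal level used only to annotate the result.
#' @return A `qol_fit` list: `method`, `interaction_estimate`,
#'   `interaction_se`, `statistic` (Wald z), `p_value`, `converged`,
#'   `log_likelihood`, `n_used`.
#' @export
fit_score_mixed_model <- function(scores, alpha = 0.05) {
  df <- as_score_long(scores)
  df <- df[!is.na(df$score), , drop = FALSE]
  df$time <- df$occasion - 1

  fit <- NULL
  converged <- FALSE
  for (attempt in 1:2) {
    ctrl <- lme4::lmerControl(
      calc.derivs = FALSE,
      check.conv.singular = "ignore",
      check.conv.grad = "ignore",
      check.conv.hess = "ignore",
      optimizer = if (attempt == 1) "bobyqa" else "Nelder_Mead")
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(score ~ time + arm:time + (time | patient_id),
                   data = df, REML = FALSE, control = ctrl))),
      error = function(e) NULL)
    if (!is.null(fit) && isTRUE(fit@optinfo$conv$opt == 0)) {
      converged <- TRUE
      break
    }
  }
  if (is.null(fit)) {
    return(qol_fit("SM", NA, NA, NA, NA_real_, FALSE, NA, nrow(df)))
  }
  beta <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  idx <- grep("arm", names(beta))[1L]
  est <- unname(beta[idx])
  se <- sqrt(vc[idx, idx])
  z <- est / se
  qol_fit("SM", est, se, z, 2 * stats::pnorm(-abs(z)), converged,
          as.numeric(stats::logLik(fit)), nrow(df))
}

qol_fit <- function(method, est, se, stat, p, converged, loglik, n_used,
                    extra = NULL) {
  out <- list(method = method,
              interaction_estimate = est,
              interaction_se = se,
              statistic = stat,
              p_value = if (isTRUE(converged)) p else NA_real_,
              converged = converged,
              log_likelihood = loglik,
              n_used = n_used)
  if (!is.null(extra)) out <- c(out, extra)
  structure(out, class = "qol_fit")
}

#' @export
print.qol_fit <- function(x, ...) {
  cat(sprintf("%s fit: interaction = %.4f (SE %.4f), %s = %.3f, p = %.4g%s\n",
              x$method, x$interaction_estimate, x$interaction_se,
              if (x$method %in% c("SM", "LPCM")) "Wald z" else "statistic",
              x$statistic, x$p_value,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

# Accepts a qol_scores panel or an already-long data frame.
as_score_long <- function(scores) {
  if (inherits(scores, "qol_scores")) {
    n <- nrow(scores$score)
    tt <- ncol(scores$score)
    data.frame(patient_id = rep(seq_len(n), times = tt),
               arm = rep(scores$arm, times = tt),
               occasion = rep(seq_len(tt), each = n),
               score = as.vector(scores$score))
  } else {
    stopifnot(all(c("patient_id", "arm", "occasion", "score") %in%
                    names(scores)))
    as.data.frame(scores)
  }
}
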