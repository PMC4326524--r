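#' All six method labels
#' @return Character vector of the method identifiers used by the harness.
#' @export
qol_methods <- function() {
  c("SM", "TTD_baseline", "TTD_best", "TUDD_baseline", "TUDD_best", "LPCM")
}

#' Run every analysis method on one simulated replicate
#'
#' Generates one complete panel from the scenario (latent trait, item
#' responses, scores), applies the MNAR missing-data mechanism if the
#' scenario requests it (the complete panel is identical whether or not
#' missingness follows, thanks to per-stage sub-seeds), and runs the
#' requested analysis methods on the same data: the score mixed model, the
#' four TTD/TUDD log-rank comparisons, and the LPCM.
#'
#' @param scenario a [qol_scenario()].
#' @param seed replicate seed (integer).
#' @param methods subset of [qol_methods()] to run.
#' @param quadrature_nodes passed to [fit_lpcm()].
#' @return List with `p_values` (named numeric), `converged` (named logical),
#'   `estimates` (named numeric: interaction estimates where defined), and
#'   `seed`.
#' @export
run_replicate <- function(scenario, seed, methods = qol_methods(),
                          quadrature_nodes = 7) {
  stopifnot(inherits(scenario, "qol_scenario"))
  methods <- match.arg(methods, qol_methods(), several.ok = TRUE)
  data <- simulate_complete_data(scenario, seed)
  items <- data$items
  if (scenario$missing_proportion > 0 && scenario$missing_mode != "none") {
    items <- apply_missingness(items, data$latent, scenario = scenario,
                               seed = stage_seed(seed, 3L))
  }
  scores <- compute_scores(items, scenario)

  p <- stats::setNames(rep(NA_real_, length(methods)), methods)
  conv <- stats::setNames(rep(FALSE, length(methods)), methods)
  est <- stats::setNames(rep(NA_real_, length(methods)), methods)

  run_safe <- function(expr) {
    tryCatch(suppressWarnings(expr), error = function(e) NULL)
  }
  for (m in methods) {
    res <- if (m == "SM") {
      run_safe(fit_score_mixed_model(scores, scenario$alpha))
    } else if (m == "LPCM") {
      run_safe(fit_lpcm(items, scenario$alpha,
                        quadrature_nodes = quadrature_nodes))
    } else {
      defn <- ttd_study_definitions(scenario$mcid,
                                    scenario$scale_direction)[[m]]
      run_safe({
        rec <- derive_survival_records(scores, defn)
        lr <- logrank_test(rec)
        list(p_value = lr$p_value, converged = TRUE,
             interaction_estimate = NA_real_)
      })
    }
    if (!is.null(res)) {
      p[m] <- res$p_value
      conv[m] <- isTRUE(res$converged)
      est[m] <- res$interaction_estimate
    }
  }
  list(p_values = p, converged = conv, estimates = est, seed = seed)
}

#' Monte-Carlo rejection rates over a scenario
#'
#' Runs `n_replicates` independent replicates (per-replicate seeds are drawn
#' up-front from the master seed, so results do not depend on execution
#' order) and summarizes each method's rejection rate of the arm-by-time
#' interaction test at the scenario's alpha. Non-converged replicates are
#' excluded from the rejection denominator and counted separately.
#'
#' @param scenario a [qol_scenario()].
#' @param n_replicates number of Monte-Carlo replicates.
#' @param master_seed integer master seed.
#' @param methods subset of [qol_methods()].
#' @param quadrature_nodes passed to [fit_lpcm()].
#' @param keep_p_values if `TRUE`, attach the full replicate-by-method
#'   p-value matrix as attribute `"p_values"`.
#' @return A data frame of summary cells: `method`, `n_replicates`,
#'   `rejection_rate`, `mc_se` (binomial), `n_nonconverged`, plus the
#'   scenario descriptors `n_patients`, `n_items`, `n_categories`,
#'   `correlation`, `n_times`, `missing_proportion`, `missing_mode`.
#' @export
run_scenario <- function(scenario, n_replicates, master_seed,
                         methods = qol_methods(), quadrature_nodes = 7,
                         keep_p_values = FALSE) {
  stopifnot(n_replicates >= 1)
  set.seed(master_seed)
  seeds <- sample.int(2147480000L, n_replicates)
  pmat <- matrix(NA_real_, n_replicates, length(methods),
                 dimnames = list(NULL, methods))
  cmat <- matrix(FALSE, n_replicates, length(methods),
                 dimnames = list(NULL, methods))
  for (r in seq_len(n_replicates)) {
    rep_out <- run_replicate(scenario, seeds[r], methods = methods,
                             quadrature_nodes = quadrature_nodes)
    pmat[r, ] <- rep_out$p_values[methods]
    cmat[r, ] <- rep_out$converged[methods]
  }
  cells <- do.call(rbind, lapply(methods, function(m) {
    ok <- cmat[, m] & !is.na(pmat[, m])
    n_ok <- sum(ok)
    rate <- if (n_ok > 0) mean(pmat[ok, m] < scenario$alpha) else NA_real_
    data.frame(method = m,
               n_replicates = n_ok,
               rejection_rate = rate,
               mc_se = if (n_ok > 0) sqrt(rate * (1 - rate) / n_ok)
                       else NA_real_,
               n_nonconverged = n_replicates - n_ok)
  }))
  flagged <- cells$n_nonconverged > 0.2 * n_replicates
  if (any(flagged))
    warning("methods with >20% non-convergence: ",
            paste(cells$method[flagged], collapse = ", "))
  cells$n_patients <- scenario$n_patients
  cells$n_items <- scenario$n_items
  cells$n_categories <- scenario$n_categories
  cells$correlation <- scenario$correlation
  cells$n_times <- scenario$n_times
  cells$missing_proportion <- scenario$missing_proportion
  cells$missing_mode <- scenario$missing_mode
  rownames(cells) <- NULL
  if (keep_p_values) {
    attr(cells, "p_values") <- pmat
    attr(cells, "converged") <- cmat
  }
  cells
}

#' Write summary cells as result files
#'
#' Emits one wide CSV laid out like the published rejection-rate tables
#' (scenario descriptors as rows, one column per method) and one JSON file
#' with the full cells including Monte-Carlo standard errors and
#' convergence counts.
#'
#' @param cells a data frame of cells from [run_scenario()] (rows from
#'   several scenarios may be concatenated).
#' @param path_csv,path_json output paths; either may be `NULL` to skip.
#' @return The wide table invisibly.
#' @export
emit_tables <- function(cells, path_csv = NULL, path_json = NULL) {
  keys <- c("n_patients", "n_items", "n_categories", "correlation",
            "n_times", "missing_proportion", "missing_mode")
  if (nrow(cells) == 0) {
    wide <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(keys) + length(qol_methods()))),
      c(keys, qol_methods()))
  } else {
    id <- interaction(cells[keys], drop = TRUE, lex.order = TRUE)
    rows <- lapply(split(cells, id), function(g) {
      out <- g[1, keys, drop = FALSE]
      for (m in g$method) out[[m]] <- g$rejection_rate[g$method == m]
      out
    })
    wide <- do.call(rbind, lapply(rows, function(r) {
      for (m in setdiff(qol_methods(), names(r))) r[[m]] <- NA_real_
      r[c(keys, qol_methods())]
    }))
    rownames(wide) <- NULL
  }
  if (!is.null(path_csv))
    utils::write.csv(wide, path_csv, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(cells, path_json, dataframe = "rows", digits = NA)
  invisible(wide)
}
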