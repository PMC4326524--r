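# Shared fixtures and independent oracles used across the test files.

# small standard scenario used by several tests
tiny_scenario <- function(...) {
  qol_scenario(n_patients = 20, n_items = 2, n_categories = 4, n_times = 5,
               correlation = 0.5, ...)
}

# Independent direct evaluation of the adjacent-category partial credit
# model: numerator of category k is exp(sum_{l=1}^{k-1} (theta - delta_l)).
pcm_brute <- function(theta, delta) {
  J <- length(delta) + 1
  num <- sapply(seq_len(J), function(k) {
    if (k == 1) return(1)
    exp(sum(theta - delta[seq_len(k - 1)]))
  })
  num / sum(num)
}

# Independent maximum-likelihood fit of the score mixed model by direct
# optimization of the marginal multivariate-normal likelihood, with the
# fixed effects profiled out by generalized least squares. Returns the
# interaction estimate, its GLS standard error, and the maximized loglik.
lmm_direct_ml <- function(df) {
  df <- df[!is.na(df$score), ]
  ids <- unique(df$patient_id)
  X <- cbind(1, df$time, df$arm * df$time)
  split_rows <- split(seq_len(nrow(df)), df$patient_id)

  nll_profiled <- function(par) {
    sdu <- exp(par[1]); sdv <- exp(par[2]); rho <- tanh(par[3])
    sde <- exp(par[4])
    D <- matrix(c(sdu^2, rho * sdu * sdv, rho * sdu * sdv, sdv^2), 2, 2)
    XtVX <- matrix(0, 3, 3); XtVy <- numeric(3)
    ll_const <- 0
    Vinv_list <- vector("list", length(split_rows))
    for (g in seq_along(split_rows)) {
      rows <- split_rows[[g]]
      Z <- cbind(1, df$time[rows])
      V <- Z %*% D %*% t(Z) + diag(sde^2, length(rows))
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      Vi <- chol2inv(ch)
      Vinv_list[[g]] <- Vi
      ll_const <- ll_const + 2 * sum(log(diag(ch)))
      XtVX <- XtVX + t(X[rows, , drop = FALSE]) %*% Vi %*% X[rows, , drop = FALSE]
      XtVy <- XtVy + t(X[rows, , drop = FALSE]) %*% Vi %*% df$score[rows]
    }
    beta <- solve(XtVX, XtVy)
    quad <- 0
    for (g in seq_along(split_rows)) {
      rows <- split_rows[[g]]
      r <- df$score[rows] - X[rows, , drop = FALSE] %*% beta
      quad <- quad + drop(t(r) %*% Vinv_list[[g]] %*% r)
    }
    0.5 * (ll_const + quad + nrow(df) * log(2 * pi))
  }

  opt <- optim(c(log(10), log(2), 0, log(10)), nll_profiled,
               method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  opt <- optim(opt$par, nll_profiled, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  # recompute beta and its GLS covariance at the optimum
  par <- opt$par
  sdu <- exp(par[1]); sdv <- exp(par[2]); rho <- tanh(par[3])
  sde <- exp(par[4])
  D <- matrix(c(sdu^2, rho * sdu * sdv, rho * sdu * sdv, sdv^2), 2, 2)
  XtVX <- matrix(0, 3, 3); XtVy <- numeric(3)
  for (rows in split_rows) {
    Z <- cbind(1, df$time[rows])
    V <- Z %*% D %*% t(Z) + diag(sde^2, length(rows))
    Vi <- chol2inv(chol(V))
    XtVX <- XtVX + t(X[rows, , drop = FALSE]) %*% Vi %*% X[rows, , drop = FALSE]
    XtVy <- XtVy + t(X[rows, , drop = FALSE]) %*% Vi %*% df$score[rows]
  }
  beta <- solve(XtVX, XtVy)
  vc <- solve(XtVX)
  list(interaction = beta[3], se = sqrt(vc[3, 3]), loglik = -opt$value)
}

# latent panel built directly from the LPCM's own conditional model, for
# parameter-recovery experiments
lpcm_truth_latent <- function(n, n_times, beta, gamma, Sigma) {
  arm <- rep(c(0L, 1L), each = n %/% 2)
  b <- MASS::mvrnorm(n, c(0, 0), Sigma)
  tim <- 0:(n_times - 1)
  theta <- outer(b[, 1], rep(1, n_times)) +
    outer(b[, 2], tim) +
    outer(rep(beta, n), tim) +
    outer(gamma * arm, tim)
  structure(list(theta = theta, arm = arm), class = "qol_latent")
}
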