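#' Gauss-Hermite nodes and log-weights
#'
#' Golub-Welsch eigendecomposition of the Hermite Jacobi matrix; returns the
#' rule for `integral exp(-x^2) f(x) dx = sum w_k f(x_k)`.
#'
#' @param n number of nodes (>= 1).
#' @return List with `nodes` and `logw`.
#' @keywords internal
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, logw = log(sqrt(pi))))
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  A <- matrix(0, n, n)
  A[cbind(i, i + 1)] <- b
  A[cbind(i + 1, i)] <- b
  e <- eigen(A, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       logw = log(pi) / 2 + 2 * log(abs(e$vectors[1, ord])))
}

#' Marginal log-likelihood of the longitudinal partial credit model
#'
#' The LPCM places the analysis model on the latent scale:
#' `theta[n,t] = beta * time + gamma * arm * time + u_n + v_n * time`, with
#' `(u_n, v_n)` bivariate normal with unstructured covariance, and item
#' responses following the partial credit model given `theta[n,t]` with a
#' free difficulty vector per item. The per-patient likelihood integrates
#' the product of PCM probabilities over the observed (non-missing) item
#' responses against the random-effect distribution, using mode/curvature
#' adaptive Gauss-Hermite quadrature in log space.
#'
#' @param items a `qol_items` panel (missing responses allowed, baseline
#'   present).
#' @param params list with `time_slope` (beta), `interaction` (gamma),
#'   `difficulties` (I x (J-1) matrix, or vector recycled to all items) and
#'   `re_covariance` (2 x 2 PSD matrix). A zero `re_covariance` degenerates
#'   to the plain product of PCM probabilities at the fixed-effect latent
#'   trajectory.
#' @param quadrature_nodes nodes per random-effect dimension (>= 3).
#' @return The total marginal log-likelihood (a scalar).
#' @export
lpcm_marginal_loglikelihood <- function(items, params, quadrature_nodes = 7) {
  stopifnot(inherits(items, "qol_items"), quadrature_nodes >= 3)
  d <- dim(items$responses)
  N <- d[1]; T_ <- d[2]; I <- d[3]
  J <- items$n_categories
  delta <- params$difficulties
  if (is.null(dim(delta))) delta <- matrix(delta, nrow = I, ncol = J - 1,
                                           byrow = TRUE)
  stopifnot(nrow(delta) == I, ncol(delta) == J - 1)
  Sig <- params$re_covariance
  stopifnot(is.matrix(Sig), all(dim(Sig) == 2))
  if (max(abs(Sig - t(Sig))) > 1e-10)
    stop("re_covariance must be symmetric")
  ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("re_covariance must be positive semidefinite")

  tim <- seq_len(T_) - 1
  if (all(Sig == 0)) {
    # degenerate random effects: direct product of PCM probabilities
    ll <- 0
    for (i in seq_len(I)) {
      for (t in seq_len(T_)) {
        x <- items$responses[, t, i]
        ok <- !is.na(x)
        if (!any(ok)) next
        th <- params$time_slope * tim[t] +
          params$interaction * items$arm[ok] * tim[t]
        p <- pcm_category_probabilities(th, delta[i, ])
        p <- matrix(p, ncol = J)
        ll <- ll + sum(log(p[cbind(seq_len(sum(ok)), x[ok])]))
      }
    }
    return(ll)
  }
  if (min(ev) < 1e-10)
    stop("singular nonzero re_covariance is not supported; use a zero matrix ",
         "for the degenerate case")
  L <- t(chol(Sig))
  par <- c(params$time_slope, params$interaction, as.vector(t(delta)),
           log(L[1, 1]), L[2, 1], log(L[2, 2]))
  gh <- gauss_hermite(quadrature_nodes)
  modes <- matrix(0, N, 2)
  res <- lpcm_loglik_cpp(as.integer(items$responses), N, T_, I, J,
                         as.integer(items$arm), tim, par,
                         gh$nodes, gh$logw, modes, FALSE)
  res$loglik
}

# objective/gradient pair over the packed parameter vector, with a
# memoized single evaluation shared between the optimizer's objective and
# gradient calls. With share = TRUE a single difficulty block is expanded to
# all items before the kernel call and the per-item gradients are pooled.
lpcm_objective_factory <- function(items, quadrature_nodes, share = FALSE) {
  d <- dim(items$responses)
  N <- d[1]; T_ <- d[2]; I <- d[3]
  J <- items$n_categories
  K <- J - 1
  gh <- gauss_hermite(quadrature_nodes)
  modes <- matrix(0, N, 2)
  resp <- as.integer(items$responses)
  arm <- as.integer(items$arm)
  tim <- seq_len(T_) - 1
  expand <- function(par) {
    if (!share || I == 1) return(par)
    c(par[1:2], rep(par[2 + seq_len(K)], I), par[2 + K + 1:3])
  }
  pool <- function(g) {
    if (!share || I == 1) return(g)
    gd <- matrix(g[2 + seq_len(I * K)], nrow = K)
    c(g[1:2], rowSums(gd), g[2 + I * K + 1:3])
  }
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL
  evaluate <- function(par) {
    if (!identical(par, cache$par)) {
      res <- lpcm_loglik_cpp(resp, N, T_, I, J, arm, tim, expand(par),
                             gh$nodes, gh$logw, modes, TRUE)
      cache$par <- par
      cache$value <- -res$loglik
      cache$gradient <- -pool(res$gradient)
    }
    invisible(NULL)
  }
  list(
    objective = function(par) { evaluate(par); cache$value },
    gradient = function(par) { evaluate(par); cache$gradient },
    npar = 2 + (if (share) 1 else I) * K + 3,
    n_items = I, n_categories = J)
}

# Data-driven starting values: pooled adjacent-category log-odds for the
# difficulties, an OLS slope of the standardized naive score for beta.
lpcm_start <- function(items, share = FALSE) {
  d <- dim(items$responses)
  N <- d[1]; T_ <- d[2]; I <- d[3]
  J <- items$n_categories
  I_eff <- if (share) 1L else I
  delta0 <- matrix(0, I_eff, J - 1)
  for (i in seq_len(I_eff)) {
    x <- if (share) items$responses else items$responses[, , i]
    counts <- tabulate(x, nbins = J) + 0.5
    delta0[i, ] <- pmax(-2, pmin(2, log(counts[-J] / counts[-1])))
  }
  sc <- (apply(items$responses, c(1, 2), mean, na.rm = TRUE) - 1) / (J - 1)
  z <- as.vector(scale(as.vector(sc)))
  tim <- rep(seq_len(T_) - 1, each = N)
  ok <- is.finite(z)
  beta0 <- if (sum(ok) > 2 && stats::var(tim[ok]) > 0)
    stats::coef(stats::lm(z[ok] ~ tim[ok]))[2] else 0
  c(beta0, 0, as.vector(t(delta0)), 0, 0, log(0.3))
}

#' Fit the longitudinal partial credit model
#'
#' Maximizes the adaptive-quadrature marginal likelihood of
#' [lpcm_marginal_loglikelihood()] over the fixed effects (time slope and
#' treatment-arm by time interaction), one free difficulty vector per item,
#' and the random-effect covariance (log-Cholesky parameterization). The
#' interaction is tested by a two-sided Wald z-test with the standard error
#' taken from the inverse of the numerically observed information.
#'
#' @param items a `qol_items` panel; baseline responses must be present.
#' @param alpha nominal level (annotation only).
#' @param quadrature_nodes adaptive Gauss-Hermite nodes per dimension.
#' @param max_restarts extra optimizations from jittered starts if the first
#'   does not converge.
#' @param share_difficulties if `TRUE`, estimate one difficulty vector common
#'   to all items (the generator's truth) instead of one per item.
#' @return A `qol_fit` list as in [fit_score_mixed_model()], with extra
#'   elements `params` (named estimate vector) and `re_covariance`.
#' @export
fit_lpcm <- function(items, alpha = 0.05, quadrature_nodes = 7,
                     max_restarts = 3, share_difficulties = FALSE) {
  stopifnot(inherits(items, "qol_items"))
  obj <- lpcm_objective_factory(items, quadrature_nodes,
                                share = share_difficulties)
  I <- obj$n_items; J <- obj$n_categories
  I_eff <- if (share_difficulties) 1L else I
  npar <- obj$npar
  lower <- c(rep(-10, npar - 3), -6, -10, -6)
  upper <- c(rep(10, npar - 3), 3, 10, 3)
  start <- lpcm_start(items, share = share_difficulties)

  best <- NULL
  for (attempt in 0:max_restarts) {
    st <- start
    if (attempt > 0) {
      # deterministic jitter pattern, scaled up with the attempt index
      jit <- sin(seq_len(npar) * 7.3 + attempt) * 0.3 * attempt
      st <- pmin(pmax(start + jit, lower + 0.01), upper - 0.01)
    }
    opt <- tryCatch(
      stats::optim(st, obj$objective, gr = obj$gradient,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e8)),
      error = function(e) NULL)
    if (is.null(opt)) next
    opt$objective <- opt$value
    ok <- opt$convergence == 0
    if (is.null(best) || opt$objective < best$objective) {
      best <- opt
      best$ok <- ok
    }
    if (ok) break
  }
  n_used <- sum(!is.na(items$responses))
  if (is.null(best))
    return(qol_fit("LPCM", NA, NA, NA, NA_real_, FALSE, NA, n_used))

  par <- best$par
  H <- gradient_hessian(obj$gradient, par, lower, upper)
  vc <- tryCatch(solve(H), error = function(e) NULL)
  converged <- isTRUE(best$ok) && !is.null(vc) && is.finite(vc[2, 2]) &&
    vc[2, 2] > 0
  est <- par[2]
  se <- if (converged) sqrt(vc[2, 2]) else NA_real_
  z <- est / se
  K <- J - 1
  l11 <- exp(par[2 + I_eff * K + 1]); l21 <- par[2 + I_eff * K + 2]
  l22 <- exp(par[2 + I_eff * K + 3])
  L <- matrix(c(l11, l21, 0, l22), 2, 2)
  names(par) <- c("time_slope", "interaction",
                  paste0("delta_i", rep(seq_len(I_eff), each = K),
                         "_k", rep(seq_len(K), I_eff)),
                  "log_chol11", "chol21", "log_chol22")
  qol_fit("LPCM", est, se, z, 2 * stats::pnorm(-abs(z)), converged,
          -best$objective, n_used,
          extra = list(params = par, re_covariance = L %*% t(L)))
}

# central-difference Hessian of the (negative loglik) gradient, symmetrized;
# steps respect box bounds.
gradient_hessian <- function(grad_fn, par, lower, upper, h_rel = 1e-4) {
  p <- length(par)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    h <- h_rel * max(1, abs(par[j]))
    up <- par; up[j] <- min(par[j] + h, upper[j])
    dn <- par; dn[j] <- max(par[j] - h, lower[j])
    H[, j] <- (grad_fn(up) - grad_fn(dn)) / (up[j] - dn[j])
  }
  (H + t(H)) / 2
}
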