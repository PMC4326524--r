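#' AR(1) covariance matrix of the latent trait
#'
#' Entry (s, t) equals `sigma2 * rho^|s-t|`: the correlation between repeated
#' HRQoL measures decays geometrically with the lag between occasions.
#'
#' @param sigma2 latent variance (> 0).
#' @param rho autocorrelation, |rho| < 1.
#' @param n_times number of occasions T.
#' @return A symmetric positive-definite T x T matrix.
#' @examples
#' build_ar1_covariance(1, 0.5, 3)
#' @export
build_ar1_covariance <- function(sigma2, rho, n_times) {
  if (!is.finite(sigma2) || sigma2 <= 0)
    stop("sigma2 must be positive")
  if (!is.finite(rho) || abs(rho) >= 1)
    stop("|rho| must be < 1")
  stopifnot(n_times >= 1)
  lag <- abs(outer(seq_len(n_times), seq_len(n_times), "-"))
  sigma2 * rho^lag
}

#' Simulate the latent HRQoL trait
#'
#' First step of the two-step generator: each patient's latent trajectory is
#' drawn from a T-variate normal with AR(1) covariance. Control-arm patients
#' (arm 0) have mean `mu0 = time_means`; experimental-arm patients (arm 1)
#' have mean `mu0 + arm_effect`. The first N/2 patients are assigned to arm 0.
#'
#' @param scenario a [qol_scenario()].
#' @param seed optional integer seed for reproducibility.
#' @return A `qol_latent` object: list with `theta` (N x T matrix) and `arm`
#'   (0/1 vector of length N).
#' @export
simulate_latent <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "qol_scenario"))
  if (!is.null(seed)) set.seed(seed)
  n <- scenario$n_patients
  n_arm <- n %/% 2L
  sigma <- build_ar1_covariance(scenario$latent_variance,
                                scenario$correlation,
                                scenario$n_times)
  arm <- rep(c(0L, 1L), each = n_arm)
  theta0 <- MASS::mvrnorm(n_arm, mu = scenario$time_means, Sigma = sigma)
  theta1 <- MASS::mvrnorm(n_arm, mu = scenario$time_means + scenario$arm_effect,
                          Sigma = sigma)
  theta <- rbind(matrix(theta0, nrow = n_arm), matrix(theta1, nrow = n_arm))
  structure(list(theta = theta, arm = arm), class = "qol_latent")
}

#' Partial credit model category probabilities
#'
#' Adjacent-category (Masters) partial credit model: for a person at latent
#' level theta answering an item with categories `1..J` and difficulty
#' parameters `delta_1..delta_{J-1}`,
#' `P(X = k) = exp(sum_{l<k} (theta - delta_l)) / normalizer`, the empty sum
#' for the lowest category being 0.
#'
#' @param theta latent trait value(s); any finite numeric vector.
#' @param difficulties numeric vector delta of length J - 1.
#' @return For scalar `theta`, a probability vector of length J; otherwise a
#'   `length(theta)` x J matrix whose rows sum to 1.
#' @examples
#' pcm_category_probabilities(0, c(-0.7, 0, 0.7))
#' @export
pcm_category_probabilities <- function(theta, difficulties) {
  if (length(theta) == 0 || any(!is.finite(theta)))
    stop("theta must be finite")
  if (any(!is.finite(difficulties)))
    stop("difficulties must be finite")
  J <- length(difficulties) + 1L
  # psi_k = (k-1) * theta - cumsum(delta)_{k-1}, psi_1 = 0
  steps <- c(0, cumsum(difficulties))
  psi <- outer(theta, 0:(J - 1L)) - rep(steps, each = length(theta))
  psi <- psi - apply(psi, 1L, max)
  p <- exp(psi)
  p <- p / rowSums(p)
  if (length(theta) == 1L) drop(p) else p
}

#' Simulate polytomous item responses from the latent trait
#'
#' Second step of the generator: given the drawn latent value `theta[n, t]`,
#' the I item responses at that occasion are independent draws from the
#' partial credit model with the scenario's shared difficulty vector (local
#' independence of items and occasions conditional on the latent trait).
#'
#' @param latent a `qol_latent` object from [simulate_latent()].
#' @param scenario the generating [qol_scenario()].
#' @param seed optional integer seed.
#' @return A `qol_items` object: list with `responses` (N x T x I integer
#'   array, values in 1..J, `NA` once missingness has been injected), `arm`,
#'   and `n_categories`.
#' @export
simulate_item_responses <- function(latent, scenario, seed = NULL) {
  stopifnot(inherits(latent, "qol_latent"), inherits(scenario, "qol_scenario"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(latent$theta)
  tt <- ncol(latent$theta)
  I <- scenario$n_items
  J <- scenario$n_categories
  probs <- pcm_category_probabilities(as.vector(latent$theta),
                                      scenario$difficulties)
  probs <- matrix(probs, ncol = J)
  cum <- t(apply(probs, 1L, cumsum))
  responses <- array(NA_integer_, dim = c(n, tt, I))
  for (i in seq_len(I)) {
    u <- stats::runif(n * tt)
    k <- rowSums(u > cum[, -J, drop = FALSE]) + 1L
    responses[, , i] <- as.integer(k)
  }
  structure(list(responses = responses, arm = latent$arm,
                 n_categories = J),
            class = "qol_items")
}

#' EORTC-style scores from item responses
#'
#' Maps each patient-occasion to a 0-100 score following the questionnaire
#' scoring convention for a symptomatic or single-scale dimension:
#' `score = ((mean of answered items) - 1) * 100 / r` with `r = J - 1` the
#' item range. When items are missing, the personal mean score is used
#' provided at least half of the I items were answered; otherwise the score
#' is missing.
#'
#' @param items a `qol_items` object.
#' @param scenario the [qol_scenario()] (supplies I and J).
#' @return A `qol_scores` object: list with `score` (N x T matrix in
#'   \[0, 100\] or `NA`) and `arm`.
#' @examples
#' sc <- qol_scenario(n_patients = 4, n_items = 2, correlation = 0.4)
#' lat <- simulate_latent(sc, seed = 1)
#' itm <- simulate_item_responses(lat, sc, seed = 2)
#' compute_scores(itm, sc)$score
#' @export
compute_scores <- function(items, scenario) {
  stopifnot(inherits(items, "qol_items"))
  resp <- items$responses
  I <- dim(resp)[3L]
  J <- items$n_categories
  answered <- apply(!is.na(resp), c(1L, 2L), sum)
  mean_resp <- apply(resp, c(1L, 2L), function(x) mean(x, na.rm = TRUE))
  score <- (mean_resp - 1) * 100 / (J - 1)
  score[answered < ceiling(I / 2)] <- NA_real_
  structure(list(score = score, arm = items$arm), class = "qol_scores")
}

#' Generate one complete dataset (latent + items + scores)
#'
#' Convenience wrapper running both generator steps with per-stage seeds
#' derived from one replicate seed, so that a missing-data run can reuse the
#' identical complete panel before deletion.
#'
#' @param scenario a [qol_scenario()].
#' @param seed replicate seed (integer).
#' @return List with elements `latent`, `items`, `scores`.
#' @export
simulate_complete_data <- function(scenario, seed) {
  latent <- simulate_latent(scenario, seed = stage_seed(seed, 1L))
  items <- simulate_item_responses(latent, scenario,
                                   seed = stage_seed(seed, 2L))
  scores <- compute_scores(items, scenario)
  list(latent = latent, items = items, scores = scores)
}

# Deterministic per-stage sub-seed (stage 1 latent, 2 items, 3 missingness),
# kept inside 32-bit integer range.
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7L + stage * 1000003) %% 2147483647)
}
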