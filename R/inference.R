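# Exact posterior inference in the two-level model.
#
# All probability arithmetic runs in log space with log-sum-exp
# normalization: content means several standard deviations from the origin
# make naive Gaussian densities underflow long before the posteriors become
# ill-defined.

#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise Gaussian log-densities for every state.
# X: n x M matrix; returns n x (N+1) matrix of log N(x; mu_k, Sigma/lambda).
# The Cholesky factor of Sigma/lambda is chol(Sigma)/sqrt(lambda).
#' @keywords internal
loglik_matrix <- function(model, X, lambda = 1) {
  stopifnot(lambda > 0)
  M <- model$feature_dim
  R <- model$chol_cov / sqrt(lambda)
  Rinv <- backsolve(R, diag(M))
  logdet <- 2 * sum(log(diag(R)))
  K <- ncol(model$means)
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    centered <- sweep(X, 2L, model$means[, k], "-")
    v <- centered %*% Rinv
    out[, k] <- -0.5 * (M * log(2 * pi) + logdet + rowSums(v * v))
  }
  out
}

# Core joint computation shared by all query functions.
# Returns list(p_states = n x (N+1), p_presence, confidence, kl_w, kl_a)
# for an n x M matrix of samples.
#' @keywords internal
posterior_matrix <- function(model, X, lambda = 1,
                             kl_w_mode = c("joint", "per_node_sum")) {
  kl_w_mode <- match.arg(kl_w_mode)
  prior <- model$prior_marginal
  log_prior <- ifelse(prior > 0, log(prior), -Inf)
  ll <- loglik_matrix(model, X, lambda)
  logj <- sweep(ll, 2L, log_prior, "+")
  lz <- apply(logj, 1L, logsumexp)
  logpost <- sweep(logj, 1L, lz, "-")
  p_states <- exp(logpost)
  # presence is the sum of the content-state marginals of the same joint, so
  # level consistency holds by construction
  p_presence <- rowSums(p_states[, -1L, drop = FALSE])
  confidence <- apply(p_states[, -1L, drop = FALSE], 1L, max)

  # KL(posterior || prior); posterior support is contained in prior support
  # because posterior mass is prior mass times a finite likelihood
  stopifnot(all(p_states[, prior == 0] < 1e-300))
  kl_terms <- ifelse(p_states > 0,
                     p_states * (logpost - rep(log_prior, each = nrow(X))),
                     0)
  if (kl_w_mode == "joint") {
    kl_w <- rowSums(kl_terms)
  } else {
    # summed binary-marginal surprise, one term per content node
    kn <- vapply(seq_along(prior), function(k) {
      kl_bernoulli(p_states[, k], prior[k])
    }, numeric(nrow(X)))
    if (is.null(dim(kn))) kn <- matrix(kn, nrow = nrow(X))
    kl_w <- rowSums(kn)
  }
  kl_a <- kl_bernoulli(p_presence, model$prior_presence)
  list(p_states = p_states, p_presence = p_presence,
       confidence = confidence, kl_w = pmax(kl_w, 0), kl_a = pmax(kl_a, 0))
}

# Vectorized Bernoulli KL in nats with the 0 log 0 = 0 convention.
#' @keywords internal
kl_bernoulli <- function(p, q) {
  term <- function(a, b) ifelse(a > 0, a * (log(a) - log(b)), 0)
  term(p, q) + term(1 - p, 1 - q)
}

# Categorical KL in nats, 0 log 0 = 0; asserts support containment.
#' @keywords internal
kl_categorical <- function(p, q) {
  stopifnot(all(q[p > 0] > 0))
  sum(ifelse(p > 0, p * (log(p) - log(q)), 0))
}

#' @keywords internal
as_sample_matrix <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != model$feature_dim)
    stop("sample dimension (", ncol(x), ") does not match feature_dim (",
         model$feature_dim, ")")
  if (anyNA(x) || any(!is.finite(x)))
    stop("sample entries must be finite")
  x
}

#' Class-conditional Gaussian likelihoods of a sensory sample
#'
#' Evaluates the emission density `N(x; mu_k, Sigma / lambda)` for every
#' state `w0..wN`.
#'
#' @param model a [hoss_model()] or [flat_model()].
#' @param x numeric feature vector of length `feature_dim`.
#' @param lambda sensory precision multiplier; the effective covariance is
#'   `Sigma / lambda`. Default 1 (the covariance as specified).
#' @return numeric `(N + 1)`-vector of densities, absent state first.
#' @export
class_likelihoods <- function(model, x, lambda = 1) {
  X <- as_sample_matrix(model, x)
  ll <- loglik_matrix(model, X, lambda)
  stats::setNames(exp(drop(ll)), model$state_labels)
}

#' Posterior probability of stimulus presence
#'
#' Computes `P(A = a1 | X = x)` by marginalizing over the content states:
#' `P(a1|x)` is proportional to `P(a1) * sum_i P(wi|a1) L(x|wi)` against
#' `(1 - P(a1)) * L(x|w0)`.
#'
#' @inheritParams class_likelihoods
#' @param model a [hoss_model()].
#' @return probability in `[0, 1]`.
#' @export
posterior_presence <- function(model, x, lambda = 1) {
  stopifnot(inherits(model, "hoss_model"))
  X <- as_sample_matrix(model, x)
  posterior_matrix(model, X, lambda)$p_presence
}

#' Marginal posterior over content states
#'
#' Computes `P(W = wk | X = x)` for `k = 0..N` under the induced marginal
#' prior, i.e. summing the joint over the awareness state.
#'
#' @inheritParams posterior_presence
#' @return numeric `(N + 1)`-vector of probabilities summing to 1, absent
#'   state first.
#' @export
posterior_states <- function(model, x, lambda = 1) {
  stopifnot(inherits(model, "hoss_model"))
  X <- as_sample_matrix(model, x)
  stats::setNames(drop(posterior_matrix(model, X, lambda)$p_states),
                  model$state_labels)
}

#' Full inference on one sensory sample
#'
#' Bundles the presence posterior, the content-state posterior, confidence
#' in identity (the maximum content-state marginal,
#' `max[P(w1|x), ..., P(wN|x)]`) and the categorical awareness report:
#' `"seen"` iff `P(a1|x)` strictly exceeds `report_threshold`.
#'
#' @inheritParams posterior_presence
#' @param report_threshold report criterion on the presence posterior, in
#'   `(0, 1)`. A posterior exactly at threshold yields `"unseen"`.
#' @return A list of class `"hoss_posterior"` with elements `p_presence`,
#'   `p_states`, `confidence`, `report`.
#' @examples
#' m <- hoss_model(cbind(c(0.5, 0.5), c(1.5, 0.5), c(0.5, 1.5)))
#' infer(m, c(1.5, 0.5))
#' @export
infer <- function(model, x, report_threshold = 0.5, lambda = 1) {
  stopifnot(inherits(model, "hoss_model"))
  if (!is.numeric(report_threshold) || length(report_threshold) != 1L ||
      report_threshold <= 0 || report_threshold >= 1)
    stop("report_threshold must be a single probability in (0, 1)")
  X <- as_sample_matrix(model, x)
  if (nrow(X) != 1L)
    stop("infer() takes a single sample; use predict() for a matrix of samples")
  post <- posterior_matrix(model, X, lambda)
  structure(
    list(
      p_presence = post$p_presence,
      p_states = stats::setNames(drop(post$p_states), model$state_labels),
      confidence = post$confidence,
      report = if (post$p_presence > report_threshold) "seen" else "unseen"
    ),
    class = "hoss_posterior"
  )
}

#' @export
print.hoss_posterior <- function(x, digits = 4, ...) {
  cat("posterior inference\n")
  cat("  P(present | x):", format(x$p_presence, digits = digits),
      " ->", x$report, "\n")
  cat("  confidence in identity:", format(x$confidence, digits = digits), "\n")
  cat("  content-state posterior:\n")
  print(round(x$p_states, digits))
  invisible(x)
}

#' Belief update (Bayesian surprise) at both levels of the hierarchy
#'
#' Measures how far the posterior moved from the prior at each level of the
#' network, in nats: `kl_w` is the Kullback-Leibler divergence from the
#' induced marginal prior over `{w0..wN}` to its posterior, and `kl_a` the
#' divergence from `Bernoulli(P(a1))` to `Bernoulli(P(a1|x))`. Under
#' predictive-coding readings this Bayesian surprise is a proxy for the
#' "activation" (summed prediction error) expected at each level, and the
#' seen/unseen asymmetry of `kl_w` is the model's computational correlate of
#' global ignition.
#'
#' @inheritParams posterior_presence
#' @param kl_w_mode `"joint"` (default) computes the KL of the full
#'   categorical distribution over `{w0..wN}`; `"per_node_sum"` sums the
#'   binary-marginal KL of each content node, the reading in which surprise
#'   accumulates node by node across the network.
#' @return A list of class `"hoss_belief_update"` with non-negative elements
#'   `kl_w` and `kl_a` (nats).
#' @examples
#' m <- hoss_model(cbind(c(0.5, 0.5), c(1.5, 0.5), c(0.5, 1.5)))
#' belief_update(m, c(1, 1))   # equidistant sample: no belief change
#' @export
belief_update <- function(model, x, lambda = 1,
                          kl_w_mode = c("joint", "per_node_sum")) {
  stopifnot(inherits(model, "hoss_model"))
  kl_w_mode <- match.arg(kl_w_mode)
  X <- as_sample_matrix(model, x)
  post <- posterior_matrix(model, X, lambda, kl_w_mode = kl_w_mode)
  structure(list(kl_w = post$kl_w, kl_a = post$kl_a),
            class = "hoss_belief_update")
}

#' @export
print.hoss_belief_update <- function(x, digits = 4, ...) {
  cat("belief update (nats): kl_w =", format(x$kl_w, digits = digits),
      " kl_a =", format(x$kl_a, digits = digits), "\n")
  invisible(x)
}

#' Brute-force inference oracle over the expanded joint state space
#'
#' Recomputes the full inference bundle by enumerating the joint table over
#' every `(A, W)` pair — including zero-prior-mass combinations such as
#' `(a1, w0)` — as `P(A) P(W|A) L(x|W)`, normalizing the table in plain
#' (non-log) arithmetic, and reading both marginals off by summation. The
#' likelihoods use [stats::mahalanobis()] and a direct determinant rather
#' than the Cholesky path of the main implementation. Intended as an
#' independent cross-check of [infer()]; the two must agree to within
#' 1e-10 componentwise on any valid input.
#'
#' @inheritParams infer
#' @return A list of class `"hoss_posterior"`, as [infer()].
#' @export
posterior_oracle <- function(model, x, report_threshold = 0.5, lambda = 1) {
  stopifnot(inherits(model, "hoss_model"))
  x <- as_sample_matrix(model, x)
  if (nrow(x) != 1L) stop("posterior_oracle() takes a single sample")
  x <- drop(x)
  N <- model$n_states
  M <- model$feature_dim
  sigma <- model$covariance / lambda
  dens <- vapply(seq_len(N + 1L), function(k) {
    q <- stats::mahalanobis(matrix(x, 1L), model$means[, k], sigma)
    exp(-0.5 * q) / sqrt((2 * pi)^M * det(sigma))
  }, numeric(1))

  # rows: a0, a1; columns: w0..wN
  p_w_given_a <- rbind(c(1, rep(0, N)),
                       c(0, model$prior_content))
  p_a <- c(1 - model$prior_presence, model$prior_presence)
  joint <- (p_a * p_w_given_a) * rep(dens, each = 2L)
  joint <- joint / sum(joint)

  p_states <- colSums(joint)
  p_presence <- sum(joint[2L, ])
  structure(
    list(
      p_presence = p_presence,
      p_states = stats::setNames(p_states, model$state_labels),
      confidence = max(p_states[-1L]),
      report = if (p_presence > report_threshold) "seen" else "unseen"
    ),
    class = "hoss_posterior"
  )
}
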