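# Flat (single-level) signal-detection comparator: "absent" is an ordinary
# stimulus class in a one-level Bayesian classifier over N+1 classes.

#' Posterior over classes in the flat comparator
#'
#' Single-level Bayes rule over the `N + 1` classes (absent class first)
#' under the flat prior. Evidence handling is identical to the hierarchical
#' model — same Gaussian emissions, same log-space arithmetic — so any
#' behavioural difference between the two models is attributable to prior
#' structure and the presence query alone.
#'
#' @param model a [flat_model()].
#' @param x numeric feature vector of length `feature_dim`.
#' @param lambda sensory precision multiplier; effective covariance is
#'   `Sigma / lambda`.
#' @return numeric `(N + 1)`-vector of class posteriors summing to 1.
#' @export
flat_posterior <- function(model, x, lambda = 1) {
  stopifnot(inherits(model, "flat_model"))
  X <- as_sample_matrix(model, x)
  log_prior <- ifelse(model$prior > 0, log(model$prior), -Inf)
  logj <- sweep(loglik_matrix(model, X, lambda), 2L, log_prior, "+")
  lz <- apply(logj, 1L, logsumexp)
  p <- exp(sweep(logj, 1L, lz, "-"))
  if (nrow(X) == 1L) stats::setNames(drop(p), model$state_labels) else p
}

#' Awareness report of the flat comparator
#'
#' The flat architecture has no dedicated presence state, so a report rule
#' must be imposed on the class posterior. The default mirrors the
#' hierarchical threshold rule applied to `1 - P(absent | x)`: report
#' `"seen"` iff `P(absent | x) < threshold`. The alternative `"argmax"`
#' rule reports `"seen"` iff the maximum a posteriori class is not the
#' absent class.
#'
#' @inheritParams flat_posterior
#' @param threshold report criterion on the absent-class posterior, in
#'   `(0, 1)`.
#' @param rule `"threshold"` (default) or `"argmax"`.
#' @return `"seen"` or `"unseen"`.
#' @export
flat_report <- function(model, x, threshold = 0.5,
                        rule = c("threshold", "argmax")) {
  rule <- match.arg(rule)
  p <- flat_posterior(model, x)
  if (rule == "threshold") {
    if (p[1L] < threshold) "seen" else "unseen"
  } else {
    if (which.max(p) != 1L) "seen" else "unseen"
  }
}

#' Belief update of the flat comparator
#'
#' Kullback-Leibler divergence, in nats, from the flat class prior to the
#' class posterior. This is the single surprise signal the flat
#' architecture supports: with a uniform prior its high-precision limit is
#' `log(N + 1)` for every class, present or absent, so the flat comparator
#' predicts no seen/unseen ignition asymmetry.
#'
#' @inheritParams flat_posterior
#' @return non-negative scalar (nats); vector for a matrix of samples.
#' @export
flat_belief_update <- function(model, x, lambda = 1) {
  stopifnot(inherits(model, "flat_model"))
  X <- as_sample_matrix(model, x)
  p <- flat_posterior(model, X, lambda)
  if (is.null(dim(p))) p <- matrix(p, 1L)
  q <- model$prior
  stopifnot(all(p[, q == 0] < 1e-300))
  lq <- ifelse(q > 0, log(q), -Inf)
  kl <- rowSums(ifelse(p > 0, p * (log(p) - rep(lq, each = nrow(p))), 0))
  pmax(kl, 0)
}
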