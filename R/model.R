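#' Construct a higher-order state-space (HOSS) observer model
#'
#' A HOSS model is a two-level generative model of awareness reports. A binary
#' awareness state `A` (absent `a0` / present `a1`) sits above a discrete
#' perceptual content state `W` taking values in `{w0, w1, ..., wN}`, where
#' `w0` is the no-content (absence) state. The nesting is asymmetric:
#' `P(W = w0 | a0) = 1` and `P(W = w0 | a1) = 0`, so awareness entails the
#' possibility of content while unawareness entails its absence. Given a
#' content state, a sensory feature vector `X` is emitted from a multivariate
#' Gaussian with a state-specific mean and a covariance shared across all
#' states.
#'
#' The induced marginal prior over the `N + 1` content states is
#' `(1 - P(a1), P(a1) * P(w1|a1), ..., P(a1) * P(wN|a1))`.
#'
#' @param means numeric matrix with `M` rows (feature dimensions) and `N + 1`
#'   columns of emission means; column 1 is the absent state `w0`, columns
#'   `2..N+1` the content states. A single numeric vector is taken as a
#'   1-column matrix (`N = 0` is rejected; at least one content state is
#'   required, so `means` needs at least 2 columns).
#' @param covariance `M x M` symmetric positive-definite covariance matrix
#'   shared by all states. Default: identity.
#' @param prior_presence prior probability `P(A = a1)` of stimulus presence,
#'   in `[0, 1]`. Default 0.5 (a flat awareness prior).
#' @param prior_content numeric `N`-vector of conditional content priors
#'   `P(wi | a1)`, non-negative and summing to 1. Default: uniform `1/N`
#'   (a flat content prior given presence).
#' @param state_labels optional character vector of `N + 1` display names for
#'   `w0..wN`. Defaults to `c("absent", "w1", ..., "wN")`. Labels are display
#'   metadata only; no computation depends on them.
#'
#' @return An object of class `"hoss_model"`: a list with elements
#'   `n_states`, `feature_dim`, `means`, `covariance`, `prior_presence`,
#'   `prior_content`, `prior_marginal`, `state_labels` and the upper Cholesky
#'   factor `chol_cov` of the covariance.
#'
#' @examples
#' # near-threshold 2D discrimination space: two content classes at unit
#' # distance from the absent class, identity covariance
#' m <- hoss_model(means = cbind(c(0.5, 0.5), c(1.5, 0.5), c(0.5, 1.5)))
#' m
#' infer(m, c(1.5, 0.5))
#' @seealso [flat_model()] for the single-level comparator, [infer()] for
#'   posterior inference, [belief_update()] for Bayesian surprise.
#' @export
hoss_model <- function(means, covariance = NULL, prior_presence = 0.5,
                       prior_content = NULL, state_labels = NULL) {
  if (is.null(dim(means))) means <- matrix(means, ncol = 1L)
  means <- as.matrix(means)
  storage.mode(means) <- "double"
  M <- nrow(means)
  if (ncol(means) < 2L)
    stop("means: need at least 2 columns (absent state w0 plus >= 1 content state)")
  N <- ncol(means) - 1L
  if (is.null(covariance)) covariance <- diag(M)
  covariance <- as.matrix(covariance)
  storage.mode(covariance) <- "double"
  if (is.null(prior_content)) prior_content <- rep(1 / N, N)
  if (is.null(state_labels))
    state_labels <- c("absent", paste0("w", seq_len(N)))

  obj <- structure(
    list(
      n_states = N,
      feature_dim = M,
      means = means,
      covariance = covariance,
      prior_presence = as.numeric(prior_presence),
      prior_content = as.numeric(prior_content),
      state_labels = as.character(state_labels)
    ),
    class = "hoss_model"
  )
  validate_hoss_model(obj)
  obj$chol_cov <- chol(covariance)
  obj$prior_marginal <- induced_marginal_prior(obj)
  obj
}

#' @keywords internal
induced_marginal_prior <- function(model) {
  c(1 - model$prior_presence, model$prior_presence * model$prior_content)
}

#' Validate a HOSS model specification
#'
#' Checks every structural invariant of the model: dimensions of the mean
#' matrix, symmetry and positive-definiteness of the covariance (a Cholesky
#' factorization must succeed), range of the presence prior, normalization of
#' the conditional content prior, and normalization of the induced marginal
#' prior. Errors name the offending field.
#'
#' @param model an object of class `"hoss_model"` (possibly not yet finalized).
#' @return `model`, invisibly, if valid.
#' @export
validate_hoss_model <- function(model) {
  M <- model$feature_dim
  N <- model$n_states
  if (!is.matrix(model$means) || nrow(model$means) != M ||
      ncol(model$means) != N + 1L || anyNA(model$means) ||
      any(!is.finite(model$means)))
    stop("means: must be a finite ", M, " x ", N + 1L,
         " matrix (feature_dim rows, n_states + 1 columns, absent state first)")
  cv <- model$covariance
  if (!is.matrix(cv) || nrow(cv) != M || ncol(cv) != M)
    stop("covariance: must be a ", M, " x ", M, " matrix")
  if (anyNA(cv) || any(!is.finite(cv)))
    stop("covariance: entries must be finite")
  if (max(abs(cv - t(cv))) > 1e-8 * max(1, max(abs(cv))))
    stop("covariance: must be symmetric")
  ok <- tryCatch({ chol(cv); TRUE }, error = function(e) FALSE)
  if (!ok)
    stop("covariance: must be positive-definite (Cholesky factorization failed)")
  p <- model$prior_presence
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("prior_presence: must be a single probability in [0, 1]")
  pc <- model$prior_content
  if (length(pc) != N || anyNA(pc) || any(pc < 0))
    stop("prior_content: must be ", N, " non-negative probabilities")
  if (abs(sum(pc) - 1) > 1e-12)
    stop("prior_content: must sum to 1 (got ", format(sum(pc), digits = 15), ")")
  if (length(model$state_labels) != N + 1L)
    stop("state_labels: must have ", N + 1L, " entries (absent state first)")
  marg <- induced_marginal_prior(model)
  stopifnot(abs(sum(marg) - 1) <= 1e-12, all(marg >= 0))
  invisible(model)
}

#' Construct a flat (single-level) signal-detection comparator model
#'
#' The flat comparator uses the same Gaussian emission model as
#' [hoss_model()] but organizes the `N + 1` classes — including "absent" —
#' in a flat, non-hierarchical structure with a single prior over all
#' classes. It is the classical-SDT-style contrast for the hierarchical
#' model: the two architectures handle evidence identically and differ only
#' in prior structure and in the existence of a higher-level presence query.
#'
#' @inheritParams hoss_model
#' @param prior numeric `(N + 1)`-vector of class priors (absent class
#'   first), summing to 1. Default: uniform.
#' @return An object of class `"flat_model"`.
#' @examples
#' fm <- flat_model(means = cbind(c(0.5, 0.5), c(1.5, 0.5), c(0.5, 1.5)))
#' flat_posterior(fm, c(1, 1))
#' @export
flat_model <- function(means, covariance = NULL, prior = NULL,
                       state_labels = NULL) {
  if (is.null(dim(means))) means <- matrix(means, ncol = 1L)
  means <- as.matrix(means)
  storage.mode(means) <- "double"
  M <- nrow(means)
  K <- ncol(means)
  if (K < 2L)
    stop("means: need at least 2 columns (absent class plus >= 1 stimulus class)")
  if (is.null(covariance)) covariance <- diag(M)
  covariance <- as.matrix(covariance)
  storage.mode(covariance) <- "double"
  if (is.null(prior)) prior <- rep(1 / K, K)
  if (is.null(state_labels))
    state_labels <- c("absent", paste0("w", seq_len(K - 1L)))

  if (length(prior) != K || anyNA(prior) || any(prior < 0))
    stop("prior: must be ", K, " non-negative probabilities (absent class first)")
  if (abs(sum(prior) - 1) > 1e-12)
    stop("prior: must sum to 1 (got ", format(sum(prior), digits = 15), ")")

  # reuse the emission checks via a throwaway hierarchical shell
  shell <- structure(
    list(n_states = K - 1L, feature_dim = M, means = means,
         covariance = covariance, prior_presence = 0.5,
         prior_content = rep(1 / (K - 1L), K - 1L),
         state_labels = state_labels),
    class = "hoss_model"
  )
  validate_hoss_model(shell)

  structure(
    list(
      n_states = K - 1L,
      feature_dim = M,
      means = means,
      covariance = covariance,
      prior = as.numeric(prior),
      state_labels = as.character(state_labels),
      chol_cov = chol(covariance)
    ),
    class = "flat_model"
  )
}

#' Convert a flat comparator to an equivalent hierarchical model
#'
#' Builds a [hoss_model()] whose induced marginal prior over the `N + 1`
#' content states equals the flat model's class prior: `P(a1)` is set to
#' `1 - prior[absent]` and `P(wi|a1)` to the renormalized stimulus-class
#' priors. With matched priors the hierarchy collapses to flat Bayes at the
#' content level, which isolates the architectural difference between the
#' two models (the presence query and prior factorization).
#'
#' @param flat an object of class `"flat_model"`.
#' @return An object of class `"hoss_model"`.
#' @export
as_hoss_model <- function(flat) {
  stopifnot(inherits(flat, "flat_model"))
  pa <- 1 - flat$prior[1L]
  pc <- if (pa > 0) flat$prior[-1L] / pa else rep(1 / flat$n_states, flat$n_states)
  hoss_model(flat$means, flat$covariance, prior_presence = pa,
             prior_content = pc, state_labels = flat$state_labels)
}

#' Convert a hierarchical model to its flat comparator
#'
#' @param model an object of class `"hoss_model"`.
#' @param prior optional flat prior over all `N + 1` classes; defaults to
#'   uniform (the conventional flat-SDT choice), not to the hierarchical
#'   model's induced marginal.
#' @return An object of class `"flat_model"`.
#' @export
as_flat_model <- function(model, prior = NULL) {
  stopifnot(inherits(model, "hoss_model"))
  flat_model(model$means, model$covariance, prior = prior,
             state_labels = model$state_labels)
}
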