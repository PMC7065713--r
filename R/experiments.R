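# Simulation experiments: feature-space maps, seeded trial sampling, and the
# precision-sweep masking experiment.

#' Define a 2D evaluation lattice
#'
#' @param lower,upper per-axis bounds (scalars are recycled to both axes);
#'   `upper > lower`.
#' @param step lattice step in feature-activation units; `step > 0`.
#' @return An object of class `"hoss_grid"`: list of axis sequences
#'   `x1`, `x2`.
#' @examples
#' grid_spec(-1, 3, 0.1)
#' @export
grid_spec <- function(lower = -1, upper = 3, step = 0.1) {
  lower <- rep_len(as.numeric(lower), 2L)
  upper <- rep_len(as.numeric(upper), 2L)
  step <- rep_len(as.numeric(step), 2L)
  if (any(!is.finite(c(lower, upper, step)))) stop("grid bounds must be finite")
  if (any(upper <= lower)) stop("grid: upper must exceed lower on both axes")
  if (any(step <= 0)) stop("grid: step must be positive")
  n_pts <- prod(floor((upper - lower) / step) + 1)
  if (n_pts > 1e6)
    stop("grid: lattice exceeds 1e6 points; coarsen step or shrink bounds")
  x1 <- seq(lower[1L], upper[1L], by = step[1L])
  x2 <- seq(lower[2L], upper[2L], by = step[2L])
  structure(list(x1 = x1, x2 = x2), class = "hoss_grid")
}

#' Posterior, confidence and surprise maps over a 2D feature lattice
#'
#' Evaluates the presence posterior, confidence in identity and both
#' belief-update measures at every point of a 2D lattice, for models with
#' `feature_dim == 2`. Points lying on the 0.5 iso-contour of the presence
#' posterior are flagged in `on_contour`: a point is flagged when
#' `p_presence` is exactly 0.5 or when `p_presence - 0.5` changes sign
#' between the point and any of its 4 lattice neighbours (both sides of a
#' crossing are flagged).
#'
#' @param model a [hoss_model()] with `feature_dim == 2`.
#' @param grid a [grid_spec()]; the default covers the near-threshold
#'   parameter set.
#' @param lambda sensory precision multiplier.
#' @return An object of class `"hoss_map"`: a data frame with one row per
#'   lattice point (x2 varying fastest) and columns `x1`, `x2`,
#'   `p_presence`, `confidence`, `kl_w`, `kl_a`, `on_contour`.
#' @examples
#' m <- hoss_model(cbind(c(0.5, 0.5), c(1.5, 0.5), c(0.5, 1.5)))
#' gm <- grid_map(m, grid_spec(-1, 3, 0.5))
#' head(gm)
#' @export
grid_map <- function(model, grid = grid_spec(), lambda = 1) {
  stopifnot(inherits(model, "hoss_model"), inherits(grid, "hoss_grid"))
  if (model$feature_dim != 2L)
    stop("grid_map is defined for 2D feature spaces (feature_dim == 2); got ",
         model$feature_dim)
  n1 <- length(grid$x1); n2 <- length(grid$x2)
  X <- cbind(rep(grid$x1, each = n2), rep(grid$x2, times = n1))
  post <- posterior_matrix(model, X, lambda)

  # sign-change contour flag on the n2 x n1 lattice (rows follow x2)
  s <- matrix(sign(post$p_presence - 0.5), nrow = n2, ncol = n1)
  flag <- s == 0
  if (n2 > 1L) {
    cross <- s[-1L, , drop = FALSE] * s[-n2, , drop = FALSE] < 0
    flag[-1L, ] <- flag[-1L, ] | cross
    flag[-n2, ] <- flag[-n2, ] | cross
  }
  if (n1 > 1L) {
    cross <- s[, -1L, drop = FALSE] * s[, -n1, drop = FALSE] < 0
    flag[, -1L] <- flag[, -1L] | cross
    flag[, -n1] <- flag[, -n1] | cross
  }

  out <- data.frame(
    x1 = X[, 1L], x2 = X[, 2L],
    p_presence = post$p_presence,
    confidence = post$confidence,
    kl_w = post$kl_w, kl_a = post$kl_a,
    on_contour = as.vector(flag)
  )
  class(out) <- c("hoss_map", "data.frame")
  attr(out, "grid") <- grid
  attr(out, "lambda") <- lambda
  out
}

# Deterministic substream seed from a base seed and index path; keeps the
# result in [1, 2^31 - 2] so set.seed() always accepts it. Each class (and
# each precision level of a sweep) gets its own substream, so adding classes
# or levels never perturbs draws made for earlier ones.
#' @keywords internal
derive_seed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483647
  for (i in c(...)) s <- (s * 48271 + i) %% 2147483647
  as.integer(s + 1)
}

#' Sample trials from the generative model and infer on each
#'
#' Draws `n_per_class` feature vectors from the emission Gaussian of every
#' state `w0..wN` (at precision `lambda`), then runs full inference on each
#' sample. Draws are seeded and bit-for-bit reproducible; each class uses
#' its own deterministic substream of the base seed.
#'
#' @param model a [hoss_model()].
#' @param n_per_class number of trials to draw per class (>= 1).
#' @param seed integer base seed.
#' @param lambda sensory precision; both generation and inference use
#'   covariance `Sigma / lambda` (the observer is matched to the world).
#' @param report_threshold criterion for the `"seen"` report.
#' @param kl_w_mode content-level surprise mode, see [belief_update()].
#' @return A data frame of class `"hoss_trials"` with columns `trial_id`,
#'   `lambda`, `true_class`, `x1..xM`, `p_presence`, `confidence`, `report`,
#'   `kl_w`, `kl_a`.
#' @examples
#' m <- hoss_model(cbind(c(3.5, 3.5), c(7, 3.5), c(3.5, 7)))
#' tr <- sample_trials(m, n_per_class = 5, seed = 1)
#' table(tr$true_class, tr$report)
#' @export
sample_trials <- function(model, n_per_class, seed, lambda = 1,
                          report_threshold = 0.5,
                          kl_w_mode = c("joint", "per_node_sum")) {
  stopifnot(inherits(model, "hoss_model"))
  kl_w_mode <- match.arg(kl_w_mode)
  if (!is.numeric(n_per_class) || length(n_per_class) != 1L ||
      is.na(n_per_class) || n_per_class < 1)
    stop("n_per_class must be a positive integer")
  n_per_class <- as.integer(n_per_class)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  if (lambda <= 0) stop("lambda must be positive")

  M <- model$feature_dim
  K <- model$n_states + 1L
  R <- model$chol_cov / sqrt(lambda)
  X <- matrix(0, n_per_class * K, M)
  true_class <- character(n_per_class * K)
  for (k in seq_len(K)) {
    set.seed(derive_seed(seed, k))
    z <- matrix(stats::rnorm(n_per_class * M), n_per_class, M)
    rows <- (k - 1L) * n_per_class + seq_len(n_per_class)
    X[rows, ] <- sweep(z %*% R, 2L, model$means[, k], "+")
    true_class[rows] <- model$state_labels[k]
  }

  post <- posterior_matrix(model, X, lambda, kl_w_mode = kl_w_mode)
  xcols <- as.data.frame(X)
  names(xcols) <- paste0("x", seq_len(M))
  out <- data.frame(
    trial_id = seq_len(nrow(X)),
    lambda = lambda,
    true_class = true_class,
    xcols,
    p_presence = post$p_presence,
    confidence = post$confidence,
    report = ifelse(post$p_presence > report_threshold, "seen", "unseen"),
    kl_w = post$kl_w,
    kl_a = post$kl_a
  )
  class(out) <- c("hoss_trials", "data.frame")
  out
}

#' Report-conditioned belief-update summary
#'
#' Splits a trial table by the model's own report (not the true class:
#' misclassified absent-class trials pool into the `"seen"` category) and
#' averages both surprise measures per category. A category with no trials
#' yields `NA` means, never zero.
#'
#' @param trials a data frame as returned by [sample_trials()], containing
#'   at least `report`, `kl_w`, `kl_a`.
#' @return A one-row data frame with columns `n_seen`, `n_unseen`, `p_seen`,
#'   `mean_kl_w_seen`, `mean_kl_w_unseen`, `mean_kl_a_seen`,
#'   `mean_kl_a_unseen`, `asym_w`, `asym_a` (asymmetry indices are
#'   seen-mean minus unseen-mean).
#' @export
summarize_by_report <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0L)
    stop("trials must be a non-empty data frame")
  stopifnot(all(c("report", "kl_w", "kl_a") %in% names(trials)))
  seen <- trials$report == "seen"
  mean_or_na <- function(v, idx) if (any(idx)) mean(v[idx]) else NA_real_
  out <- data.frame(
    n_seen = sum(seen),
    n_unseen = sum(!seen),
    p_seen = mean(seen),
    mean_kl_w_seen = mean_or_na(trials$kl_w, seen),
    mean_kl_w_unseen = mean_or_na(trials$kl_w, !seen),
    mean_kl_a_seen = mean_or_na(trials$kl_a, seen),
    mean_kl_a_unseen = mean_or_na(trials$kl_a, !seen)
  )
  out$asym_w <- out$mean_kl_w_seen - out$mean_kl_w_unseen
  out$asym_a <- out$mean_kl_a_seen - out$mean_kl_a_unseen
  out
}

#' Simulated backward-masking experiment over a precision sweep
#'
#' Models increasing stimulus-onset asynchrony (SOA) as increasing sensory
#' precision: at each level `lambda` the effective covariance for both
#' stimulus generation and observer inference is `Sigma / lambda`. For each
#' level, `n_per_class` trials per class are drawn, inference is run, trials
#' are classified by the model's own report, and report-conditioned mean
#' belief updates are aggregated. The signature pattern is asymmetric
#' ignition: the content-level surprise gap between seen and unseen trials
#' grows with precision while the awareness-level surprise stays
#' comparatively symmetric.
#'
#' @inheritParams sample_trials
#' @param precisions vector of positive precision multipliers, conventionally
#'   ascending (ascending SOA). Default
#'   `c(0.02, 0.05, 0.1, 0.2, 0.5, 1, 2)`, which spans near-chance to
#'   near-ceiling seen rates for the packaged wide-separation parameter set.
#' @param keep_trials if `TRUE`, the per-trial tables are retained in the
#'   result (one per level, row-bound).
#' @return An object of class `"hoss_sweep"`: list with `summary` (one row
#'   per level: `lambda`, `n_seen`, `n_unseen`, `p_seen`,
#'   `mean_kl_w_seen`, `mean_kl_w_unseen`, `mean_kl_a_seen`,
#'   `mean_kl_a_unseen`, `asym_w`, `asym_a`), optional `trials`, and the
#'   call parameters.
#' @examples
#' m <- hoss_model(cbind(c(3.5, 3.5), c(7, 3.5), c(3.5, 7)))
#' sw <- masking_sweep(m, precisions = c(0.1, 1), n_per_class = 100, seed = 7)
#' sw$summary
#' @export
masking_sweep <- function(model, precisions = c(0.02, 0.05, 0.1, 0.2, 0.5, 1, 2),
                          n_per_class = 2000, seed = 1,
                          kl_w_mode = c("joint", "per_node_sum"),
                          report_threshold = 0.5, keep_trials = FALSE) {
  stopifnot(inherits(model, "hoss_model"))
  kl_w_mode <- match.arg(kl_w_mode)
  if (length(precisions) < 1L || any(!is.finite(precisions)) ||
      any(precisions <= 0))
    stop("precisions must be positive finite values")

  rows <- vector("list", length(precisions))
  trial_tabs <- if (keep_trials) vector("list", length(precisions)) else NULL
  for (i in seq_along(precisions)) {
    lam <- precisions[i]
    tr <- sample_trials(model, n_per_class, seed = derive_seed(seed, 1000L + i),
                        lambda = lam, report_threshold = report_threshold,
                        kl_w_mode = kl_w_mode)
    rows[[i]] <- cbind(lambda = lam, summarize_by_report(tr))
    if (keep_trials) trial_tabs[[i]] <- tr
  }
  out <- list(
    summary = do.call(rbind, rows),
    trials = if (keep_trials) do.call(rbind, trial_tabs) else NULL,
    precisions = precisions,
    n_per_class = as.integer(n_per_class),
    seed = seed,
    kl_w_mode = kl_w_mode,
    report_threshold = report_threshold
  )
  class(out) <- "hoss_sweep"
  out
}

#' @export
print.hoss_sweep <- function(x, digits = 4, ...) {
  cat("precision-sweep masking simulation (", x$n_per_class,
      " trials/class, seed ", x$seed, ", kl_w_mode = ", x$kl_w_mode, ")\n",
      sep = "")
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}
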