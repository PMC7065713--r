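# S3 methods for the model classes.

#' @export
print.hoss_model <- function(x, digits = 4, ...) {
  cat("higher-order state-space observer model\n")
  cat("  content states:", x$n_states, " feature dims:", x$feature_dim, "\n")
  cat("  P(present) =", format(x$prior_presence, digits = digits),
      "; P(w_i | present) =",
      paste(format(x$prior_content, digits = digits), collapse = " "), "\n")
  mns <- x$means
  colnames(mns) <- x$state_labels
  rownames(mns) <- paste0("x", seq_len(x$feature_dim))
  cat("  emission means:\n")
  print(round(mns, digits))
  invisible(x)
}

#' @export
print.flat_model <- function(x, digits = 4, ...) {
  cat("flat signal-detection comparator model\n")
  cat("  classes:", x$n_states + 1L, "(incl. absent) feature dims:",
      x$feature_dim, "\n")
  cat("  class prior:",
      paste(format(x$prior, digits = digits), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.hoss_model <- function(object, ...) {
  d <- stats::dist(t(object$means))
  out <- list(
    n_states = object$n_states,
    feature_dim = object$feature_dim,
    prior_marginal = stats::setNames(object$prior_marginal,
                                     object$state_labels),
    min_mean_separation = min(d),
    max_mean_separation = max(d),
    covariance_logdet = 2 * sum(log(diag(object$chol_cov)))
  )
  class(out) <- "summary.hoss_model"
  out
}

#' @export
print.summary.hoss_model <- function(x, digits = 4, ...) {
  cat("HOSS model summary\n")
  cat("  states:", x$n_states, " feature dims:", x$feature_dim, "\n")
  cat("  induced marginal prior over {w0..wN}:\n")
  print(round(x$prior_marginal, digits))
  cat("  mean separation (Euclidean): min",
      format(x$min_mean_separation, digits = digits), " max",
      format(x$max_mean_separation, digits = digits), "\n")
  cat("  log det covariance:", format(x$covariance_logdet, digits = digits),
      "\n")
  invisible(x)
}

#' Posterior inference for a matrix of sensory samples
#'
#' Vectorized counterpart of [infer()]: runs exact inference on every row
#' of `newdata` and returns one row of posterior quantities per sample.
#'
#' @param object a [hoss_model()].
#' @param newdata numeric matrix or data frame with `feature_dim` columns
#'   (a bare vector is taken as one sample).
#' @param lambda sensory precision multiplier.
#' @param report_threshold criterion for the `"seen"` report.
#' @param kl_w_mode content-level surprise mode, see [belief_update()].
#' @param ... unused.
#' @return A data frame with columns `x1..xM`, `p_presence`, `confidence`,
#'   `report`, `kl_w`, `kl_a`, and one `p_<label>` column per state.
#' @export
predict.hoss_model <- function(object, newdata, lambda = 1,
                               report_threshold = 0.5,
                               kl_w_mode = c("joint", "per_node_sum"), ...) {
  kl_w_mode <- match.arg(kl_w_mode)
  X <- as_sample_matrix(object, as.matrix(newdata))
  post <- posterior_matrix(object, X, lambda, kl_w_mode = kl_w_mode)
  xcols <- as.data.frame(X)
  names(xcols) <- paste0("x", seq_len(ncol(X)))
  pcols <- as.data.frame(post$p_states)
  names(pcols) <- paste0("p_", object$state_labels)
  cbind(
    xcols,
    data.frame(
      p_presence = post$p_presence,
      confidence = post$confidence,
      report = ifelse(post$p_presence > report_threshold, "seen", "unseen"),
      kl_w = post$kl_w,
      kl_a = post$kl_a
    ),
    pcols
  )
}

#' Simulate trials from the generative model
#'
#' Runs the generative model forward: draws `nsim` trials per class and
#' performs inference on each. Thin wrapper around [sample_trials()].
#'
#' @param object a [hoss_model()].
#' @param nsim trials per class.
#' @param seed integer base seed (required for reproducibility).
#' @param lambda sensory precision multiplier.
#' @param ... passed to [sample_trials()].
#' @return A `"hoss_trials"` data frame, see [sample_trials()].
#' @export
simulate.hoss_model <- function(object, nsim = 1, seed = 1, lambda = 1, ...) {
  sample_trials(object, n_per_class = nsim, seed = seed, lambda = lambda, ...)
}

#' Plot a feature-space map or a precision sweep
#'
#' For a `"hoss_map"`, draws an image of one map quantity over the lattice
#' with the 0.5 presence iso-contour overlaid in white. For a
#' `"hoss_sweep"`, draws the seen rate and the report-conditioned mean
#' surprise per level. Plotting is a thin display layer over the tables;
#' all quantitative content lives in the data frames themselves.
#'
#' @param x a `"hoss_map"` from [grid_map()].
#' @param what which column to draw.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.hoss_map <- function(x, what = c("p_presence", "confidence",
                                      "kl_w", "kl_a"), ...) {
  what <- match.arg(what)
  grid <- attr(x, "grid")
  n1 <- length(grid$x1); n2 <- length(grid$x2)
  z <- matrix(x[[what]], nrow = n2, ncol = n1)  # rows follow x2
  graphics::image(grid$x1, grid$x2, t(z), xlab = "feature 1",
                  ylab = "feature 2", main = what,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  p <- matrix(x$p_presence, nrow = n2, ncol = n1)
  graphics::contour(grid$x1, grid$x2, t(p), levels = 0.5, col = "white",
                    lwd = 2, add = TRUE, drawlabels = FALSE)
  invisible(x)
}

#' @rdname plot.hoss_map
#' @export
plot.hoss_sweep <- function(x, ...) {
  s <- x$summary
  oldpar <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(oldpar))
  graphics::plot(s$lambda, s$p_seen, type = "b", log = "x",
                 xlab = "precision (SOA proxy)", ylab = "P(report seen)",
                 ylim = c(0, 1), main = "seen rate", ...)
  rng <- range(c(s$mean_kl_w_seen, s$mean_kl_w_unseen), na.rm = TRUE)
  graphics::matplot(s$lambda, cbind(s$mean_kl_w_seen, s$mean_kl_w_unseen),
                    type = "b", log = "x", pch = c(19, 1), lty = 1,
                    col = c("firebrick", "steelblue"), ylim = rng,
                    xlab = "precision (SOA proxy)", ylab = "mean KL (nats)",
                    main = "content-level surprise")
  graphics::legend("topleft", c("seen", "unseen"), pch = c(19, 1),
                   col = c("firebrick", "steelblue"), bty = "n")
  rng <- range(c(s$mean_kl_a_seen, s$mean_kl_a_unseen), na.rm = TRUE)
  graphics::matplot(s$lambda, cbind(s$mean_kl_a_seen, s$mean_kl_a_unseen),
                    type = "b", log = "x", pch = c(19, 1), lty = 1,
                    col = c("firebrick", "steelblue"), ylim = rng,
                    xlab = "precision (SOA proxy)", ylab = "mean KL (nats)",
                    main = "awareness-level surprise")
  invisible(x)
}
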