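# Shared fixtures, built in code.

# Near-threshold 2D parameter set: absent mean (0.5, 0.5), content means one
# unit away along each axis, identity covariance, flat hierarchical priors.
near_threshold_model <- function(...) {
  hoss_model(cbind(c(0.5, 0.5), c(1.5, 0.5), c(0.5, 1.5)), ...)
}

# Widely separated 2D parameter set used in the masking sweep: absent mean
# (3.5, 3.5), content means 3.5 units away along each axis.
wide_separation_model <- function(...) {
  hoss_model(cbind(c(3.5, 3.5), c(7, 3.5), c(3.5, 7)), ...)
}

# Random valid model: N content states in M dims, random PD covariance
# (A'A + eps I), random priors. Draws from the current RNG stream.
random_model <- function(N = sample(1:5, 1), M = sample(1:4, 1)) {
  means <- matrix(stats::rnorm(M * (N + 1), sd = 2), M, N + 1)
  A <- matrix(stats::rnorm(M * M), M, M)
  covariance <- crossprod(A) + diag(M) * 0.2
  pc <- stats::runif(N) + 0.05
  hoss_model(means, covariance,
             prior_presence = stats::runif(1, 0.05, 0.95),
             prior_content = pc / sum(pc))
}

# Independent Gaussian density via mahalanobis + det, bypassing the
# package's Cholesky path.
ref_density <- function(x, mu, sigma) {
  M <- length(x)
  q <- stats::mahalanobis(matrix(x, 1), mu, sigma)
  exp(-0.5 * q) / sqrt((2 * pi)^M * det(sigma))
}
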