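test_that("class likelihoods match an independent Gaussian density", {
  m <- near_threshold_model()
  # density at a state's own mean is the bivariate standard-normal mode
  lik <- class_likelihoods(m, c(0.5, 0.5))
  expect_equal(unname(lik[1]), 1 / (2 * pi), tolerance = 1e-12)
  # the centroid (1, 1) is equidistant from all three means
  lik <- class_likelihoods(m, c(1, 1))
  expect_equal(max(lik) - min(lik), 0, tolerance = 1e-15)
  # hand-evaluated exponents at (1.5, 0.5): distances^2 (1, 0, 2) to
  # (w0, w1, w2) give ratios (e^-0.5, 1, e^-1)
  lik <- class_likelihoods(m, c(1.5, 0.5))
  expect_equal(unname(lik / lik[2]),
               c(exp(-0.5), 1, exp(-1)), tolerance = 1e-12)
  # absolute values against a mahalanobis/det reference, incl. scaled cov
  set.seed(11)
  for (i in 1:20) {
    rm <- random_model()
    x <- stats::rnorm(rm$feature_dim, sd = 2)
    lam <- stats::runif(1, 0.2, 5)
    got <- class_likelihoods(rm, x, lambda = lam)
    want <- vapply(seq_len(rm$n_states + 1), function(k)
      ref_density(x, rm$means[, k], rm$covariance / lam), numeric(1))
    expect_equal(unname(got), want, tolerance = 1e-10)
  }
  expect_error(class_likelihoods(m, c(1, 2, 3)), "dimension")
  expect_error(class_likelihoods(m, c(1, NA)), "finite")
})

test_that("presence posterior matches hand-derived closed forms", {
  m <- near_threshold_model()
  # equal likelihoods leave the posterior at the prior
  expect_equal(posterior_presence(m, c(1, 1)), 0.5, tolerance = 1e-14)
  # closed form at (1.5, 0.5) under flat hierarchical priors
  num <- 0.25 * (1 + exp(-1))
  expect_equal(posterior_presence(m, c(1.5, 0.5)),
               num / (num + 0.5 * exp(-0.5)), tolerance = 1e-13)
  # at the absent mean of the wide-separation space the absent class wins
  w <- wide_separation_model()
  expect_lt(posterior_presence(w, c(3.5, 3.5)), 0.5)
  expect_equal(posterior_presence(w, c(3.5, 3.5)),
               posterior_oracle(w, c(3.5, 3.5))$p_presence, tolerance = 1e-12)
})

test_that("content-state posterior is a normalized marginal with the right argmax", {
  m <- near_threshold_model()
  expect_equal(unname(posterior_states(m, c(1, 1))), c(0.5, 0.25, 0.25),
               tolerance = 1e-13)
  # symmetric means mirrored about the identity line: equal content
  # posteriors on the line
  p <- posterior_states(m, c(0.3, 0.3))
  expect_equal(unname(p[2]), unname(p[3]), tolerance = 1e-13)
  # a sample dominated by one feature axis pins the matching content state
  w <- wide_separation_model()
  expect_identical(unname(which.max(posterior_states(w, c(7.2, 3.4)))), 2L)
  expect_identical(unname(which.max(posterior_states(w, c(3.4, 7.2)))), 3L)
})

test_that("inference bundles report, confidence and posteriors coherently", {
  m <- near_threshold_model()
  # exactly at threshold -> unseen (strict inequality)
  b <- infer(m, c(1, 1))
  expect_identical(b$report, "unseen")
  expect_equal(b$p_presence, 0.5, tolerance = 1e-14)
  # seen case with hand-derived confidence
  b <- infer(m, c(1.5, 0.5))
  expect_identical(b$report, "seen")
  denom <- 0.25 * (1 + exp(-1)) + 0.5 * exp(-0.5)
  expect_equal(b$confidence, 0.25 / denom, tolerance = 1e-13)
  expect_lte(b$confidence, b$p_presence)
  # far from all content means the absent state dominates
  expect_identical(infer(wide_separation_model(), c(0, 0))$report, "unseen")
  expect_error(infer(m, c(1, 1), report_threshold = 1.5), "report_threshold")
  expect_output(print(b), "seen")
})

test_that("belief updates vanish at the prior and obey Bernoulli symmetry", {
  m <- near_threshold_model()
  bu <- belief_update(m, c(1, 1))
  expect_equal(bu$kl_w, 0, tolerance = 1e-13)
  expect_equal(bu$kl_a, 0, tolerance = 1e-13)
  expect_output(print(bu), "nats")
  # Bernoulli KL about a flat prior is symmetric: find samples whose
  # presence posteriors are complementary by symmetry of the parameter set
  kl1 <- belief_update(m, c(1.5, 0.5))
  kl2 <- belief_update(m, c(0.5, 1.5))
  expect_equal(kl1$kl_a, kl2$kl_a, tolerance = 1e-12)
  p1 <- posterior_presence(m, c(1.5, 0.5))
  # direct check of the symmetry kl_a(p) = kl_a(1 - p) via the formula
  klb <- function(p, q) p * log(p / q) + (1 - p) * log((1 - p) / (1 - q))
  expect_equal(klb(p1, 0.5), klb(1 - p1, 0.5), tolerance = 1e-12)
})

test_that("high-precision belief updates reach the degenerate-posterior limits", {
  # Sigma = 0.01 I: posteriors are effectively point masses
  w <- wide_separation_model(covariance = 0.01 * diag(2))
  # at a content mean: KL(delta_w1 || (0.5, 0.25, 0.25)) = -log(0.25)
  bu <- belief_update(w, c(7, 3.5))
  expect_equal(bu$kl_w, log(4), tolerance = 1e-6)
  expect_equal(bu$kl_a, log(2), tolerance = 1e-6)
  # at the absent mean: KL(delta_w0 || prior) = -log(0.5)
  bu <- belief_update(w, c(3.5, 3.5))
  expect_equal(bu$kl_w, log(2), tolerance = 1e-6)
  expect_equal(bu$kl_a, log(2), tolerance = 1e-6)
  # same limits via the lambda route on the unit-covariance model
  bu <- belief_update(wide_separation_model(), c(7, 3.5), lambda = 100)
  expect_equal(bu$kl_w, log(4), tolerance = 1e-6)
})

test_that("per-node surprise mode sums binary-marginal divergences", {
  # with a single content state both binary nodes carry the categorical
  # distribution, so the per-node sum is exactly twice the joint KL
  m1 <- hoss_model(cbind(0, 2), prior_presence = 0.3)
  x <- 1.2
  joint <- belief_update(m1, x, kl_w_mode = "joint")$kl_w
  pernode <- belief_update(m1, x, kl_w_mode = "per_node_sum")$kl_w
  expect_equal(pernode, 2 * joint, tolerance = 1e-12)
  # independent evaluation for N = 2
  m <- near_threshold_model()
  x <- c(2, 0.2)
  p <- posterior_states(m, x)
  q <- m$prior_marginal
  klb <- function(p, q) {
    t1 <- if (p > 0) p * log(p / q) else 0
    t2 <- if (p < 1) (1 - p) * log((1 - p) / (1 - q)) else 0
    t1 + t2
  }
  want <- sum(vapply(1:3, function(k) klb(p[k], q[k]), numeric(1)))
  expect_equal(belief_update(m, x, kl_w_mode = "per_node_sum")$kl_w, want,
               tolerance = 1e-12)
})

test_that("posteriors stay normalized in log space for extreme samples", {
  m <- near_threshold_model()
  for (x in list(c(100, 0), c(-70, -70), c(100, 100), c(0, -100))) {
    p <- posterior_states(m, x)
    expect_true(all(is.finite(p)))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    pp <- posterior_presence(m, x)
    expect_gte(pp, 0)
    expect_lte(pp, 1)
  }
})

test_that("level consistency: presence equals summed content posteriors", {
  set.seed(303)
  for (i in 1:50) {
    rm <- random_model()
    x <- stats::rnorm(rm$feature_dim, sd = 4)
    p <- posterior_states(rm, x)
    expect_equal(posterior_presence(rm, x), sum(p[-1]), tolerance = 1e-12)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("posterior equals prior at Mahalanobis-equidistant points", {
  # construct models whose means all sit at equal Mahalanobis distance from
  # a centre c, then probe at c
  set.seed(99)
  for (i in 1:25) {
    N <- sample(1:4, 1); M <- sample(2:4, 1)
    A <- matrix(stats::rnorm(M * M), M, M)
    covariance <- crossprod(A) + diag(M) * 0.3
    L <- t(chol(covariance))
    centre <- stats::rnorm(M)
    r <- stats::runif(1, 0.5, 3)
    means <- vapply(seq_len(N + 1), function(k) {
      u <- stats::rnorm(M); u <- u / sqrt(sum(u^2))
      centre + r * as.numeric(L %*% u)
    }, numeric(M))
    m <- hoss_model(means, covariance)
    expect_equal(unname(posterior_states(m, centre)), m$prior_marginal,
                 tolerance = 1e-12)
    bu <- belief_update(m, centre)
    expect_lt(bu$kl_w, 1e-12)
    expect_lt(bu$kl_a, 1e-12)
  }
})

test_that("axis-swap symmetry of the 2D maps", {
  for (m in list(near_threshold_model(), wide_separation_model())) {
    pts <- list(c(0.2, 1.7), c(2.5, -0.5), c(6, 3), c(1.1, 1.0))
    for (x in pts) {
      xs <- rev(x)
      expect_equal(posterior_presence(m, x), posterior_presence(m, xs),
                   tolerance = 1e-12)
      expect_equal(infer(m, x)$confidence, infer(m, xs)$confidence,
                   tolerance = 1e-12)
    }
  }
})

test_that("degenerate presence prior forces the oracle and main path to agree", {
  m <- hoss_model(cbind(c(0, 0), c(2, 0)), prior_presence = 1)
  for (x in list(c(0, 0), c(5, 5), c(-3, 1))) {
    expect_equal(posterior_presence(m, x), 1, tolerance = 1e-12)
    expect_equal(posterior_oracle(m, x)$p_presence, 1, tolerance = 1e-12)
    expect_equal(unname(posterior_states(m, x)[1]), 0, tolerance = 1e-300)
  }
})
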