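---
title: "Awareness reports as higher-order inference: the model behind hoss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Awareness reports as higher-order inference: the model behind hoss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoss)
```

## The model

`hoss` simulates how an ideal observer comes to say "I saw it" or "I saw
nothing". The observer carries a two-level generative model of its sensory
input:

* **Awareness state** `A`: binary, `a1` (something present) vs `a0`
  (nothing present), with prior `P(a1)`.
* **Content state** `W`: categorical over `w0, w1, ..., wN`, where `w1..wN`
  are perceptual identities (say, left- vs right-tilted gratings) and `w0`
  is the no-content state.
* **Sensory evidence** `X`: an `M`-dimensional feature vector drawn from a
  multivariate Gaussian `N(mu_k, Sigma)` whose mean depends on the content
  state; the covariance is shared across states.

The two levels are tied together asymmetrically: `P(w0 | a0) = 1` and
`P(w0 | a1) = 0`. Being aware entails having some content; being unaware
entails having none. This nesting — many content states under "present",
exactly one under "absent" — is the substantive assumption of the model,
and everything the package demonstrates follows from it. Inference is
exact: with `N + 1` discrete states the joint is a small table, and both
queries are plain marginals,

* detection: `P(a1 | x) ∝ P(a1) Σ_i P(wi|a1) L(x|wi)`,
* identification: `P(wk | x) ∝ P(wk) L(x|wk)` under the induced marginal
  prior `(1 − P(a1), P(a1)P(w1|a1), ...)`.

The awareness report is a threshold decision on the detection posterior:
"seen" iff `P(a1|x) > 0.5` (strictly; a posterior exactly at threshold is
reported "unseen" — ties are not evidence for presence). Confidence in
identity is `max_i P(wi|x)`, the maximum *marginal* content posterior, not
a posterior conditioned on presence. These are decision-rule conventions,
fixed here once: the strict threshold matches the definition of the report
as posterior mass strictly favouring presence, and marginal confidence
keeps detection and identification queries on the same joint rather than
making one conditional on the other. Because the content marginals sum to
the presence posterior, confidence can never exceed reported visibility.

### Belief updates as an ignition proxy

For each sample the package computes the Kullback–Leibler divergence from
prior to posterior, in nats, at both levels: `kl_w` for the content level
and `kl_a` for the (Bernoulli) awareness level. KL(posterior ‖ prior) is
the standard "Bayesian surprise" direction in the predictive-coding
literature, where it stands proxy for the summed prediction-error activity
a level of a neural hierarchy would produce; the reverse direction is not
offered because nothing downstream depends on it and two directions invite
silent misuse.

The asymmetric nesting makes `kl_w` asymmetric across reports. With flat
hierarchical priors (`P(a1) = 0.5`, `P(wi|a1) = 1/N`) the induced content
prior is `(1/2, 1/(2N), ..., 1/(2N))`. When precise evidence lands near a
content mean the content posterior collapses onto one `wi` and
`kl_w → −log(1/(2N)) = log(2N)`; when it lands near the absent mean,
`kl_w → −log(1/2) = log 2`. For `N = 2`: `log 4 ≈ 1.386` nats on "seen"
trials versus `log 2 ≈ 0.693` on "unseen" — a factor-two gap that grows
with `N`, the model's computational correlate of global ignition. At the
awareness level both limits are `log 2`: detection surprise is symmetric.
The test suite and `scripts/acceptance.R` recompute these limits from
simulated trials rather than quoting them.

`kl_w` has two modes. The default (`joint`) is the KL of the full
categorical distribution over `{w0..wN}` — the simplest reading of
"belief change at the content level". `per_node_sum` instead sums the
binary-marginal KL of every state node, the natural reading if each
content state is a separate population whose activation tracks its own
marginal. The two orderings agree; only the scale differs (for `N = 1`
the per-node sum is exactly twice the joint KL, a relation the tests pin
down).

### The flat comparator

`flat_model()` implements the classical signal-detection alternative:
"absent" is just another class in a single-level Bayesian classifier with
one prior over all `N + 1` classes. Evidence handling is identical — the
tests verify that a hierarchical model whose induced marginal prior equals
the flat prior reproduces the flat posterior exactly — so the only
differences are the prior factorization and the existence of a dedicated
presence query. Under a uniform prior the flat model's surprise limit is
`log(N + 1)` at *every* class mean, present or absent alike: no ignition
asymmetry. Because the flat architecture has no presence state, a report
rule must be imposed; the default ("seen" iff `P(absent|x) < 0.5`) mirrors
the hierarchical threshold on `1 − P(absent)`, and an argmax rule is
available as an option. These comparator metrics are constructed for
contrast; the flat model has no quantitative behaviour to reproduce beyond
its architecture.

## Parameters and packaged configurations

Two 2D parameter sets ship with the package (YAML under `inst/extdata`),
both with identity covariance, flat hierarchical priors and `N = 2`
content states whose means each load one feature axis:

* `nearthreshold_2d.yaml` — absent mean `(0.5, 0.5)`, content means
  `(1.5, 0.5)` and `(0.5, 1.5)`. One standard deviation of separation:
  the regime where detection and identification posteriors dissociate
  visibly, used for the feature-space maps.
* `discrimination_2d.yaml` / `masking_sweep.yaml` — absent mean
  `(3.5, 3.5)`, content means `(7, 3.5)` and `(3.5, 7)`. Wide (3.5 sd)
  separation, used for the flat-SDT contrast and as the stimulus set of
  the masking simulation.

Which feature axis carries which content state is arbitrary; state labels
are display metadata and no computation depends on them.

The masking experiment models stimulus-onset asynchrony (SOA) as sensory
precision: a scalar `lambda > 0` multiplies the inverse covariance, so
both stimulus generation and observer inference use `Sigma / lambda`
(units: inverse feature-activation variance). The observer is matched to
the world — precision is known, not estimated; estimating it is a model
extension the package deliberately does not attempt. The packaged sweep
grid `{0.02, 0.05, 0.1, 0.2, 0.5, 1, 2}` was chosen once so that the
seen rate for present-class trials spans near-chance to near-ceiling for
the wide-separation set; the default of 2000 trials per class keeps
binomial error on the report rates near 1% while the whole sweep runs in
seconds. Trials are drawn in equal numbers from every class including
absent (the mix is configurable), and report-conditioned averages condition
purely on the model's report, so misclassified absent-class trials pool
into "seen".

Map lattices default to `[-1, 3]^2` with step 0.1 for the near-threshold
set (covering all three means with ~1.5 sd of margin); the wide-separation
set is mapped on `[0, 10]^2` with the same step. Axis extents are display
choices — posteriors are defined everywhere — and the step only controls
lattice resolution, including how finely the flagged 0.5 iso-contour of
`p_presence` is localized.

## Numerical choices

* **Log-space throughout.** Content means sit up to several sd from the
  evaluation region, and sweep precisions scale Mahalanobis distances by
  `lambda`; naive densities underflow (`exp(-612)` is zero in double
  precision) long before posteriors become ill-defined. All posteriors are
  normalized by log-sum-exp; the tests push `|x|` to 100 and require exact
  normalization.
* **One Cholesky factor.** `Sigma` is factorized once at construction
  (validating positive-definiteness as a side effect); `Sigma / lambda`
  reuses it as `chol(Sigma) / sqrt(lambda)` for both density evaluation
  and sampling.
* **Level consistency by construction.** `P(a1|x)` is computed as the sum
  of the content-state posteriors of one joint, so the two queries can
  never drift apart numerically.
* **KL conventions.** Nats everywhere; `0 log 0 = 0`. Posterior support is
  contained in prior support by construction (posterior mass is prior mass
  times a finite likelihood), so no KL is ever infinite; the code asserts
  this rather than assuming it.
* **Degenerate priors.** `P(a1) ∈ {0, 1}` is allowed: zero-prior states
  get `-Inf` log-prior and exactly zero posterior.
* **Seeding.** Every class (and every precision level of a sweep) draws
  from its own substream, derived from the base seed by a small
  multiplicative-congruential step, so adding classes or levels never
  perturbs draws made for earlier ones, and seeded runs are reproducible
  bit for bit — repeated runs write byte-identical CSVs.
* **The oracle.** `posterior_oracle()` re-derives every posterior by
  enumerating the expanded joint over all `(A, W)` pairs — including the
  zero-mass `(a1, w0)` and `(a0, wi)` cells — in plain arithmetic with
  `mahalanobis()`-based densities. It shares no code path with `infer()`
  beyond input validation and must agree with it to 1e-10; the test suite
  sweeps 200 randomized models through both.

## Design choices at genuinely open points

* **"Flat priors" at both levels** are read *conditionally*: `P(a1) = 0.5`
  and `P(wi|a1) = 1/N`. The induced marginal over `{w0..wN}` is then not
  flat — and cannot be: for `N > 1` a flat marginal over `N + 1` states
  would contradict a flat awareness prior. The hierarchical reading is the
  only self-consistent one, and it is what makes the `log 2N` vs `log 2`
  asymmetry emerge from flat beliefs rather than from a biased prior.
* **Confidence from marginal content posteriors**, not presence-conditioned
  ones (see above). A presence-conditioned variant can be recovered as
  `confidence / p_presence` from any returned table.
* **Tie-break at threshold → "unseen"**, the strict reading of
  "posterior above threshold".

## What the generator does and does not emulate

The built-in sampler *is* the model run forward: class-conditional
Gaussians with shared covariance, precision known to the observer. Passing
tests therefore demonstrate internal coherence of the architecture — that
exact inference in the nested model produces graded visibility, identity
confidence dissociating from detection in the unseen region, and the
asymmetric ignition signature — under exactly matched generative
assumptions. They do not show that real masking data follow these curves:
real sensory noise is non-Gaussian and state-dependent, real observers
misestimate precision, criteria drift over trials, and reaction times and
learning are outside the model. The package makes the architecture's
predictions explicit; it does not fit data.

## Known limitations

* No learning of the state space or priors; no precision inference; no
  temporal dynamics, message passing or reaction-time model.
* Shared covariance across states is assumed, not optional.
* Maps are restricted to 2D feature spaces (inference itself is
  dimension-general).
* The flat comparator's report rule is a modelling convention, not an
  empirical claim; its metrics exist for contrast only.

## Problem sizes used by the shipped checks

The test suite and acceptance script use 200 randomized models for the
oracle sweep, 41×41 lattices for maps, and 2000 trials per class per
precision level (42,000 inferences for the full sweep). Everything is
vectorized over trials; the entire suite runs in a few seconds.
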