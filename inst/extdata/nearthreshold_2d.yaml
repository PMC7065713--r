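# Near-threshold 2D discrimination space: two content classes at unit
# distance from the absent class. Used for posterior / confidence /
# surprise maps on the default [-1, 3]^2 lattice.
n_states: 2
feature_dim: 2
means:
- [0.5, 0.5]
- [1.5, 0.5]
- [0.5, 1.5]
covariance:
- [1.0, 0.0]
- [0.0, 1.0]
prior_presence: 0.5
prior_content_given_presence: [0.5, 0.5]
state_labels: [absent, w1, w2]
flat_prior: [0.3333333333333333, 0.3333333333333333, 0.3333333333333333]
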