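# Widely separated 2D discrimination space: content means several standard
# deviations from the absent mean near the origin region. Used for the
# flat-SDT contrast and as the stimulus set of the masking sweep; map
# lattice [0, 10]^2.
n_states: 2
feature_dim: 2
means:
- [3.5, 3.5]
- [7.0, 3.5]
- [3.5, 7.0]
covariance:
- [1.0, 0.0]
- [0.0, 1.0]
prior_presence: 0.5
prior_content_given_presence: [0.5, 0.5]
state_labels: [absent, w1, w2]
flat_prior: [0.3333333333333333, 0.3333333333333333, 0.3333333333333333]
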