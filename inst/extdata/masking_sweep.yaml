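# Masking-sweep parameter set: the widely separated stimulus classes plus
# the default precision grid. Precision multiplies the inverse covariance
# (effective covariance Sigma / lambda) for both stimulus generation and
# observer inference; ascending precision models ascending stimulus-onset
# asynchrony. The grid spans near-chance to near-ceiling seen rates.
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
precisions: [0.02, 0.05, 0.1, 0.2, 0.5, 1.0, 2.0]
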