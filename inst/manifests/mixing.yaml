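# Mixed training-set study: assay-format-dependent readout noise in the
# public-like domain; compares compilation approaches a/b/c under random and
# cluster nested CV.
name: mixing
spec:
  formatNoiseSD: 1.5
stages: [mixing]
algorithm: xgb
provider: estate_like
schemes: [random, cluster]
assay_format: cell_based
seed: 1
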