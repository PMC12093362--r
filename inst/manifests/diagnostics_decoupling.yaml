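# High chemical-space similarity with an inverted label rule in the
# proprietary-like domain: nearest-neighbor similarity is high while cross
# domain performance collapses, showing that chemical-space proximity alone
# does not guarantee model transferability.
name: diagnostics-decoupling
spec:
  scaffoldOverlap: 0.9
  flipLabelRule: true
stages: [within, cross, chemspace]
algorithm: xgb
provider: estate_like
schemes: [random]
seed: 1
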