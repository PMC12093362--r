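# Over-prediction bias study: opposite class skews, moderate overlap.
name: bias
spec:
  scaffoldOverlap: 0.5
  activeFractionPublic: 0.8
  activeFractionProprietary: 0.2
stages: [within, cross]
algorithm: xgb
provider: estate_like
schemes: [random]
seed: 1
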