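# Cross-domain transfer study: low scaffold overlap between the domains.
name: domain-shift
spec:
  scaffoldOverlap: 0.1
  identityOverlap: 0.05
stages: [within, cross, chemspace]
algorithm: xgb
provider: estate_like
schemes: [random]
seed: 1
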