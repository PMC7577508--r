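# Birth-death model: one species produced at rate k, degraded at rate gamma.
# gamma is fixed; k is inferred with a log-uniform prior over four decades.
schema_version: 1
species: [X]
x0: [0]
reactions:
  - reactants: {}
    products: {X: 1}
    rate: k
  - reactants: {X: 1}
    products: {}
    rate: gamma
parameters:
  - {name: k, kind: log-uniform, lower: 0.01, upper: 100}
  - {name: gamma, fixed: 0.1}
observation:
  channels:
    - {species: {X: 1}, sigma: 1}
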