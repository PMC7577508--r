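# Stochastic Lotka-Volterra predator-prey model: prey birth X -> 2X (c1),
# predation X + Y -> 2Y (c2), predator death Y -> 0 (c3).  Both species are
# observed.  Initial state and rate defaults are package choices drawn from
# the standard stochastic-kinetics inference literature.
schema_version: 1
species: [prey, predator]
x0: [50, 100]
reactions:
  - reactants: {prey: 1}
    products: {prey: 2}
    rate: c1
  - reactants: {prey: 1, predator: 1}
    products: {predator: 2}
    rate: c2
  - reactants: {predator: 1}
    products: {}
    rate: c3
parameters:
  - {name: c1, kind: log-uniform, lower: 0.1, upper: 10}
  - {name: c2, kind: log-uniform, lower: 0.0005, upper: 0.05}
  - {name: c3, kind: log-uniform, lower: 0.06, upper: 6}
observation:
  channels:
    - {species: {prey: 1}, sigma: 2}
    - {species: {predator: 1}, sigma: 2}
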