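# Two-state gene transcription model with staged nascent-RNA elongation.
# The gene switches on/off (k_on, k_off); while on, transcription initiates
# at rate k_r.  Each nascent RNA traverses 8 sequential stages at per-stage
# rate lambda and is then released to an unobserved sink, so one
# transcription event dwells in the observable region for an
# Erlang(8, lambda) time with mean 8/lambda.  Released RNA is cleared from
# the sink at the same rate, keeping the state bounded; it never enters
# the read-out.  The single observed channel is the total nascent RNA
# (sum over the 8 stages).  Prior bounds are package defaults spanning
# decades around plausible per-minute rates.
schema_version: 1
species: [G_off, G_on, RNA_1, RNA_2, RNA_3, RNA_4, RNA_5, RNA_6, RNA_7, RNA_8, RNA_rel]
x0: [1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0]
reactions:
  - reactants: {G_off: 1}
    products: {G_on: 1}
    rate: k_on
  - reactants: {G_on: 1}
    products: {G_off: 1}
    rate: k_off
  - reactants: {G_on: 1}
    products: {G_on: 1, RNA_1: 1}
    rate: k_r
  - reactants: {RNA_1: 1}
    products: {RNA_2: 1}
    rate: lambda
  - reactants: {RNA_2: 1}
    products: {RNA_3: 1}
    rate: lambda
  - reactants: {RNA_3: 1}
    products: {RNA_4: 1}
    rate: lambda
  - reactants: {RNA_4: 1}
    products: {RNA_5: 1}
    rate: lambda
  - reactants: {RNA_5: 1}
    products: {RNA_6: 1}
    rate: lambda
  - reactants: {RNA_6: 1}
    products: {RNA_7: 1}
    rate: lambda
  - reactants: {RNA_7: 1}
    products: {RNA_8: 1}
    rate: lambda
  - reactants: {RNA_8: 1}
    products: {RNA_rel: 1}
    rate: lambda
  - reactants: {RNA_rel: 1}
    products: {}
    rate: lambda
parameters:
  - {name: k_on, kind: log-uniform, lower: 0.001, upper: 1}
  - {name: k_off, kind: log-uniform, lower: 0.001, upper: 1}
  - {name: k_r, kind: log-uniform, lower: 0.1, upper: 10}
  - {name: lambda, kind: log-uniform, lower: 0.4, upper: 40}
observation:
  channels:
    - species: {RNA_1: 1, RNA_2: 1, RNA_3: 1, RNA_4: 1, RNA_5: 1, RNA_6: 1, RNA_7: 1, RNA_8: 1}
      sigma: 1
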