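# Default run configuration for the tetramer-dosage model.
model:
  tau: 0.1             # penetrance threshold on the statistic
  'n': 64              # tetramers per cell (8 x 8 grid); quoted: bare n is a YAML boolean
  k: 4                 # mutant subunits required for a leaky tetramer
  statistic: p_any_leaky
oe_weight: 8           # overexpression transgene weight (baseline units)
knockdown_fraction: 0.25   # retained mutant expression after RNAi
seed: 1
n_cells: 10000
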