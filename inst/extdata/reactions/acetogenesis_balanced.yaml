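# Element- and charge-balanced homoacetogenic overall reaction:
# 2 CO2 + 4 H2 -> CH3COO- + H+ + 2 H2O
name: acetogenesis (balanced)
species:
  - species: CO2
    coefficient: -2
    formula: CO2
    dgf_kj_mol: -394
  - species: H2
    coefficient: -4
    formula: H2
    dgf_kj_mol: 0
  - species: acetate
    coefficient: 1
    formula: C2H3O2
    charge: -1
    dgf_kj_mol: -370.3
  - species: H+
    coefficient: 1
    formula: H
    charge: 1
    dgf_kj_mol: 0
  - species: H2O
    coefficient: 2
    formula: H2O
    dgf_kj_mol: -237.13
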