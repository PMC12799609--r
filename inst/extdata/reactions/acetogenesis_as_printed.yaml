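# CO2 reduction to acetate, with the stoichiometric bookkeeping exactly as
# reported (one CO2, four H2, no water): carbon/hydrogen-imbalanced, kept to
# reproduce the reported +23.7 kJ/mol; see acetogenesis_balanced.yaml for the
# element-balanced form.
name: acetogenesis (as printed)
species:
  - species: CO2
    coefficient: -1
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
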