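# PHB monomer (3-hydroxybutyrate) condensation from two acetate
name: PHB monomer from acetate
species:
  - species: acetate
    coefficient: -2
    formula: C2H3O2
    charge: -1
    dgf_kj_mol: -370.3
  - species: 3-HB
    coefficient: 1
    formula: C4H7O3
    charge: -1
    dgf_kj_mol: -361.84
  - species: H2O
    coefficient: 1
    formula: H2O
    dgf_kj_mol: -237.13
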