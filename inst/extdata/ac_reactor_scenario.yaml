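# Carbon-ledger scenario for the anaerobic-sludge (AC) gas-fermentation
# reactor: reported per-stream values; the residual metabolites term is left
# implicit so the balance reports it.
streams:
  - name: sodium bicarbonate
    role: input
    category: substrate
    conc_g_per_l: 6
    formula: NaHCO3
  - name: inoculum biomass
    role: input
    category: biomass
    carbon_gc_per_l: 0.45
  - name: dissolved CO2 in
    role: input
    category: dissolved_gas
    carbon_mgc_per_l: 48
  - name: acetic acid
    role: output
    category: vfa
    carbon_gc_per_l: 0.48
  - name: butyric acid
    role: output
    category: vfa
    carbon_gc_per_l: 0.324
  - name: dissolved CO2 out
    role: output
    category: dissolved_gas
    carbon_mgc_per_l: 25
  - name: biomass out
    role: output
    category: biomass
    carbon_gc_per_l: 0.3455
cod_delta_g_per_l: 0.54
vss_g_per_l: 10
vfa_total_g_per_l: 2.017
vfa_ratio_acetic_to_butyric: 1.5
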