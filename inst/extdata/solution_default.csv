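# Default culture-solution composition, expressed as molar ratios to Ca.
# These are RECONSTRUCTED defaults (back-computed from published calcite
# ratio / partition-coefficient pairs: Sr/Ca 3.7 mmol/mol with D_Sr 0.42,
# Se/Ca 0.047 mmol/mol with D_Se 0.048), not a measured medium composition.
# Override with your own solution table (element, ratio_to_ca_mmol_per_mol)
# or a molarity table (element, molarity_mol_per_l).
element,ratio_to_ca_mmol_per_mol
Sr,8.81
Se,0.98
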