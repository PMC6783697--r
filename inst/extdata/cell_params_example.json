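{
  "_comment": "Example cell-parameter configuration. Units: volumes um^3, masses Da, density g/L. The two ribosome masses are literature-derived approximations for the yeast 80S particle (proteins ~1.4 MDa; full particle incl. rRNA ~3.3 MDa); they are synthetic defaults for examples, not values quoted from any single measurement.",
  "cell_volume": 42,
  "cytoplasm_fraction": 0.65,
  "n_trna_cell": 3000000,
  "trna_nucleotides": 75,
  "nucleotide_mass": 340,
  "ribosome_protein_mass": 1400000,
  "ribosome_total_mass": 3300000,
  "target_density": 90,
  "target_rib_cyt": 0.2229
}
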