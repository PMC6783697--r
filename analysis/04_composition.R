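#!/usr/bin/env Rscript
# Build the one-ribosome simulation-cell composition: minimal scaling
# factor s such that the rounded copy numbers of the top-by-mass protein
# types meet the density and rib/cyt targets within 2%.
# Writes results/composition/.

library(cytocell)

tables <- read_tables("results/data/abundances.tsv",
                      "results/data/datasets.tsv",
                      "results/data/annotations.tsv")
p <- jsonlite::read_json("results/params.json", simplifyVector = TRUE)
params <- cell_parameters(n_ribosomes_cell = p$n_ribosomes_cell,
                          ribosome_protein_mass = p$ribosome_protein_mass,
                          ribosome_total_mass = p$ribosome_total_mass)
targets <- list(rib_cyt = p$derived_target_rib_cyt,
                density = p$derived_target_density)

parts <- filter_cytoplasmic(tables$annotations, tables$abundance)
spec <- suppressWarnings(
  build_composition(parts$cytoplasmic$abundance,
                    parts$cytoplasmic$annotations,
                    params, builder_config(),
                    datasets = p$selected_datasets,
                    targets = targets, top_n = 200))
write_composition(spec, "results/composition")
print(spec)

# how stable is the molecule count across the feasible range of s?
if (spec$feasible) {
  ranked <- suppressWarnings(rank_by_mass(parts$cytoplasmic$abundance,
                                          parts$cytoplasmic$annotations,
                                          datasets = p$selected_datasets))
  ranked <- head(ranked, 200)
  ranked$per_box_abundance <- per_ribosome_abundance(ranked$abundance,
                                                     params$n_ribosomes_cell)
  fixed <- list(ribosome_protein_mass = params$ribosome_protein_mass,
                ribosome_total_mass = params$ribosome_total_mass,
                trna_mass_total = spec$n_trna * params$trna_mass)
  box_vol <- params$cytoplasm_volume / params$n_ribosomes_cell
  cfg <- builder_config()
  n_mol <- c()
  for (s in seq(spec$scaling_factor, cfg$s_max, by = 0.05)) {
    fk <- feasible_K(ranked$per_box_abundance, ranked$molecular_mass_da, s,
                     targets, cfg, fixed, box_vol)
    if (!is.na(fk$K)) n_mol <- c(n_mol, sum(fk$copies[seq_len(fk$K)]))
  }
  message(sprintf("Across %d feasible scaling factors, total molecules span %d-%d (%.0f%% variation)",
                  length(n_mol), min(n_mol), max(n_mol),
                  100 * (max(n_mol) - min(n_mol)) / min(n_mol)))
}
message("Composition written to results/composition/")
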