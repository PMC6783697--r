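#!/usr/bin/env Rscript
# Physical parameters of the simulation cell: ribosome count from the
# pooled median of ribosomal-protein abundances in the absolute-scale MS
# datasets, cytoplasm volume, box edge and tRNA share. Box targets (density
# and rib/cyt) are derived from the same proteome so that the composition
# step is self-consistent. Writes results/params.json.

library(cytocell)

tables <- read_tables("results/data/abundances.tsv",
                      "results/data/datasets.tsv",
                      "results/data/annotations.tsv")
meta <- tables$datasets
selected <- meta$dataset_id[meta$technique == "MS_absolute"]
rib_ids <- tables$annotations$protein_id[tables$annotations$is_ribosomal]
pooled <- as.vector(tables$abundance[rib_ids, selected])
n_rib <- median(pooled, na.rm = TRUE)

# ribosome masses from the packaged literature-derived example config
cfg <- jsonlite::read_json(system.file("extdata", "cell_params_example.json",
                                       package = "cytocell"),
                           simplifyVector = TRUE)
params <- cell_parameters(n_ribosomes_cell = n_rib,
                          ribosome_protein_mass = cfg$ribosome_protein_mass,
                          ribosome_total_mass = cfg$ribosome_total_mass)

parts <- filter_cytoplasmic(tables$annotations, tables$abundance)
ranked <- suppressWarnings(rank_by_mass(parts$cytoplasmic$abundance,
                                        parts$cytoplasmic$annotations,
                                        datasets = selected))
targets <- derive_targets(sum(ranked$mass_da), params)

message(sprintf("Ribosomes per cell (pooled median, %d MS datasets): %s",
                length(selected), format(round(n_rib), big.mark = ",")))
message(sprintf("Cytoplasm volume: %.1f um^3; box edge %.1f angstrom; %d tRNAs per box",
                params$cytoplasm_volume,
                box_length(params$cytoplasm_volume, n_rib),
                trna_count_box(params$n_trna_cell, n_rib)))
message(sprintf("Derived targets: density %.1f g/L, rib/cyt %.4f",
                targets$density, targets$rib_cyt))
message(sprintf("Top 200 of %d ranked cytoplasmic proteins carry %.0f%% of the protein mass",
                nrow(ranked),
                100 * cumulative_mass_fraction(ranked, min(200, nrow(ranked)))))

out <- c(unclass(params),
         list(selected_datasets = selected,
              derived_target_density = targets$density,
              derived_target_rib_cyt = targets$rib_cyt))
dir.create("results", showWarnings = FALSE)
jsonlite::write_json(out, "results/params.json", auto_unbox = TRUE,
                     digits = NA, na = "null")
message("Parameters written to results/params.json")
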