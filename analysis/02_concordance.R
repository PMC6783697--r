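#!/usr/bin/env Rscript
# Cross-dataset concordance of the compendium written by 01_simulate.R:
# compartment filtering, CV structure, per-dataset ribosome estimates,
# pairwise Welch / Mann-Whitney matrices with Bonferroni and BH control,
# ontology-profile similarity and GFP-vs-MS median divergence.
# Writes results/concordance/.

library(cytocell)

tables <- read_tables("results/data/abundances.tsv",
                      "results/data/datasets.tsv",
                      "results/data/annotations.tsv")
conc <- concordance_report(tables, "results/concordance",
                           alpha = 0.05, top_n = 200)

cv <- conc$cv_summary
message("CV summary:")
for (i in seq_len(nrow(cv))) {
  message(sprintf("  %-35s %6.1f%%", cv$quantity[i], cv$cv_percent[i]))
}

est <- conc$ribosome_estimates
meta <- tables$datasets
grp <- ifelse(meta$technique %in% c("MS_absolute", "MS_normalized"),
              "MS", meta$technique)[match(est$dataset_id, meta$dataset_id)]
for (g in unique(grp)) {
  v <- est$value[grp == g & est$available]
  message(sprintf("Mean per-dataset ribosome estimate, %s: %s copies/cell",
                  g, format(round(mean(v)), big.mark = ",")))
}

pw <- conc$pairwise_welch
message(sprintf("Pairwise Welch tests: %d pairs, %d Bonferroni-significant, %d BH-significant",
                nrow(pw), sum(pw$bonferroni_sig), sum(pw$bh_sig)))
md <- conc$median_divergence
if (!is.null(md)) {
  message(sprintf("GFP vs MS medians differing by >25%%: %.0f%% of %s proteins, %.0f%% of %s proteins",
                  100 * md$fraction_divergent[1], md$protein_class[1],
                  100 * md$fraction_divergent[2], md$protein_class[2]))
}
message("Artifacts written to results/concordance/")
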