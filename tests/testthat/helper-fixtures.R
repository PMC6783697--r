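# Fixtures are built in code at test time; nothing is stored on disk.

# Write a tiny three-table compendium to a temp dir and return the paths.
write_tiny_tables <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                              abundances = NULL, annotations = NULL,
                              datasets = NULL) {
  if (is.null(abundances)) {
    abundances <- data.frame(
      protein_id = c("YAL001C", "YBL002W", "YCL003C"),
      D1 = c(100, 200, 300),
      D2 = c(110, NA, 290),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(datasets)) {
    datasets <- data.frame(
      dataset_id = c("D1", "D2"),
      technique = c("MS_absolute", "GFP"),
      medium = "SD", phase = "exponential", units = "molecules_per_cell",
      stringsAsFactors = FALSE
    )
  }
  if (is.null(annotations)) {
    annotations <- data.frame(
      protein_id = c("YAL001C", "YBL002W", "YCL003C"),
      molecular_mass_da = c(50000, 30000, 20000),
      compartments = c("cytoplasm", "cytoplasm", "nucleus"),
      is_ribosomal = c(0L, 0L, 0L),
      go_classes = c("glycolysis", "glycolysis;protein folding", ""),
      stringsAsFactors = FALSE
    )
  }
  paths <- list(
    abundances = file.path(dir, "abundances.tsv"),
    datasets = file.path(dir, "datasets.tsv"),
    annotations = file.path(dir, "annotations.tsv")
  )
  write.table(abundances, paths$abundances, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  write.table(datasets, paths$datasets, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(annotations, paths$annotations, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}

# Small unbiased synthetic parameter set used across tests.
small_synth <- function(seed, n_proteins = 120, n_ribosomal = 20,
                        cv = 0.3, missing_rate = 0.1,
                        datasets = ms_panel(5), bias_rib = 1,
                        bias_nonrib = 1, true_ribosome_count = 150000) {
  synth_params(
    n_proteins = n_proteins, n_ribosomal = n_ribosomal,
    datasets = datasets,
    true_ribosome_count = true_ribosome_count,
    technique_bias = list(
      MS_absolute = list(nonribosomal = bias_nonrib, ribosomal = bias_rib),
      MS_normalized = list(nonribosomal = bias_nonrib, ribosomal = bias_rib),
      GFP = list(nonribosomal = bias_nonrib, ribosomal = bias_rib),
      TAP = list(nonribosomal = bias_nonrib, ribosomal = bias_rib)),
    technique_cv = c(MS_absolute = cv, MS_normalized = cv,
                     GFP = cv, TAP = cv),
    missing_rate = missing_rate,
    seed = seed
  )
}

ms_panel <- function(n, technique = "MS_absolute", prefix = "MS") {
  data.frame(dataset_id = paste0(prefix, seq_len(n)),
             technique = technique, medium = "SD", phase = "exponential",
             units = "molecules_per_cell", stringsAsFactors = FALSE)
}

# Panel of n_ms MS plus n_gfp GFP datasets.
mixed_panel <- function(n_ms = 5, n_gfp = 5) {
  rbind(ms_panel(n_ms), ms_panel(n_gfp, technique = "GFP", prefix = "GF"))
}
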