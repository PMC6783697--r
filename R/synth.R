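# Synthetic proteomics generator. Emulates the structure of a unified
# multi-study yeast protein-abundance compendium -- log-normally distributed
# per-cell copy numbers, several measurement techniques with
# technique-specific multiplicative bias and dispersion (GFP tagging
# under-reports ribosomal proteins and is noisier than mass spectrometry),
# a fixed true ribosome count driving 1:1 ribosomal-protein abundances, and
# missing entries -- so every downstream stage can be tested against known
# ground truth.

#' Default synthetic dataset panel
#'
#' Twenty-one datasets mirroring the make-up of the large published yeast
#' compendia: 5 absolute-scale mass-spectrometry datasets, 6 normalized MS
#' datasets, 9 GFP-microscopy datasets and 1 TAP-immunoblot dataset, with
#' varied growth media and phases.
#'
#' @return data.frame: dataset_id, technique, medium, phase, units.
#' @export
default_dataset_panel <- function() {
  ids <- c(paste0("MSA", 1:5), paste0("MSN", 1:6), paste0("GFP", 1:9), "TAP1")
  tech <- c(rep("MS_absolute", 5), rep("MS_normalized", 6),
            rep("GFP", 9), rep("TAP", 1))
  media <- rep(c("SD", "YPD", "SC"), length.out = length(ids))
  phase <- rep(c("exponential", "stationary"), length.out = length(ids))
  data.frame(dataset_id = ids, technique = tech, medium = media,
             phase = phase, units = "molecules_per_cell",
             stringsAsFactors = FALSE)
}

#' Parameters of the synthetic proteome generator
#'
#' Defaults describe a compendium-sized proteome: 5,391 proteins of which 79
#' are ribosomal, measured by the 21-dataset panel of
#' [default_dataset_panel()], with 150,000 ribosomes per cell (mid-range of
#' classical estimates), log-normal copy numbers (median ~3,000 copies,
#' sdlog 2), GFP-specific under-reporting of ribosomal proteins and higher
#' GFP dispersion, normalization-induced shrinkage in normalized MS data,
#' and 10 percent missing entries. About 70 percent of non-ribosomal
#' proteins are assigned a non-cytoplasmic compartment, matching the share
#' of a full proteome that compartment filtering removes.
#'
#' Multiplicative noise is log-normal with unit median and a log-sd chosen
#' so its coefficient of variation equals `technique_cv` for the dataset's
#' technique; biases are multiplicative and separate for ribosomal vs
#' non-ribosomal proteins.
#'
#' @param n_proteins total proteins.
#' @param n_ribosomal how many are ribosomal (1:1 per ribosome).
#' @param datasets dataset panel data.frame (dataset_id, technique, medium,
#'   phase, units).
#' @param true_ribosome_count ground-truth ribosomes per cell.
#' @param abundance_logmean,abundance_logsd natural-log location and scale of
#'   non-ribosomal per-cell copy numbers.
#' @param technique_bias named list per technique, each a list with
#'   `nonribosomal` and `ribosomal` multiplicative factors (> 0).
#' @param technique_cv named numeric vector of per-technique noise CVs (>= 0).
#' @param missing_rate fraction of matrix cells masked missing, in [0, 1).
#' @param mass_range c(min, max) molecular mass in Da.
#' @param noncyto_fraction fraction of non-ribosomal proteins assigned an
#'   excluded (non-cytoplasmic) compartment.
#' @param seed integer RNG seed; same seed, same params, identical output.
#' @return validated list of class `synth_params`.
#' @export
synth_params <- function(n_proteins = 5391,
                         n_ribosomal = 79,
                         datasets = default_dataset_panel(),
                         true_ribosome_count = 150000,
                         abundance_logmean = log(3000),
                         abundance_logsd = 2,
                         technique_bias = list(
                           MS_absolute = list(nonribosomal = 1, ribosomal = 1),
                           MS_normalized = list(nonribosomal = 0.7, ribosomal = 0.24),
                           GFP = list(nonribosomal = 0.7, ribosomal = 0.4),
                           TAP = list(nonribosomal = 1, ribosomal = 1)),
                         technique_cv = c(MS_absolute = 0.69,
                                          MS_normalized = 0.69,
                                          GFP = 1.03,
                                          TAP = 0.8),
                         missing_rate = 0.1,
                         mass_range = c(10000, 150000),
                         noncyto_fraction = 0.7,
                         seed = 1L) {
  .check_positive(n_proteins, "n_proteins")
  .check_positive(n_ribosomal, "n_ribosomal")
  if (n_ribosomal >= n_proteins) {
    stop("'n_ribosomal' must be smaller than 'n_proteins'", call. = FALSE)
  }
  stopifnot(is.data.frame(datasets))
  needed <- c("dataset_id", "technique")
  if (!all(needed %in% names(datasets))) {
    stop("'datasets' must have columns dataset_id and technique", call. = FALSE)
  }
  bad <- setdiff(datasets$technique, TECHNIQUES)
  if (length(bad)) {
    stop("'datasets': unknown technique ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  .check_positive(true_ribosome_count, "true_ribosome_count")
  .check_positive(abundance_logsd, "abundance_logsd")
  for (tech in unique(datasets$technique)) {
    b <- technique_bias[[tech]]
    if (is.null(b) || is.null(b$nonribosomal) || is.null(b$ribosomal) ||
        b$nonribosomal <= 0 || b$ribosomal <= 0) {
      stop("'technique_bias' must give positive nonribosomal and ribosomal ",
           "factors for technique ", tech, call. = FALSE)
    }
    if (is.na(technique_cv[tech]) || technique_cv[tech] < 0) {
      stop("'technique_cv' must be >= 0 for technique ", tech, call. = FALSE)
    }
  }
  .check_fraction(missing_rate, "missing_rate", open_right = TRUE)
  if (length(mass_range) != 2L || any(mass_range <= 0) ||
      mass_range[1] > mass_range[2]) {
    stop("'mass_range' must be c(min, max) with 0 < min <= max", call. = FALSE)
  }
  .check_fraction(noncyto_fraction, "noncyto_fraction")
  if (length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  structure(list(
    n_proteins = as.integer(n_proteins),
    n_ribosomal = as.integer(n_ribosomal),
    datasets = datasets,
    true_ribosome_count = true_ribosome_count,
    abundance_logmean = abundance_logmean,
    abundance_logsd = abundance_logsd,
    technique_bias = technique_bias,
    technique_cv = technique_cv,
    missing_rate = missing_rate,
    mass_range = mass_range,
    noncyto_fraction = noncyto_fraction,
    seed = as.integer(seed)
  ), class = "synth_params")
}

# log-normal multiplicative noise with unit median and CV = cv
.noise_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = 0, sd = sdlog))
}

#' Generate a synthetic proteomics compendium with known truth
#'
#' Draws non-ribosomal true per-cell copy numbers from a log-normal, fixes
#' every ribosomal protein's true abundance at the true ribosome count (1:1
#' stoichiometry), applies per-technique multiplicative bias and log-normal
#' noise per dataset, masks entries missing completely at random, draws
#' molecular masses uniformly, and assigns compartments such that a
#' configurable fraction of non-ribosomal proteins is non-cytoplasmic.
#' Ribosomal proteins are annotated to the ribosome compartment and named
#' from the packaged 80S protein list when 79 are requested.
#'
#' The generator is fully deterministic given `params$seed` and leaves the
#' caller's RNG state untouched.
#'
#' @param params a [synth_params()] object.
#' @return list with `abundance` (matrix, NA = missing), `annotations`
#'   (data.frame as from [read_tables()]), `datasets` (the panel), and
#'   `truth` (list: true_ribosome_count, true_abundance, dataset_bias,
#'   seed).
#' @export
generate_dataset <- function(params) {
  if (!inherits(params, "synth_params")) {
    params <- do.call(synth_params, params)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(params$seed)

  n <- params$n_proteins
  n_rib <- params$n_ribosomal
  n_non <- n - n_rib

  rib_ids <- if (n_rib == 79L) {
    ribosomal_protein_ids()
  } else {
    sprintf("RP%03d", seq_len(n_rib))
  }
  non_ids <- sprintf("P%04d", seq_len(n_non))
  ids <- c(rib_ids, non_ids)

  true_ab <- c(rep(params$true_ribosome_count, n_rib),
               stats::rlnorm(n_non, params$abundance_logmean,
                             params$abundance_logsd))
  names(true_ab) <- ids
  is_rib <- c(rep(TRUE, n_rib), rep(FALSE, n_non))

  ds <- params$datasets
  mat <- matrix(NA_real_, nrow = n, ncol = nrow(ds),
                dimnames = list(ids, ds$dataset_id))
  bias_tab <- data.frame(dataset_id = ds$dataset_id,
                         technique = ds$technique,
                         bias_nonribosomal = NA_real_,
                         bias_ribosomal = NA_real_,
                         cv = NA_real_,
                         stringsAsFactors = FALSE)
  for (j in seq_len(nrow(ds))) {
    tech <- ds$technique[j]
    b <- params$technique_bias[[tech]]
    cv <- unname(params$technique_cv[tech])
    bias <- ifelse(is_rib, b$ribosomal, b$nonribosomal)
    mat[, j] <- true_ab * bias * .noise_factors(n, cv)
    bias_tab$bias_nonribosomal[j] <- b$nonribosomal
    bias_tab$bias_ribosomal[j] <- b$ribosomal
    bias_tab$cv[j] <- cv
  }
  if (params$missing_rate > 0) {
    mask <- stats::runif(length(mat)) < params$missing_rate
    mat[mask] <- NA_real_
  }

  masses <- stats::runif(n, params$mass_range[1], params$mass_range[2])
  excl_pool <- setdiff(default_excluded_compartments(), "ribosome")
  noncyto <- stats::runif(n_non) < params$noncyto_fraction
  non_comp <- ifelse(noncyto, sample(excl_pool, n_non, replace = TRUE),
                     "cytoplasm")
  go_pool <- c("translation", "glycolysis", "protein folding", "proteolysis",
               "oxidation-reduction", "transport", "amino-acid biosynthesis",
               "nucleotide metabolism", "cell cycle", "signaling",
               "stress response", "lipid metabolism")
  go <- lapply(seq_len(n), function(i) {
    if (is_rib[i]) "translation"
    else sample(go_pool, sample(1:3, 1))
  })

  annotations <- data.frame(
    protein_id = ids,
    molecular_mass_da = masses,
    is_ribosomal = is_rib,
    stringsAsFactors = FALSE
  )
  annotations$compartments <- c(rep(list(c("ribosome", "cytoplasm")), n_rib),
                                as.list(non_comp))
  annotations$go_classes <- go

  list(
    abundance = mat,
    annotations = annotations,
    datasets = ds,
    truth = list(
      true_ribosome_count = params$true_ribosome_count,
      true_abundance = true_ab,
      dataset_bias = bias_tab,
      seed = params$seed
    )
  )
}

#' Write a synthetic compendium to disk in the package TSV dialect
#'
#' Emits `abundances.tsv`, `datasets.tsv`, `annotations.tsv` (readable back
#' with [read_tables()]) and `truth.json` under `dir`.
#'
#' @param synth output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_tables <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ab <- data.frame(protein_id = rownames(synth$abundance),
                   synth$abundance, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(ab, file.path(dir, "abundances.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(synth$datasets, file.path(dir, "datasets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- synth$annotations
  flat <- data.frame(
    protein_id = ann$protein_id,
    molecular_mass_da = ann$molecular_mass_da,
    compartments = vapply(ann$compartments, paste, "", collapse = ";"),
    is_ribosomal = as.integer(ann$is_ribosomal),
    go_classes = vapply(ann$go_classes, paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.table(flat, file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- synth$truth
  jsonlite::write_json(
    list(true_ribosome_count = truth$true_ribosome_count,
         seed = truth$seed,
         dataset_bias = truth$dataset_bias,
         true_abundance = as.list(truth$true_abundance)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
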