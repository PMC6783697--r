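# Pipeline driver and run report. The numbered scripts under analysis/ are
# thin wrappers over these functions; run_pipeline() chains
# synth -> ingest -> concordance -> cell parameters -> composition and
# leaves every artifact as TSV/JSON on disk, render_report() summarises the
# artifacts without recomputing anything.

#' Full concordance analysis of an ingested compendium
#'
#' Computes and writes the concordance artifacts: per-group CV summary,
#' per-dataset ribosome estimates, pairwise Welch and Mann-Whitney test
#' matrices over ribosomal-protein abundances (Bonferroni and BH control),
#' ontology-profile Pearson and Jaccard similarity over each dataset's
#' top-N-by-mass proteins, and GFP-vs-MS median-divergence fractions.
#'
#' @param tables list as returned by [read_tables()] or [generate_dataset()]
#'   (`abundance`, `datasets`, `annotations`).
#' @param out_dir output directory for the TSV artifacts.
#' @param alpha family-wise alpha for the pairwise tests.
#' @param top_n top-by-mass list size for the ontology profiles.
#' @return list of the computed tables, invisibly (artifacts on disk).
#' @export
concordance_report <- function(tables, out_dir, alpha = 0.05, top_n = 200) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ab <- tables$abundance
  ann <- tables$annotations
  meta <- tables$datasets
  rib_ids <- ann$protein_id[ann$is_ribosomal]
  parts <- filter_cytoplasmic(ann, ab)
  cyto_ab <- parts$cytoplasmic$abundance

  # per-protein CV across datasets, averaged within compartment class
  protein_cv <- function(m) {
    cvs <- apply(m, 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L || mean(v) == 0) NA_real_ else cv_percent(v)
    })
    mean(cvs, na.rm = TRUE)
  }
  grp_cv <- group_ribosomal_cv(ab, rib_ids, meta)
  cv_summary <- data.frame(
    quantity = c("mean_per_protein_cv_cytoplasmic",
                 "mean_per_protein_cv_ribosomal",
                 paste0("mean_ribosomal_cv_", grp_cv$group)),
    cv_percent = c(protein_cv(cyto_ab),
                   protein_cv(ab[rib_ids, , drop = FALSE]),
                   grp_cv$mean_cv_percent),
    stringsAsFactors = FALSE
  )
  utils::write.table(cv_summary, file.path(out_dir, "cv_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  est <- ribosome_estimates(ab, rib_ids, statistic = "mean")
  utils::write.table(est, file.path(out_dir, "ribosome_estimates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  samples <- lapply(stats::setNames(colnames(ab), colnames(ab)), function(d) {
    v <- ab[rib_ids, d]
    v[!is.na(v)]
  })
  pw_welch <- pairwise_matrix(samples, test = "welch", alpha = alpha)
  pw_mwu <- pairwise_matrix(samples, test = "mannwhitney", alpha = alpha)
  utils::write.table(pw_welch, file.path(out_dir, "pairwise_welch.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pw_mwu, file.path(out_dir, "pairwise_mwu.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # ontology similarity over each dataset's top-N-by-mass cytoplasmic proteins
  cyto_ann <- parts$cytoplasmic$annotations
  go_map <- stats::setNames(cyto_ann$go_classes, cyto_ann$protein_id)
  top_lists <- lapply(stats::setNames(colnames(cyto_ab), colnames(cyto_ab)),
                      function(d) {
    r <- suppressWarnings(
      rank_by_mass(cyto_ab, cyto_ann, datasets = d, statistic = "value"))
    utils::head(r$protein_id, top_n)
  })
  profiles <- ontology_profiles(top_lists, go_map)
  ids <- names(profiles)
  pairs <- utils::combn(ids, 2L)
  onto <- data.frame(
    dataset_a = pairs[1L, ], dataset_b = pairs[2L, ],
    pearson_r = apply(pairs, 2L, function(p) {
      profile_pearson(profiles[[p[1]]], profiles[[p[2]]])
    }),
    jaccard = apply(pairs, 2L, function(p) {
      ontology_jaccard(names(profiles[[p[1]]]), names(profiles[[p[2]]]))
    }),
    stringsAsFactors = FALSE
  )
  utils::write.table(onto[, c("dataset_a", "dataset_b", "pearson_r")],
                     file.path(out_dir, "ontology_pearson.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(onto[, c("dataset_a", "dataset_b", "jaccard")],
                     file.path(out_dir, "ontology_jaccard.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # GFP-vs-MS per-protein median divergence, cytoplasmic and ribosomal
  gfp_cols <- meta$dataset_id[meta$technique == "GFP"]
  ms_cols <- meta$dataset_id[meta$technique %in% c("MS_absolute",
                                                   "MS_normalized")]
  div <- NULL
  if (length(gfp_cols) >= 1L && length(ms_cols) >= 1L) {
    row_median <- function(m, cols) {
      apply(m[, cols, drop = FALSE], 1L, function(v) {
        v <- v[!is.na(v)]
        if (!length(v)) NA_real_ else stats::median(v)
      })
    }
    d_cyto <- median_divergence(row_median(cyto_ab, gfp_cols),
                                row_median(cyto_ab, ms_cols))
    rib_ab <- ab[rib_ids, , drop = FALSE]
    d_rib <- median_divergence(row_median(rib_ab, gfp_cols),
                               row_median(rib_ab, ms_cols))
    div <- data.frame(
      protein_class = c("cytoplasmic", "ribosomal"),
      fraction_divergent = c(d_cyto$fraction, d_rib$fraction),
      n_proteins = c(d_cyto$n, d_rib$n),
      threshold = 0.25,
      stringsAsFactors = FALSE
    )
    utils::write.table(div, file.path(out_dir, "median_divergence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  invisible(list(cv_summary = cv_summary, ribosome_estimates = est,
                 pairwise_welch = pw_welch, pairwise_mwu = pw_mwu,
                 ontology = onto, median_divergence = div))
}

#' Run the whole pipeline from a single configuration
#'
#' Stages: optional synthetic-data generation, ingestion, concordance
#' analysis, cell-parameter assembly (with the ribosome count taken from the
#' pooled median of ribosomal-protein abundances in the selected datasets),
#' and composition building. Artifacts land under `config$out_dir`; each
#' stage logs what it consumed and produced, and a failure stops the run
#' with a stage-named error.
#'
#' Configuration keys (a list, or a path to a JSON file of the same shape):
#' `out_dir`; either `synth` (arguments for [synth_params()], empty list for
#' all defaults) or `input_dir` holding abundances/datasets/annotations.tsv;
#' `selected_datasets` (ids used for the ribosome estimate and the
#' composition abundance statistic; default: the MS_absolute datasets);
#' `alpha`; `top_n`; `cell` (arguments for [cell_parameters()];
#' `ribosome_protein_mass` and `ribosome_total_mass` are required);
#' `builder` (arguments for [builder_config()]); `derive_targets`
#' (logical: compute density and rib/cyt targets from the ingested data
#' instead of the configured targets).
#'
#' @param config list or JSON path.
#' @return list(tables, concordance, params, spec), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config: out_dir is required", call. = FALSE)
  if (is.null(config$synth) && is.null(config$input_dir)) {
    stop("config: either 'synth' or 'input_dir' is required", call. = FALSE)
  }
  if (is.null(config$cell)) {
    stop("config: 'cell' (cell_parameters arguments) is required", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  tables <- if (!is.null(config$synth)) {
    stage("synth", {
      sp <- do.call(synth_params, config$synth)
      syn <- generate_dataset(sp)
      write_synthetic_tables(syn, file.path(out_dir, "input"))
      message("synth: ", sp$n_proteins, " proteins x ", nrow(sp$datasets),
              " datasets (seed ", sp$seed, ")")
      syn
    })
  } else {
    stage("ingest", {
      tb <- read_tables(file.path(config$input_dir, "abundances.tsv"),
                        file.path(config$input_dir, "datasets.tsv"),
                        file.path(config$input_dir, "annotations.tsv"))
      message("ingest: ", nrow(tb$abundance), " proteins x ",
              ncol(tb$abundance), " datasets from ", config$input_dir)
      tb
    })
  }

  conc <- stage("concordance", {
    concordance_report(tables, file.path(out_dir, "concordance"),
                       alpha = config$alpha %||% 0.05,
                       top_n = config$top_n %||% 200)
  })

  res <- stage("cell-params", {
    meta <- tables$datasets
    selected <- config$selected_datasets %||%
      meta$dataset_id[meta$technique == "MS_absolute"]
    rib_ids <- tables$annotations$protein_id[tables$annotations$is_ribosomal]
    pooled <- as.vector(tables$abundance[rib_ids, selected, drop = FALSE])
    pooled <- pooled[!is.na(pooled)]
    if (length(pooled) < 2L) {
      stop("fewer than 2 ribosomal-protein observations in selected datasets")
    }
    n_rib <- stats::median(pooled)
    cell_args <- config$cell
    cell_args$n_ribosomes_cell <- cell_args$n_ribosomes_cell %||% n_rib
    params <- do.call(cell_parameters, cell_args)
    message("cell-params: ", round(params$n_ribosomes_cell),
            " ribosomes/cell (pooled median over ",
            length(pooled), " observations in ",
            length(selected), " datasets)")
    jsonlite::write_json(unclass(params), file.path(out_dir, "params.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    list(params = params, selected = selected)
  })

  spec <- stage("build", {
    parts <- filter_cytoplasmic(tables$annotations, tables$abundance)
    targets <- NULL
    if (isTRUE(config$derive_targets)) {
      ranked_all <- suppressWarnings(
        rank_by_mass(parts$cytoplasmic$abundance,
                     parts$cytoplasmic$annotations,
                     datasets = res$selected))
      targets <- derive_targets(sum(ranked_all$mass_da), res$params)
    }
    bc <- do.call(builder_config, config$builder %||% list())
    sp <- suppressWarnings(
      build_composition(parts$cytoplasmic$abundance,
                        parts$cytoplasmic$annotations,
                        res$params, bc, datasets = res$selected,
                        targets = targets,
                        top_n = config$top_n %||% 200))
    write_composition(sp, file.path(out_dir, "composition"))
    message("build: ", if (isTRUE(sp$feasible)) {
      sprintf("feasible at s = %.3f with %d types / %d molecules",
              sp$scaling_factor, sp$n_types, sp$n_molecules)
    } else sprintf("infeasible (binding: %s)", sp$binding_constraint))
    sp
  })

  invisible(list(tables = tables, concordance = conc,
                 params = res$params, spec = spec))
}

.read_if <- function(path, reader) if (file.exists(path)) reader(path) else NULL

#' Render a human-readable run report from on-disk artifacts
#'
#' Summarises what the pipeline wrote -- CV by technique group,
#' significance counts under Bonferroni and BH, ontology-similarity
#' ranges, ribosome estimates, and the final composition -- without
#' recomputing anything. Missing artifacts are listed as absent and the
#' report is still produced.
#'
#' @param artifacts_dir the pipeline output directory.
#' @param file output path for the markdown report (default
#'   `report.md` inside `artifacts_dir`).
#' @return the report lines, invisibly; the report is written to `file`.
#' @export
render_report <- function(artifacts_dir, file = file.path(artifacts_dir, "report.md")) {
  tsv <- function(p) utils::read.delim(p, stringsAsFactors = FALSE)
  lines <- c("# Simulation-cell pipeline report", "")
  absent <- character(0)

  cv <- .read_if(file.path(artifacts_dir, "concordance", "cv_summary.tsv"), tsv)
  if (is.null(cv)) absent <- c(absent, "cv_summary.tsv") else {
    lines <- c(lines, "## Coefficients of variation", "",
               sprintf("- %s: %.1f%%", cv$quantity, cv$cv_percent), "")
  }

  est <- .read_if(file.path(artifacts_dir, "concordance",
                            "ribosome_estimates.tsv"), tsv)
  if (is.null(est)) absent <- c(absent, "ribosome_estimates.tsv") else {
    avail <- est[est$available == TRUE | est$available == "TRUE", ]
    lines <- c(lines, "## Ribosome estimates (copies/cell)", "",
               sprintf("- %s: %.0f (n = %d)", avail$dataset_id, avail$value,
                       avail$n),
               if (nrow(est) > nrow(avail))
                 sprintf("- unavailable: %s",
                         paste(est$dataset_id[!(est$dataset_id %in%
                                                  avail$dataset_id)],
                               collapse = ", ")),
               "")
  }

  for (tst in c("welch", "mwu")) {
    pw <- .read_if(file.path(artifacts_dir, "concordance",
                             paste0("pairwise_", tst, ".tsv")), tsv)
    if (is.null(pw)) absent <- c(absent, paste0("pairwise_", tst, ".tsv"))
    else {
      lines <- c(lines, sprintf(
        "## Pairwise %s tests: %d pairs, %d Bonferroni-significant, %d BH-significant",
        tst, nrow(pw), sum(pw$bonferroni_sig), sum(pw$bh_sig)), "")
    }
  }

  op <- .read_if(file.path(artifacts_dir, "concordance",
                           "ontology_pearson.tsv"), tsv)
  oj <- .read_if(file.path(artifacts_dir, "concordance",
                           "ontology_jaccard.tsv"), tsv)
  if (is.null(op) || is.null(oj)) absent <- c(absent, "ontology similarity")
  else {
    lines <- c(lines, "## Ontology-profile similarity", "",
               sprintf("- Pearson r range: [%.3f, %.3f]",
                       min(op$pearson_r, na.rm = TRUE),
                       max(op$pearson_r, na.rm = TRUE)),
               sprintf("- Jaccard range: [%.3f, %.3f]",
                       min(oj$jaccard), max(oj$jaccard)), "")
  }

  md <- .read_if(file.path(artifacts_dir, "concordance",
                           "median_divergence.tsv"), tsv)
  if (!is.null(md)) {
    lines <- c(lines, "## GFP-vs-MS median divergence (>25%)", "",
               sprintf("- %s proteins: %.0f%% of %d divergent",
                       md$protein_class, 100 * md$fraction_divergent,
                       md$n_proteins), "")
  }

  sm <- .read_if(file.path(artifacts_dir, "composition", "summary.json"),
                 function(p) jsonlite::read_json(p, simplifyVector = TRUE))
  if (is.null(sm)) absent <- c(absent, "composition/summary.json") else {
    lines <- c(lines, "## Composition", "",
               if (isTRUE(sm$feasible)) c(
                 sprintf("- scaling factor: %.3f", sm$scaling_factor),
                 sprintf("- %d protein molecules of %d types, %s tRNAs, 1 ribosome",
                         sm$n_molecules, sm$n_types, format(sm$n_trna)),
                 sprintf("- box edge: %.1f angstrom", sm$box_length_angstrom),
                 sprintf("- density %.2f g/L (target %.2f); rib/cyt %.4f (target %.4f)",
                         sm$achieved_density_g_per_l, sm$target_density_g_per_l,
                         sm$achieved_rib_cyt, sm$target_rib_cyt))
               else sprintf("- infeasible (binding constraint: %s)",
                            sm$binding_constraint),
               "")
  }

  if (length(absent)) {
    lines <- c(lines, "## Absent artifacts", "",
               paste0("- ", absent), "")
  }
  writeLines(lines, file)
  invisible(lines)
}
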