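# Reading abundance / dataset-metadata / annotation tables, GO-slim
# compartment filtering, and ranking proteins by their per-cell mass
# contribution (molecular mass x abundance).
#
# TSV dialect: UTF-8, tab-delimited, header row, '.' decimal, empty cell =
# missing. abundances.tsv: protein_id then one column per dataset id.
# datasets.tsv: dataset_id, technique, medium, phase, units.
# annotations.tsv: protein_id, molecular_mass_da, compartments
# (semicolon-separated), is_ribosomal (0/1), go_classes (semicolon-separated,
# optional).

TECHNIQUES <- c("MS_absolute", "MS_normalized", "GFP", "TAP")

#' Default GO-slim compartments excluded from the cytoplasmic set
#'
#' Proteins annotated to any of these compartments are removed when defining
#' the cytoplasmic proteome: nucleus, cell wall, ribosome, mitochondrion,
#' endoplasmic reticulum and vacuole.
#'
#' @return character vector of compartment labels.
#' @export
default_excluded_compartments <- function() {
  c("nucleus", "cell wall", "ribosome", "mitochondrion",
    "endoplasmic reticulum", "vacuole")
}

#' The packaged ribosomal-protein gene list
#'
#' The 79 proteins of the 80S ribosome (family-level names), one per
#' ribosome at 1:1 stoichiometry. Supply `path` to use your own list
#' (one id per line, '#' comments allowed).
#'
#' @param path optional path to an alternative list.
#' @return character vector of gene names.
#' @export
ribosomal_protein_ids <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ribosomal_proteins_80s.txt",
                                package = "cytocell", mustWork = TRUE)
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

.split_semicolon <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) character(0)
    else trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

#' Read the abundance, dataset-metadata and annotation tables
#'
#' Reads the three TSV files, validates them (unique ids, known technique
#' vocabulary, non-negative abundances), joins abundances to annotations on
#' protein id (case-insensitive) and drops -- with a warning naming them --
#' proteins that lack an annotation row. Row and column order follow the
#' abundance file.
#'
#' @param abundance_path,metadata_path,annotation_path file paths.
#' @return list with `abundance` (numeric matrix, proteins x datasets, NA =
#'   missing), `datasets` (data.frame: dataset_id, technique, medium, phase,
#'   units) and `annotations` (data.frame: protein_id, molecular_mass_da,
#'   compartments (list column), is_ribosomal, go_classes (list column)),
#'   with annotations aligned to the abundance rows.
#' @export
read_tables <- function(abundance_path, metadata_path, annotation_path) {
  for (p in c(abundance_path, metadata_path, annotation_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  ab <- utils::read.delim(abundance_path, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))

  if (anyDuplicated(ab[[1]])) {
    stop("duplicate protein id in abundance table: ",
         paste(unique(ab[[1]][duplicated(ab[[1]])]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(ann$protein_id)) {
    stop("duplicate protein id in annotation table: ",
         paste(unique(ann$protein_id[duplicated(ann$protein_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(meta$dataset_id)) {
    stop("duplicate dataset id in metadata table", call. = FALSE)
  }
  bad_tech <- setdiff(meta$technique, TECHNIQUES)
  if (length(bad_tech)) {
    stop("unknown technique label(s): ", paste(bad_tech, collapse = ", "),
         "; expected one of ", paste(TECHNIQUES, collapse = ", "), call. = FALSE)
  }

  mat <- as.matrix(ab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(ab[[1]])
  if (!setequal(colnames(mat), meta$dataset_id)) {
    stop("abundance columns do not match metadata dataset ids", call. = FALSE)
  }
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative abundance for protein '%s' in dataset '%s'",
                 rownames(mat)[neg[1, 1]], colnames(mat)[neg[1, 2]]),
         call. = FALSE)
  }

  # case-insensitive join on systematic names
  key <- toupper(rownames(mat))
  ann_key <- toupper(ann$protein_id)
  hit <- match(key, ann_key)
  if (anyNA(hit)) {
    dropped <- rownames(mat)[is.na(hit)]
    warning("dropping ", length(dropped), " protein(s) without annotation: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    mat <- mat[!is.na(hit), , drop = FALSE]
    hit <- hit[!is.na(hit)]
  }
  ann <- ann[hit, , drop = FALSE]
  if (any(!is.finite(ann$molecular_mass_da)) || any(ann$molecular_mass_da <= 0)) {
    stop("molecular_mass_da must be positive for every annotated protein",
         call. = FALSE)
  }

  annotations <- data.frame(
    protein_id = rownames(mat),
    molecular_mass_da = ann$molecular_mass_da,
    is_ribosomal = as.logical(as.integer(ann$is_ribosomal)),
    stringsAsFactors = FALSE
  )
  annotations$compartments <- .split_semicolon(ann$compartments)
  annotations$go_classes <- if ("go_classes" %in% names(ann)) {
    .split_semicolon(ann$go_classes)
  } else {
    rep(list(character(0)), nrow(annotations))
  }

  list(abundance = mat, datasets = meta, annotations = annotations)
}

#' Restrict to the cytoplasmic proteome
#'
#' A protein is excluded iff its GO-slim compartment set intersects
#' `excluded_compartments` -- any excluded compartment wins even when the
#' protein is also annotated cytoplasmic, so organellar mass is never double
#' counted. Ribosomal proteins are returned as a separate partition for
#' stoichiometry analysis and are never part of the cytoplasmic set.
#'
#' @param annotations annotation data.frame from [read_tables()].
#' @param abundance abundance matrix from [read_tables()].
#' @param excluded_compartments non-empty character vector; defaults to
#'   [default_excluded_compartments()].
#' @return list with `cytoplasmic` and `ribosomal`, each holding `abundance`
#'   and `annotations` aligned subsets, plus `excluded_ids`.
#' @export
filter_cytoplasmic <- function(annotations, abundance,
                               excluded_compartments = default_excluded_compartments()) {
  if (!length(excluded_compartments)) {
    stop("excluded_compartments must be non-empty", call. = FALSE)
  }
  stopifnot(identical(annotations$protein_id, rownames(abundance)))
  excl <- tolower(excluded_compartments)
  hits_excluded <- vapply(annotations$compartments, function(cs) {
    any(tolower(cs) %in% excl)
  }, logical(1))
  ribosomal <- annotations$is_ribosomal
  cyto <- !hits_excluded & !ribosomal

  list(
    cytoplasmic = list(
      abundance = abundance[cyto, , drop = FALSE],
      annotations = annotations[cyto, , drop = FALSE]
    ),
    ribosomal = list(
      abundance = abundance[ribosomal, , drop = FALSE],
      annotations = annotations[ribosomal, , drop = FALSE]
    ),
    excluded_ids = annotations$protein_id[hits_excluded & !ribosomal]
  )
}

#' Rank proteins by per-cell mass contribution
#'
#' Per-cell mass of a protein is its molecular mass times its abundance. The
#' abundance statistic is either the per-protein median across the chosen
#' dataset columns (the default, robust to outlier datasets) or the value
#' from a single named dataset. Proteins with no non-missing abundance in
#' the chosen columns are excluded with a warning. Ties in mass are broken
#' by lexicographic protein id.
#'
#' @param abundance abundance matrix (proteins x datasets).
#' @param annotations aligned annotation data.frame.
#' @param datasets character vector of dataset columns to use (default: all).
#' @param statistic `"median"` across the chosen datasets, or `"value"` with
#'   exactly one dataset column.
#' @return data.frame (protein_id, abundance, molecular_mass_da, mass_da)
#'   sorted by decreasing mass.
#' @export
rank_by_mass <- function(abundance, annotations,
                         datasets = colnames(abundance),
                         statistic = c("median", "value")) {
  statistic <- match.arg(statistic)
  stopifnot(identical(annotations$protein_id, rownames(abundance)))
  missing_cols <- setdiff(datasets, colnames(abundance))
  if (length(missing_cols)) {
    stop("unknown dataset column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  sub <- abundance[, datasets, drop = FALSE]
  if (statistic == "value" && ncol(sub) != 1L) {
    stop("statistic = 'value' needs exactly one dataset column", call. = FALSE)
  }
  a <- apply(sub, 1L, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else stats::median(v)
  })
  if (anyNA(a)) {
    warning("excluding ", sum(is.na(a)),
            " protein(s) with no abundance in the chosen datasets: ",
            paste(names(a)[is.na(a)], collapse = ", "), call. = FALSE)
  }
  keep <- !is.na(a)
  out <- data.frame(
    protein_id = annotations$protein_id[keep],
    abundance = unname(a[keep]),
    molecular_mass_da = annotations$molecular_mass_da[keep],
    stringsAsFactors = FALSE
  )
  out$mass_da <- out$abundance * out$molecular_mass_da
  out <- out[order(-out$mass_da, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cumulative mass fraction of the top-N ranked proteins
#'
#' @param ranked output of [rank_by_mass()].
#' @param n how many top proteins to sum, 1 <= n <= nrow(ranked).
#' @return fraction of the total per-cell protein mass carried by the top n.
#' @examples
#' r <- data.frame(protein_id = c("A", "B"), abundance = 1,
#'                 molecular_mass_da = c(3, 1), mass_da = c(3, 1))
#' cumulative_mass_fraction(r, 1)  # 0.75
#' @export
cumulative_mass_fraction <- function(ranked, n) {
  if (!nrow(ranked)) stop("empty ranking", call. = FALSE)
  if (n < 1 || n > nrow(ranked)) {
    stop("n must lie in [1, ", nrow(ranked), "]", call. = FALSE)
  }
  sum(ranked$mass_da[seq_len(n)]) / sum(ranked$mass_da)
}
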