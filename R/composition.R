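# Building the one-ribosome simulation-cell composition: scaling whole-cell
# protein abundances to a single ribosome's share of the cytoplasm,
# selecting the top protein types by mass, and searching for the smallest
# abundance scaling factor whose rounded copy numbers satisfy both the
# target macromolecular density and the target ribosomal-to-cytoplasmic
# protein mass ratio.

#' Configuration of the scaling-factor search
#'
#' The scaling factor s multiplies every per-box protein abundance before
#' rounding to integer copies; it compensates the mass lost by dropping
#' low-abundance species and fractional copies. The search walks an
#' ascending grid and keeps the smallest feasible s (the smallest factor
#' preserves the most representative protein composition), breaking ties at
#' equal s by the smallest number of protein types K.
#'
#' @param s_min,s_max,s_step grid over s (defaults 1 to 5 by 0.001).
#' @param density_tolerance relative tolerance on the density target.
#' @param ratio_tolerance relative tolerance on the rib/cyt target.
#' @return validated list of class `builder_config`.
#' @export
builder_config <- function(s_min = 1.0, s_max = 5.0, s_step = 0.001,
                           density_tolerance = 0.02, ratio_tolerance = 0.02) {
  if (s_min >= s_max) stop("s_min must be < s_max", call. = FALSE)
  .check_positive(s_step, "s_step")
  .check_positive(density_tolerance, "density_tolerance")
  .check_positive(ratio_tolerance, "ratio_tolerance")
  structure(list(s_min = s_min, s_max = s_max, s_step = s_step,
                 density_tolerance = density_tolerance,
                 ratio_tolerance = ratio_tolerance),
            class = "builder_config")
}

#' Scale a whole-cell abundance to one ribosome's share
#'
#' @param abundance_cell copies per cell (>= 0).
#' @param n_ribosomes_cell ribosomes per cell (> 0).
#' @return fractional copies per one-ribosome box.
#' @examples
#' per_ribosome_abundance(252426, 126213)  # 2
#' @export
per_ribosome_abundance <- function(abundance_cell, n_ribosomes_cell) {
  .check_positive(n_ribosomes_cell, "n_ribosomes_cell")
  if (any(abundance_cell < 0, na.rm = TRUE)) {
    stop("abundance must be non-negative", call. = FALSE)
  }
  abundance_cell / n_ribosomes_cell
}

#' Integer copy numbers after scaling
#'
#' Rounds s * a half away from zero; a zero result means the protein is
#' dropped from the composition.
#'
#' @param a per-box fractional abundance (>= 0).
#' @param s scaling factor (> 0).
#' @return integer copy numbers (possibly 0).
#' @examples
#' integer_copies(0.4, 1.803)  # 1
#' integer_copies(0.2, 1.803)  # 0 -> dropped
#' @export
integer_copies <- function(a, s) {
  .check_positive(s, "s")
  if (any(a < 0, na.rm = TRUE)) stop("a must be non-negative", call. = FALSE)
  round_half_away(s * a)
}

# Achieved metrics for prefix masses; cyto_mass in Da, box volume in um^3.
.achieved <- function(cyto_mass, fixed, box_volume_um3) {
  list(
    rib_cyt = fixed$ribosome_protein_mass / cyto_mass,
    density = macromolecular_density(
      cyto_mass + fixed$ribosome_total_mass + fixed$trna_mass_total,
      box_volume_um3)
  )
}

#' Smallest feasible number of protein types at a given scaling factor
#'
#' With copy numbers c_i = [integer_copies()] of the top-K ranked per-box
#' abundances, the composition is feasible when both constraints hold
#' within their relative tolerances: the rib/cyt ratio
#' ribosome_protein_mass / sum(c_i m_i), and the macromolecular density
#' (sum(c_i m_i) + ribosome_total_mass + trna_mass_total) / box volume.
#' Returns the smallest such K, or NA when no prefix works.
#'
#' @param per_box_abundance fractional per-box abundances, ranked by
#'   decreasing per-cell mass (rank order is the selection order).
#' @param masses molecular masses in Da, aligned with `per_box_abundance`.
#' @param s scaling factor.
#' @param targets list(rib_cyt, density).
#' @param config a [builder_config()] (tolerances are taken from it).
#' @param fixed list(ribosome_protein_mass, ribosome_total_mass,
#'   trna_mass_total), all in Da.
#' @param box_volume_um3 box volume in um^3.
#' @return list(K, copies, achieved_rib_cyt, achieved_density), or NA-K when
#'   infeasible (with `ratio_ok_somewhere` / `density_ok_somewhere` flags).
#' @export
feasible_K <- function(per_box_abundance, masses, s, targets, config,
                       fixed, box_volume_um3) {
  if (!length(per_box_abundance)) stop("empty ranking", call. = FALSE)
  stopifnot(length(per_box_abundance) == length(masses))
  copies <- integer_copies(per_box_abundance, s)
  cm <- cumsum(copies * masses)
  valid <- cm > 0
  rc <- ifelse(valid, fixed$ribosome_protein_mass / cm, Inf)
  dens <- (cm + fixed$ribosome_total_mass + fixed$trna_mass_total) *
    .DA_TO_G / (box_volume_um3 * .UM3_TO_L)
  ratio_ok <- valid & abs(rc - targets$rib_cyt) / targets$rib_cyt <=
    config$ratio_tolerance
  density_ok <- abs(dens - targets$density) / targets$density <=
    config$density_tolerance
  ok <- which(ratio_ok & density_ok)
  if (!length(ok)) {
    return(list(K = NA_integer_, copies = copies,
                ratio_ok_somewhere = any(ratio_ok),
                density_ok_somewhere = any(density_ok)))
  }
  K <- ok[1L]
  list(K = K, copies = copies,
       achieved_rib_cyt = rc[K], achieved_density = dens[K])
}

#' Search for the minimal scaling factor satisfying both constraints
#'
#' Walks the ascending s grid of `config` and returns the first (smallest)
#' s with a feasible prefix, together with its smallest feasible K and the
#' assembled composition. Grid search rather than root finding because the
#' objective is stepwise in s (integer rounding). When no grid point is
#' feasible the result carries `feasible = FALSE` and names the binding
#' constraint (the one that never held anywhere on the grid, or "joint"
#' when each held somewhere but never together).
#'
#' @param ranked data.frame with columns protein_id, per_box_abundance,
#'   molecular_mass_da, in selection (descending per-cell mass) order.
#' @param targets list(rib_cyt, density).
#' @param config a [builder_config()].
#' @param fixed list(ribosome_protein_mass, ribosome_total_mass,
#'   trna_mass_total) in Da.
#' @param box_volume_um3 box volume in um^3.
#' @param n_trna,box_length_angstrom bookkeeping fields copied into the
#'   returned spec.
#' @return a `composition_spec` list; see [build_composition()].
#' @export
search_min_scaling <- function(ranked, targets, config, fixed,
                               box_volume_um3, n_trna = NA,
                               box_length_angstrom = NA) {
  stopifnot(inherits(config, "builder_config"))
  if (!nrow(ranked)) stop("empty ranking", call. = FALSE)
  s_grid <- seq(config$s_min, config$s_max, by = config$s_step)
  ratio_any <- FALSE
  density_any <- FALSE
  for (s in s_grid) {
    fk <- feasible_K(ranked$per_box_abundance, ranked$molecular_mass_da,
                     s, targets, config, fixed, box_volume_um3)
    if (!is.na(fk$K)) {
      return(.assemble_spec(ranked, s, fk, targets, config,
                            box_volume_um3, n_trna, box_length_angstrom))
    }
    ratio_any <- ratio_any || fk$ratio_ok_somewhere
    density_any <- density_any || fk$density_ok_somewhere
  }
  binding <- if (!ratio_any && !density_any) "both"
  else if (!ratio_any) "rib_cyt"
  else if (!density_any) "density"
  else "joint"
  structure(list(feasible = FALSE, binding_constraint = binding,
                 targets = targets, config = config,
                 n_ribosomes = 1L, n_trna = n_trna,
                 box_length_angstrom = box_length_angstrom),
            class = "composition_spec")
}

.assemble_spec <- function(ranked, s, fk, targets, config,
                           box_volume_um3, n_trna, box_length_angstrom) {
  K <- fk$K
  copies <- fk$copies[seq_len(K)]
  keep <- copies >= 1
  entries <- data.frame(
    protein_id = ranked$protein_id[seq_len(K)][keep],
    copy_number = as.integer(copies[keep]),
    molecular_mass_da = ranked$molecular_mass_da[seq_len(K)][keep],
    stringsAsFactors = FALSE
  )
  cyto_mass <- sum(entries$copy_number * entries$molecular_mass_da)
  entries$mass_fraction_of_cytoplasmic <-
    entries$copy_number * entries$molecular_mass_da / cyto_mass
  structure(list(
    feasible = TRUE,
    entries = entries,
    scaling_factor = s,
    K = K,
    n_types = nrow(entries),
    n_molecules = sum(entries$copy_number),
    n_ribosomes = 1L,
    n_trna = n_trna,
    box_length_angstrom = box_length_angstrom,
    achieved_density = fk$achieved_density,
    achieved_rib_cyt = fk$achieved_rib_cyt,
    targets = targets,
    config = config
  ), class = "composition_spec")
}

#' Derive density and rib/cyt targets from a proteome
#'
#' Computes the two box targets from whole-cell quantities: the rib/cyt
#' ratio as (n_ribosomes x ribosome protein mass) / total cytoplasmic
#' protein mass, and the macromolecular density as the total mass of
#' cytoplasmic proteins, ribosomes (rRNA-inclusive) and tRNAs over the
#' cytoplasm volume. Used when targets are to be self-consistent with the
#' abundance data feeding the builder.
#'
#' @param cytoplasmic_mass_cell total non-ribosomal cytoplasmic protein mass
#'   per cell, Da.
#' @param params a [cell_parameters()] with `n_ribosomes_cell` set.
#' @return list(rib_cyt, density).
#' @export
derive_targets <- function(cytoplasmic_mass_cell, params) {
  stopifnot(inherits(params, "cell_parameters"))
  .check_positive(cytoplasmic_mass_cell, "cytoplasmic_mass_cell")
  n_rib <- params$n_ribosomes_cell
  .check_positive(n_rib %||% -1, "n_ribosomes_cell")
  total_mass <- cytoplasmic_mass_cell +
    n_rib * params$ribosome_total_mass +
    params$n_trna_cell * params$trna_mass
  list(
    rib_cyt = rib_cyt_ratio(n_rib * params$ribosome_protein_mass,
                            cytoplasmic_mass_cell),
    density = macromolecular_density(total_mass, params$cytoplasm_volume)
  )
}

#' Build the full one-ribosome simulation-cell composition
#'
#' End-to-end builder: ranks the filtered cytoplasmic proteome by per-cell
#' mass, scales abundances to one ribosome's share, derives box geometry
#' and tRNA count from the cell parameters, and runs the minimal
#' scaling-factor search against the configured (or data-derived) targets.
#'
#' @param abundance filtered cytoplasmic abundance matrix.
#' @param annotations aligned annotation data.frame.
#' @param params a [cell_parameters()] with `n_ribosomes_cell` set; its
#'   `target_density` and `target_rib_cyt` are the constraints unless
#'   `targets` overrides them.
#' @param config a [builder_config()].
#' @param datasets dataset columns used for the abundance statistic
#'   (per-protein median across them); default all columns.
#' @param targets optional list(rib_cyt, density) overriding the params
#'   targets (e.g. from [derive_targets()]).
#' @param top_n optional cap on ranked protein types considered.
#' @return a `composition_spec` list (see [search_min_scaling()]).
#' @export
build_composition <- function(abundance, annotations, params, config = builder_config(),
                              datasets = colnames(abundance),
                              targets = NULL, top_n = NULL) {
  stopifnot(inherits(params, "cell_parameters"))
  n_rib <- params$n_ribosomes_cell
  if (is.null(n_rib)) {
    stop("params$n_ribosomes_cell must be set (estimate it upstream)",
         call. = FALSE)
  }
  ranked <- rank_by_mass(abundance, annotations, datasets = datasets)
  if (!is.null(top_n)) ranked <- utils::head(ranked, top_n)
  ranked$per_box_abundance <- per_ribosome_abundance(ranked$abundance, n_rib)

  box_vol <- params$cytoplasm_volume / n_rib
  n_trna <- trna_count_box(params$n_trna_cell, n_rib)
  blen <- box_length(params$cytoplasm_volume, n_rib)
  fixed <- list(ribosome_protein_mass = params$ribosome_protein_mass,
                ribosome_total_mass = params$ribosome_total_mass,
                trna_mass_total = n_trna * params$trna_mass)
  targets <- targets %||% list(rib_cyt = params$target_rib_cyt,
                               density = params$target_density)
  search_min_scaling(ranked, targets, config, fixed, box_vol,
                     n_trna = n_trna, box_length_angstrom = blen)
}

#' Write a composition to disk
#'
#' Emits `composition.tsv` (protein_id, copy_number, molecular_mass_da,
#' mass_fraction_of_cytoplasmic) and `summary.json` (scaling_factor,
#' n_types, n_molecules, n_trna, box_length_angstrom,
#' achieved_density_g_per_l, achieved_rib_cyt, target_density_g_per_l,
#' target_rib_cyt, feasible).
#'
#' @param spec a `composition_spec`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_composition <- function(spec, dir) {
  stopifnot(inherits(spec, "composition_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (isTRUE(spec$feasible)) {
    utils::write.table(spec$entries, file.path(dir, "composition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- list(
    scaling_factor = if (isTRUE(spec$feasible)) spec$scaling_factor else NA,
    n_types = spec$n_types %||% NA,
    n_molecules = spec$n_molecules %||% NA,
    n_trna = spec$n_trna,
    box_length_angstrom = spec$box_length_angstrom,
    achieved_density_g_per_l = spec$achieved_density %||% NA,
    achieved_rib_cyt = spec$achieved_rib_cyt %||% NA,
    target_density_g_per_l = spec$targets$density,
    target_rib_cyt = spec$targets$rib_cyt,
    feasible = isTRUE(spec$feasible)
  )
  if (!isTRUE(spec$feasible)) {
    summary$binding_constraint <- spec$binding_constraint
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' @export
print.composition_spec <- function(x, ...) {
  if (isTRUE(x$feasible)) {
    cat("One-ribosome simulation-cell composition\n")
    cat(sprintf("  scaling factor s = %.3f (top %d ranked types considered)\n",
                x$scaling_factor, x$K))
    cat(sprintf("  %d protein molecules of %d types, %s tRNAs, 1 ribosome\n",
                x$n_molecules, x$n_types, format(x$n_trna)))
    cat(sprintf("  box edge %.1f angstrom\n", x$box_length_angstrom))
    cat(sprintf("  density %.2f g/L (target %.2f), rib/cyt %.4f (target %.4f)\n",
                x$achieved_density, x$targets$density,
                x$achieved_rib_cyt, x$targets$rib_cyt))
  } else {
    cat("Infeasible composition: no scaling factor on the grid satisfies\n")
    cat("  binding constraint:", x$binding_constraint, "\n")
  }
  invisible(x)
}
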