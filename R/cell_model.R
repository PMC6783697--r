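# Physical parameters of the yeast cytoplasm and of the one-ribosome
# simulation cell: volumes, masses, macromolecular density, the
# ribosomal-to-cytoplasmic protein mass ratio, box geometry and tRNA scaling.

#' Assemble the physical parameters of the cell model
#'
#' Collects the constants describing a haploid budding-yeast cell and the
#' targets for the simulation box into a validated `cell_parameters` object.
#' Defaults reflect commonly used literature values: a 42 um^3 cell of which
#' 65 percent is cytoplasm, 3 million tRNAs per cell of 75 nucleotides at
#' 340 Da each, and a target ribosomal-to-cytoplasmic protein mass ratio
#' (rib/cyt) of 0.2229 at a target macromolecular density of 90 g/L.
#'
#' The two ribosome masses have no defaults and must be supplied: the mass of
#' the ribosomal proteins alone (`ribosome_protein_mass`, the rib/cyt
#' numerator) and the full 80S particle including rRNA
#' (`ribosome_total_mass`, which enters the density budget). A
#' literature-derived example lives in
#' `system.file("extdata", "cell_params_example.json", package = "cytocell")`.
#'
#' @param cell_volume cell volume in um^3.
#' @param cytoplasm_fraction fraction of cell volume that is cytoplasm, in (0,1].
#' @param n_ribosomes_cell ribosomes per cell (estimated upstream or supplied).
#' @param n_trna_cell tRNA molecules per cell.
#' @param trna_nucleotides nucleotides in an average tRNA.
#' @param nucleotide_mass average nucleotide mass in Da.
#' @param ribosome_protein_mass summed mass of the ribosomal proteins of one
#'   ribosome, Da.
#' @param ribosome_total_mass mass of one complete ribosome including rRNA, Da.
#' @param target_density target macromolecular density of the box, g/L.
#' @param target_rib_cyt target ribosomal-to-cytoplasmic protein mass ratio.
#' @return a list of class `cell_parameters`; `cytoplasm_volume` (um^3) and
#'   `trna_mass` (Da) are derived fields.
#' @examples
#' cp <- cell_parameters(n_ribosomes_cell = 126213,
#'                       ribosome_protein_mass = 1.4e6,
#'                       ribosome_total_mass = 3.3e6)
#' cp$cytoplasm_volume  # 27.3
#' @export
cell_parameters <- function(cell_volume = 42,
                            cytoplasm_fraction = 0.65,
                            n_ribosomes_cell = NULL,
                            n_trna_cell = 3e6,
                            trna_nucleotides = 75,
                            nucleotide_mass = 340,
                            ribosome_protein_mass,
                            ribosome_total_mass,
                            target_density = 90,
                            target_rib_cyt = 0.2229) {
  .check_positive(cell_volume, "cell_volume")
  .check_positive(cytoplasm_fraction, "cytoplasm_fraction")
  .check_fraction(cytoplasm_fraction, "cytoplasm_fraction")
  .check_positive(n_trna_cell, "n_trna_cell")
  .check_positive(trna_nucleotides, "trna_nucleotides")
  .check_positive(nucleotide_mass, "nucleotide_mass")
  if (missing(ribosome_protein_mass) || missing(ribosome_total_mass)) {
    stop("ribosome_protein_mass and ribosome_total_mass are required; ",
         "there are no defaults for the per-ribosome masses", call. = FALSE)
  }
  .check_positive(ribosome_protein_mass, "ribosome_protein_mass")
  .check_positive(ribosome_total_mass, "ribosome_total_mass")
  if (ribosome_total_mass < ribosome_protein_mass) {
    stop("ribosome_total_mass (rRNA-inclusive) cannot be smaller than ",
         "ribosome_protein_mass", call. = FALSE)
  }
  .check_positive(target_density, "target_density")
  .check_positive(target_rib_cyt, "target_rib_cyt")
  if (!is.null(n_ribosomes_cell)) .check_positive(n_ribosomes_cell, "n_ribosomes_cell")

  structure(list(
    cell_volume = cell_volume,
    cytoplasm_fraction = cytoplasm_fraction,
    cytoplasm_volume = cytoplasm_volume(cell_volume, cytoplasm_fraction),
    n_ribosomes_cell = n_ribosomes_cell,
    n_trna_cell = n_trna_cell,
    trna_nucleotides = trna_nucleotides,
    nucleotide_mass = nucleotide_mass,
    trna_mass = average_trna_mass(trna_nucleotides, nucleotide_mass),
    ribosome_protein_mass = ribosome_protein_mass,
    ribosome_total_mass = ribosome_total_mass,
    target_density = target_density,
    target_rib_cyt = target_rib_cyt
  ), class = "cell_parameters")
}

#' Cytoplasm volume from cell volume and cytoplasmic fraction
#'
#' @param cell_volume cell volume, um^3.
#' @param fraction cytoplasmic volume fraction in (0,1].
#' @return cytoplasm volume in um^3.
#' @examples
#' cytoplasm_volume(42, 0.65)  # 27.3
#' @export
cytoplasm_volume <- function(cell_volume, fraction) {
  .check_positive(cell_volume, "cell_volume")
  .check_positive(fraction, "fraction")
  .check_fraction(fraction, "fraction")
  cell_volume * fraction
}

#' Average tRNA mass
#'
#' @param n_nucleotides nucleotides per tRNA.
#' @param nucleotide_mass average nucleotide mass, Da.
#' @return mass in Da.
#' @examples
#' average_trna_mass(75, 340)  # 25500
#' @export
average_trna_mass <- function(n_nucleotides, nucleotide_mass) {
  .check_positive(n_nucleotides, "n_nucleotides")
  .check_positive(nucleotide_mass, "nucleotide_mass")
  n_nucleotides * nucleotide_mass
}

#' Macromolecular density in g/L
#'
#' Converts a total macromolecular mass in daltons inside a volume in cubic
#' micrometres to grams per litre (1 Da = 1/6.0221408e23 g, about
#' 1.66054e-24 g; 1 um^3 = 1e-15 L).
#'
#' @param total_mass_da total mass, Da (>= 0).
#' @param volume_um3 volume, um^3 (> 0).
#' @return density in g/L.
#' @examples
#' macromolecular_density(6.0221408e23, 1e15)  # one mole of Da in 1 L: ~1 g/L
#' @export
macromolecular_density <- function(total_mass_da, volume_um3) {
  if (!is.numeric(total_mass_da) || any(total_mass_da < 0)) {
    stop("'total_mass_da' must be non-negative", call. = FALSE)
  }
  .check_positive(volume_um3, "volume_um3")
  (total_mass_da * .DA_TO_G) / (volume_um3 * .UM3_TO_L)
}

#' Ribosomal-to-cytoplasmic protein mass ratio
#'
#' @param ribosomal_mass total ribosomal-protein mass, Da (>= 0).
#' @param cytoplasmic_mass total non-ribosomal cytoplasmic protein mass, Da (> 0).
#' @return the unitless rib/cyt ratio.
#' @examples
#' rib_cyt_ratio(2, 10)  # 0.2
#' @export
rib_cyt_ratio <- function(ribosomal_mass, cytoplasmic_mass) {
  if (!is.numeric(ribosomal_mass) || any(ribosomal_mass < 0)) {
    stop("'ribosomal_mass' must be non-negative", call. = FALSE)
  }
  .check_positive(cytoplasmic_mass, "cytoplasmic_mass")
  ribosomal_mass / cytoplasmic_mass
}

#' Edge length of the cubic one-ribosome simulation cell
#'
#' The cytoplasm volume is divided evenly among the cell's ribosomes and the
#' cube root of one ribosome's share gives the box edge, reported in angstrom.
#' An explicit `override_angstrom` forces any length (useful to match an
#' externally fixed box).
#'
#' @param cytoplasm_volume_um3 cytoplasm volume, um^3.
#' @param n_ribosomes ribosomes per cell.
#' @param override_angstrom optional fixed edge length, angstrom.
#' @return edge length in angstrom.
#' @examples
#' box_length(1, 1)  # a 1 um^3 cube: 10000 angstrom
#' @export
box_length <- function(cytoplasm_volume_um3, n_ribosomes, override_angstrom = NULL) {
  if (!is.null(override_angstrom)) {
    .check_positive(override_angstrom, "override_angstrom")
    return(override_angstrom)
  }
  .check_positive(cytoplasm_volume_um3, "cytoplasm_volume_um3")
  .check_positive(n_ribosomes, "n_ribosomes")
  (cytoplasm_volume_um3 / n_ribosomes)^(1 / 3) * .UM_TO_ANGSTROM
}

#' tRNA copies in the one-ribosome box
#'
#' Scales the whole-cell tRNA pool down to one ribosome's share of the
#' cytoplasm (equivalently, to the box volume when the box is one ribosome's
#' share), rounding half away from zero. `override` forces any count.
#'
#' @param n_trna_cell tRNAs per cell.
#' @param n_ribosomes ribosomes per cell.
#' @param override optional fixed count.
#' @return integer tRNA count for the box.
#' @examples
#' trna_count_box(3e6, 126213)  # 24
#' @export
trna_count_box <- function(n_trna_cell, n_ribosomes, override = NULL) {
  if (!is.null(override)) {
    .check_positive(override, "override")
    return(round_half_away(override))
  }
  .check_positive(n_trna_cell, "n_trna_cell")
  .check_positive(n_ribosomes, "n_ribosomes")
  round_half_away(n_trna_cell / n_ribosomes)
}
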