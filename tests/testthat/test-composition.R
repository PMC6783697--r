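test_that("per-ribosome scaling and integer rounding follow the conventions", {
  expect_equal(per_ribosome_abundance(126213, 126213), 1)
  expect_equal(per_ribosome_abundance(252426, 126213), 2)
  expect_equal(per_ribosome_abundance(0, 126213), 0)
  expect_error(per_ribosome_abundance(-1, 10), "non-negative")
  expect_error(per_ribosome_abundance(5, 0), "n_ribosomes_cell")

  expect_equal(integer_copies(0.4, 1.803), 1)   # 0.7212 -> 1
  expect_equal(integer_copies(0.2, 1.803), 0)   # 0.3606 -> 0, dropped
  expect_equal(integer_copies(1, 1), 1)
  expect_error(integer_copies(-0.1, 1), "non-negative")
  expect_error(integer_copies(1, 0), "s")
})

# shared toy fixture: 3 types, masses 100/50/10 kDa, per-box abundances
# 10/20/30, ribosomal protein mass 1,000 kDa
toy_fixture <- function(ratio_tol = 0.01, density_tol = 0.01) {
  fixed <- list(ribosome_protein_mass = 1e6, ribosome_total_mass = 2e6,
                trna_mass_total = 0)
  list(per_box = c(10, 20, 30), masses = c(1e5, 5e4, 1e4), fixed = fixed,
       box_volume = 1e-4,
       config = builder_config(s_min = 1, s_max = 3, s_step = 0.01,
                               ratio_tolerance = ratio_tol,
                               density_tolerance = density_tol))
}

test_that("feasible_K returns the smallest prefix satisfying both constraints", {
  fx <- toy_fixture()
  # targets taken exactly from s = 1 at the full list: rib/cyt = 0.25 needs
  # all three types, so the full-list K is the answer
  copies <- integer_copies(fx$per_box, 1)
  full_mass <- sum(copies * fx$masses)
  targets <- list(rib_cyt = fx$fixed$ribosome_protein_mass / full_mass,
                  density = macromolecular_density(
                    full_mass + fx$fixed$ribosome_total_mass, fx$box_volume))
  fk <- feasible_K(fx$per_box, fx$masses, 1, targets, fx$config, fx$fixed,
                   fx$box_volume)
  expect_equal(fk$K, 3)
  expect_equal(fk$achieved_rib_cyt, targets$rib_cyt)
  expect_equal(fk$achieved_density, targets$density)
  # unreachable targets: no prefix works, flags say which side failed
  bad <- feasible_K(fx$per_box, fx$masses, 1,
                    list(rib_cyt = 1e-6, density = targets$density),
                    fx$config, fx$fixed, fx$box_volume)
  expect_true(is.na(bad$K))
  expect_false(bad$ratio_ok_somewhere)
  expect_error(feasible_K(numeric(0), numeric(0), 1, list(), fx$config,
                          fx$fixed, fx$box_volume), "empty")
})

test_that("the minimal scaling search agrees with brute force on the toy system", {
  fx <- toy_fixture()
  targets <- list(rib_cyt = 0.25,
                  density = macromolecular_density(
                    4e6 + fx$fixed$ribosome_total_mass, fx$box_volume))
  ranked <- data.frame(protein_id = c("A", "B", "C"),
                       per_box_abundance = fx$per_box,
                       molecular_mass_da = fx$masses,
                       stringsAsFactors = FALSE)
  spec <- search_min_scaling(ranked, targets, fx$config, fx$fixed,
                             fx$box_volume)
  oracle <- brute_force_min_scaling(fx$per_box, fx$masses, targets,
                                    fx$config, fx$fixed, fx$box_volume)
  expect_false(is.null(oracle))
  expect_true(spec$feasible)
  expect_equal(spec$scaling_factor, oracle$s)
  expect_equal(spec$K, oracle$K)
})

test_that("a fixture feasible at the grid minimum returns s* = 1", {
  fx <- toy_fixture(ratio_tol = 0.05, density_tol = 0.05)
  copies <- integer_copies(fx$per_box, 1)
  mass <- sum(copies * fx$masses)
  targets <- list(rib_cyt = fx$fixed$ribosome_protein_mass / mass,
                  density = macromolecular_density(
                    mass + fx$fixed$ribosome_total_mass, fx$box_volume))
  ranked <- data.frame(protein_id = c("A", "B", "C"),
                       per_box_abundance = fx$per_box,
                       molecular_mass_da = fx$masses)
  spec <- search_min_scaling(ranked, targets, fx$config, fx$fixed,
                             fx$box_volume)
  expect_equal(spec$scaling_factor, 1)
})

test_that("vanishing tolerances on incommensurate masses are infeasible with a named constraint", {
  ranked <- data.frame(protein_id = c("A", "B"),
                       per_box_abundance = c(1.3, 0.7),
                       molecular_mass_da = c(sqrt(2) * 1e5, pi * 1e4))
  cfg <- builder_config(s_min = 1, s_max = 2, s_step = 0.05,
                        ratio_tolerance = 1e-12, density_tolerance = 1e-12)
  fixed <- list(ribosome_protein_mass = 1e6, ribosome_total_mass = 2e6,
                trna_mass_total = 0)
  spec <- search_min_scaling(ranked, list(rib_cyt = 0.25, density = 50),
                             cfg, fixed, 1e-4)
  expect_false(spec$feasible)
  expect_true(spec$binding_constraint %in%
                c("rib_cyt", "density", "both", "joint"))
})

test_that("scaled prefix mass is non-decreasing in s and refinement never raises s*", {
  set.seed(31)
  a <- runif(8, 0.2, 4)
  m <- runif(8, 2e4, 1.2e5)
  grid <- seq(1, 3, by = 0.02)
  for (K in c(3, 8)) {
    mass_s <- vapply(grid, function(s) sum(integer_copies(a[1:K], s) * m[1:K]),
                     numeric(1))
    expect_true(all(diff(mass_s) >= 0))
  }
  # a finer grid can only find an equal or smaller minimal s
  fx <- random_composition_fixture()
  ranked <- data.frame(protein_id = sprintf("P%02d", seq_along(fx$per_box)),
                       per_box_abundance = fx$per_box,
                       molecular_mass_da = fx$masses)
  coarse <- search_min_scaling(ranked, fx$targets, fx$config, fx$fixed,
                               fx$box_volume)
  fine_cfg <- fx$config
  fine_cfg$s_step <- fx$config$s_step / 2
  fine <- search_min_scaling(ranked, fx$targets, fine_cfg, fx$fixed,
                             fx$box_volume)
  expect_true(coarse$feasible && fine$feasible)
  expect_lte(fine$scaling_factor, coarse$scaling_factor)
})

test_that("end-to-end builder is self-consistent on synthetic data", {
  p <- small_synth(seed = 55, n_proteins = 500, n_ribosomal = 79,
                   missing_rate = 0.05)
  syn <- generate_dataset(p)
  parts <- filter_cytoplasmic(syn$annotations, syn$abundance)
  rib_ids <- syn$annotations$protein_id[syn$annotations$is_ribosomal]
  pooled <- as.vector(syn$abundance[rib_ids, ])
  n_rib <- median(pooled[!is.na(pooled)])
  params <- cell_parameters(n_ribosomes_cell = n_rib,
                            ribosome_protein_mass = 1.4e6,
                            ribosome_total_mass = 3.3e6)
  ranked <- suppressWarnings(rank_by_mass(parts$cytoplasmic$abundance,
                                          parts$cytoplasmic$annotations))
  targets <- derive_targets(sum(ranked$mass_da), params)
  spec <- suppressWarnings(
    build_composition(parts$cytoplasmic$abundance,
                      parts$cytoplasmic$annotations, params,
                      targets = targets))
  expect_true(spec$feasible)
  expect_lte(abs(spec$achieved_rib_cyt - targets$rib_cyt) / targets$rib_cyt,
             0.02)
  expect_lte(abs(spec$achieved_density - targets$density) / targets$density,
             0.02)
  expect_equal(spec$n_types, nrow(spec$entries))
  expect_equal(spec$n_molecules, sum(spec$entries$copy_number))
  expect_true(all(spec$entries$copy_number >= 1))
})

test_that("a one-protein degenerate cell builds a one-entry composition", {
  ann <- data.frame(protein_id = "A", molecular_mass_da = 5e4,
                    is_ribosomal = FALSE, stringsAsFactors = FALSE)
  ann$compartments <- list("cytoplasm")
  ann$go_classes <- list(character(0))
  mat <- matrix(3, 1, 1, dimnames = list("A", "D1"))
  params <- cell_parameters(n_ribosomes_cell = 1,
                            ribosome_protein_mass = 1e6,
                            ribosome_total_mass = 2e6,
                            target_rib_cyt = 1e6 / 1.5e5,
                            target_density = macromolecular_density(
                              3 * 5e4 + 2e6 + 3e6 * 25500, 27.3))
  spec <- build_composition(mat, ann, params,
                            builder_config(density_tolerance = 0.5,
                                           ratio_tolerance = 0.05))
  expect_true(spec$feasible)
  expect_identical(spec$entries$protein_id, "A")
})

test_that("written composition artifacts reproduce the summary bit for bit", {
  fx <- toy_fixture(ratio_tol = 0.05, density_tol = 0.05)
  copies <- integer_copies(fx$per_box, 1)
  mass <- sum(copies * fx$masses)
  targets <- list(rib_cyt = fx$fixed$ribosome_protein_mass / mass,
                  density = macromolecular_density(
                    mass + fx$fixed$ribosome_total_mass, fx$box_volume))
  ranked <- data.frame(protein_id = c("A", "B", "C"),
                       per_box_abundance = fx$per_box,
                       molecular_mass_da = fx$masses)
  spec <- search_min_scaling(ranked, targets, fx$config, fx$fixed,
                             fx$box_volume, n_trna = 0,
                             box_length_angstrom = 580)
  dir <- withr::local_tempdir()
  write_composition(spec, dir)
  tsv <- read.delim(file.path(dir, "composition.tsv"))
  sm <- jsonlite::read_json(file.path(dir, "summary.json"),
                            simplifyVector = TRUE)
  recomputed <- macromolecular_density(
    sum(tsv$copy_number * tsv$molecular_mass_da) +
      fx$fixed$ribosome_total_mass + fx$fixed$trna_mass_total,
    fx$box_volume)
  expect_equal(recomputed, sm$achieved_density_g_per_l, tolerance = 1e-12)
  expect_equal(sum(tsv$copy_number), sm$n_molecules)
  expect_equal(nrow(tsv), sm$n_types)
})
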