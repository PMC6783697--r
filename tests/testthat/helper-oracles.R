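# Independent oracles, coded from first principles so they do not share the
# implementation path they check.

# Exhaustive search over the whole (s, K) grid: for every grid s and every
# prefix K, recompute copies, mass, ratio and density directly and record
# feasibility; return the minimum-s (then minimum-K) feasible point.
brute_force_min_scaling <- function(per_box, masses, targets, config,
                                    fixed, box_volume_um3) {
  da_to_g <- 1 / 6.0221408e23
  s_grid <- seq(config$s_min, config$s_max, by = config$s_step)
  best <- NULL
  for (s in s_grid) {
    for (K in seq_along(per_box)) {
      copies <- floor(s * per_box[1:K] + 0.5)  # half away from zero, a >= 0
      mass <- sum(copies * masses[1:K])
      if (mass <= 0) next
      rc <- fixed$ribosome_protein_mass / mass
      dens <- (mass + fixed$ribosome_total_mass + fixed$trna_mass_total) *
        da_to_g / (box_volume_um3 * 1e-15)
      ok <- abs(rc - targets$rib_cyt) / targets$rib_cyt <= config$ratio_tolerance &&
        abs(dens - targets$density) / targets$density <= config$density_tolerance
      if (ok) { best <- list(s = s, K = K); break }
    }
    if (!is.null(best)) break
  }
  best
}

# Random small composition system whose targets are taken from a randomly
# chosen (s0, K0) point of the grid, so a feasible point is known to exist.
random_composition_fixture <- function(n_max = 10) {
  n <- sample(2:n_max, 1)
  per_box <- sort(runif(n, 0.1, 5), decreasing = TRUE)
  masses <- runif(n, 2e4, 1.2e5)
  config <- builder_config(s_min = 1, s_max = 3, s_step = 0.01,
                           density_tolerance = 0.02, ratio_tolerance = 0.02)
  fixed <- list(ribosome_protein_mass = 1.4e6, ribosome_total_mass = 3.3e6,
                trna_mass_total = 22 * 25500)
  box_volume <- 2e-4  # um^3, roughly a 580-angstrom cube
  s0 <- sample(seq(config$s_min, config$s_max, by = config$s_step), 1)
  K0 <- sample(seq_len(n), 1)
  copies <- floor(s0 * per_box[1:K0] + 0.5)
  mass <- sum(copies * masses[1:K0])
  if (mass <= 0) mass <- sum(masses)  # degenerate draw; any target works
  targets <- list(
    rib_cyt = fixed$ribosome_protein_mass / mass,
    density = (mass + fixed$ribosome_total_mass + fixed$trna_mass_total) /
      6.0221408e23 / (box_volume * 1e-15)
  )
  list(per_box = per_box, masses = masses, config = config, fixed = fixed,
       box_volume = box_volume, targets = targets)
}

# U statistic by direct pair counting (no ranks).
u_by_counting <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Exact two-sided Mann-Whitney p by enumerating every split of the pooled
# values into a group of size length(x).
mwu_enumeration_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  mu <- m * length(y) / 2
  obs <- u_by_counting(x, y)
  idx <- combn(length(pooled), m)
  us <- apply(idx, 2, function(i) u_by_counting(pooled[i], pooled[-i]))
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}
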