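test_that("cv_percent matches hand values, is scale invariant, and guards its domain", {
  expect_equal(cv_percent(c(2, 2, 2)), 0)
  expect_equal(cv_percent(c(1, 2, 3)), 50)  # sd = 1, mean = 2
  expect_error(cv_percent(5), "at least 2")
  expect_error(cv_percent(c(-1, 1)), "mean is zero")
  set.seed(1)
  for (i in 1:20) {
    x <- runif(10, 1, 100)
    c_scale <- runif(1, 0.01, 50)
    expect_equal(cv_percent(c_scale * x), cv_percent(x))
  }
})

test_that("ribosome estimates summarise each dataset's ribosomal abundances", {
  mat <- cbind(D1 = c(100, 100, 100), D2 = c(80, 100, 120),
               D3 = c(NA, NA, NA))
  rownames(mat) <- c("R1", "R2", "R3")
  est <- ribosome_estimates(mat, c("R1", "R2", "R3"), statistic = "mean")
  expect_equal(est$value[est$dataset_id == "D1"], 100)
  expect_equal(est$sd[est$dataset_id == "D1"], 0)
  expect_equal(est$value[est$dataset_id == "D2"], 100)
  # all-missing column is marked unavailable, not dropped silently
  expect_false(est$available[est$dataset_id == "D3"])
  expect_true(is.na(est$value[est$dataset_id == "D3"]))
  expect_error(ribosome_estimates(mat, c("R1", "R9")), "R9")
})

test_that("Welch test reproduces hand-computed statistics and conventions", {
  r <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  # x = 1:3 vs y = 4:6: t = -3/sqrt(2/3), df = 4
  r2 <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r2$df, 4, tolerance = 1e-12)
  expect_equal(r2$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
  # degenerate variance conventions
  expect_equal(welch_t_test(c(5, 5), c(5, 5))$p, 1)
  expect_warning(r3 <- welch_t_test(c(5, 5), c(7, 7)), "constant")
  expect_equal(r3$p, 0)
})

test_that("Mann-Whitney U is exact for small samples and rank invariant", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 2 / 6)
  expect_true(r$exact)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 1)
  a <- mann_whitney_u(c(1, 2, 3), c(2, 3, 4) + 1000)
  b <- mann_whitney_u(c(1, 2, 3), c(1001, 1002, 1003))
  expect_equal(a$p, b$p)
  expect_equal(a$U, b$U)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("exact Mann-Whitney p agrees with independent oracles for all m+n <= 10", {
  set.seed(42)
  for (m in 1:5) for (n in m:(10 - m)) {
    # tie-free case: wilcox.test's exact distribution is the oracle
    x <- rnorm(m); y <- rnorm(n)
    ours <- mann_whitney_u(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    # tied case: full-enumeration oracle by pair counting
    xt <- sample(1:3, m, replace = TRUE)
    yt <- sample(1:3, n, replace = TRUE)
    expect_equal(mann_whitney_u(xt, yt)$p, mwu_enumeration_p(xt, yt),
                 tolerance = 1e-12)
  }
})

test_that("large-sample Mann-Whitney approximation tracks wilcox.test with ties", {
  set.seed(7)
  x <- sample(1:8, 15, replace = TRUE)
  y <- sample(3:10, 15, replace = TRUE)
  ours <- mann_whitney_u(x, y)
  expect_false(ours$exact)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
})

test_that("pairwise matrix applies Bonferroni and BH over the pair family", {
  set.seed(3)
  samples <- lapply(setNames(1:5, paste0("D", 1:5)),
                    function(i) rnorm(8, mean = i / 2))
  pw <- pairwise_matrix(samples, test = "welch", alpha = 0.05)
  expect_equal(attr(pw, "n_pairs"), choose(5, 2))
  expect_equal(attr(pw, "bonferroni_alpha"), 0.05 / 10)
  expect_equal(pw$p_bh, p.adjust(pw$p_raw, "BH"))
  expect_true(all(pw$p_bh >= pw$p_raw))
  # Bonferroni-significant pairs are always BH-significant too
  expect_true(all(!pw$bonferroni_sig | pw$bh_sig))
  # two datasets: a single pair tested at alpha itself
  pw2 <- pairwise_matrix(samples[1:2], test = "mannwhitney")
  expect_equal(attr(pw2, "n_pairs"), 1)
  expect_equal(attr(pw2, "bonferroni_alpha"), 0.05)
  # unavailable datasets (fewer than 2 values) are skipped
  samples$D6 <- numeric(0)
  pw3 <- pairwise_matrix(samples, test = "welch")
  expect_equal(attr(pw3, "n_pairs"), choose(5, 2))
  expect_error(pairwise_matrix(list(a = 1:5)), "at least 2 datasets")
})

test_that("BH step-up matches the hand-worked example", {
  expect_equal(p.adjust(c(0.01, 0.04, 0.03), "BH"), c(0.03, 0.04, 0.04))
})

test_that("ontology profiles count multi-class proteins toward every class", {
  go <- list(A = "glycolysis", B = c("glycolysis", "folding"),
             C = character(0))
  pr <- ontology_profiles(list(d1 = c("A", "B"), d2 = "C"), go)
  expect_equal(pr$d1, c(folding = 1L, glycolysis = 2L))
  expect_length(pr$d2, 0)
  expect_error(ontology_profiles(list(d1 = "Z"), go), "Z")
})

test_that("profile Pearson and Jaccard behave like their definitions", {
  p1 <- c(a = 1, b = 2, c = 3)
  expect_equal(profile_pearson(p1, p1), 1)
  expect_equal(profile_pearson(p1, c(a = 3, b = 2, c = 1)), -1)
  expect_equal(profile_pearson(p1, c(a = 1, b = 1, c = 2)), sqrt(3) / 2,
               tolerance = 1e-12)
  # alignment on the union with zero fill
  expect_equal(profile_pearson(c(a = 1, b = 2), c(b = 2, c = 1)),
               cor(c(1, 2, 0), c(0, 2, 1)))
  # zero variance after alignment is undefined
  expect_true(is.na(profile_pearson(c(a = 2, b = 2, c = 2), p1)))
  # affine invariance
  expect_equal(profile_pearson(2 + 3 * p1, p1), 1)

  expect_equal(ontology_jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(ontology_jaccard(letters[1:3], letters[1:3]), 1)
  expect_equal(ontology_jaccard(letters[1:3], letters[4:6]), 0)
  expect_equal(ontology_jaccard(character(0), character(0)), 1)
  set.seed(9)
  for (i in 1:10) {
    s1 <- sample(letters, 5); s2 <- sample(letters, 7)
    expect_equal(ontology_jaccard(s1, s2), ontology_jaccard(s2, s1))
    expect_gte(ontology_jaccard(s1, s2), 0)
    expect_lte(ontology_jaccard(s1, s2), 1)
  }
})

test_that("median divergence uses the symmetric relative difference", {
  expect_equal(median_divergence(c(1, 2, 3), c(1, 2, 3))$fraction, 0)
  d <- median_divergence(c(10, 10, 10, 10), c(10, 14, 20, 10), threshold = 0.25)
  # symmetric relative differences 0, 1/3, 2/3, 0 -> half divergent
  expect_equal(d$fraction, 0.5)
  expect_identical(d$divergent, c(FALSE, TRUE, TRUE, FALSE))
  # threshold 0 flags any inequality
  expect_equal(median_divergence(c(1, 1), c(1, 1.01), threshold = 0)$fraction,
               0.5)
  # both medians zero: non-divergent by convention
  expect_equal(median_divergence(c(0, 1), c(0, 1))$fraction, 0)
  # one-sided denominators are available
  expect_equal(median_divergence(8, 10, threshold = 0.24,
                                 denominator = "a")$fraction, 1)
  expect_equal(median_divergence(8, 10, threshold = 0.24,
                                 denominator = "b")$fraction, 0)
})

test_that("extra-ribosomal set comparison has a uniform null and detects separation", {
  mat <- matrix(rep(c(10, 20, 30, 40), each = 3), 4, 3, byrow = TRUE,
                dimnames = list(paste0("R", 1:4), paste0("D", 1:3)))
  same <- extra_ribosomal_comparison(c("R1", "R2", "R3", "R4"),
                                     c("R1", "R2", "R3", "R4"), mat)
  expect_equal(same$p_means, 1)
  expect_equal(same$p_medians, 1)
  expect_error(extra_ribosomal_comparison("R1", c("R2", "R3"), mat), "at least 2")

  # null: both sets drawn from one distribution -> p uniform on [0, 1]
  set.seed(2024)
  ps <- replicate(1000, {
    m <- matrix(rlnorm(16 * 4, 10, 0.5), 16, 4,
                dimnames = list(sprintf("R%02d", 1:16), paste0("D", 1:4)))
    extra_ribosomal_comparison(rownames(m)[1:8], rownames(m)[9:16], m)$p_means
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  # power: clearly separated sets are detected
  m2 <- matrix(c(rlnorm(8 * 4, 5, 0.1), rlnorm(8 * 4, 12, 0.1)), 16, 4,
               byrow = TRUE, dimnames = list(sprintf("R%02d", 1:16),
                                             paste0("D", 1:4)))
  far <- extra_ribosomal_comparison(rownames(m2)[1:8], rownames(m2)[9:16], m2)
  expect_lt(far$p_means, 0.001)
})

test_that("group ribosomal CV separates noisier GFP data from MS data", {
  p <- small_synth(seed = 21, n_proteins = 150, n_ribosomal = 79,
                   datasets = mixed_panel(5, 5))
  p$technique_cv <- c(MS_absolute = 0.69, MS_normalized = 0.69,
                      GFP = 1.03, TAP = 0.8)
  syn <- generate_dataset(p)
  rib <- syn$annotations$protein_id[syn$annotations$is_ribosomal]
  g <- group_ribosomal_cv(syn$abundance, rib, syn$datasets)
  expect_gt(g$mean_cv_percent[g$group == "GFP"],
            g$mean_cv_percent[g$group == "MS"])
})
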