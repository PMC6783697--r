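# Cross-dataset concordance statistics: coefficients of variation,
# per-dataset ribosome estimates from ribosomal-protein stoichiometry,
# pairwise hypothesis-test matrices with Bonferroni and Benjamini-Hochberg
# control, gene-ontology profile similarity, and median-divergence screening
# between dataset groups.

#' Coefficient of variation as a percentage
#'
#' 100 x sample standard deviation (n-1 denominator) / mean. Missing values
#' are dropped first.
#'
#' @param values numeric vector with at least 2 non-missing values and
#'   non-zero mean.
#' @return CV in percent.
#' @examples
#' cv_percent(c(1, 2, 3))  # 50
#' @export
cv_percent <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) stop("need at least 2 non-missing values", call. = FALSE)
  m <- mean(v)
  if (m == 0) stop("mean is zero; CV undefined", call. = FALSE)
  100 * stats::sd(v) / m
}

#' Per-dataset ribosome-count estimates from ribosomal proteins
#'
#' Every ribosomal protein occurs once per ribosome, so each reported
#' ribosomal-protein abundance is an independent observation of the number of
#' ribosomes per cell. The chosen statistic (mean or median) over the
#' non-missing ribosomal-protein abundances of each dataset column gives that
#' dataset's estimate; a column with fewer than 2 values is marked
#' unavailable (some datasets report no ribosomal proteins at all).
#'
#' @param abundance abundance matrix (proteins x datasets).
#' @param ribosomal_ids row names to treat as ribosomal proteins.
#' @param statistic `"mean"` or `"median"`.
#' @return data.frame: dataset_id, statistic, value, sd, n, available.
#' @export
ribosome_estimates <- function(abundance, ribosomal_ids,
                               statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  missing_ids <- setdiff(ribosomal_ids, rownames(abundance))
  if (length(missing_ids)) {
    stop("ribosomal ids absent from matrix: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "), call. = FALSE)
  }
  sub <- abundance[ribosomal_ids, , drop = FALSE]
  fun <- if (statistic == "mean") mean else stats::median
  res <- lapply(colnames(sub), function(d) {
    v <- sub[, d]
    v <- v[!is.na(v)]
    if (length(v) < 2L) {
      data.frame(dataset_id = d, statistic = statistic, value = NA_real_,
                 sd = NA_real_, n = length(v), available = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(dataset_id = d, statistic = statistic, value = fun(v),
                 sd = stats::sd(v), n = length(v), available = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, res)
}

#' Average ribosomal-protein CV per technique group
#'
#' For each dataset, the CV (percent) of the ribosomal-protein abundances it
#' reports; datasets are then grouped by technique family (both MS flavours
#' pooled as "MS") and the group mean CV returned. A consistently measured
#' dataset should show a small ribosomal CV, since every ribosomal protein
#' counts the same ribosome pool.
#'
#' @param abundance abundance matrix (proteins x datasets).
#' @param ribosomal_ids ribosomal-protein row names.
#' @param datasets_meta data.frame with dataset_id and technique.
#' @return data.frame: group, mean_cv_percent, n_datasets.
#' @export
group_ribosomal_cv <- function(abundance, ribosomal_ids, datasets_meta) {
  sub <- abundance[intersect(ribosomal_ids, rownames(abundance)), ,
                   drop = FALSE]
  per_ds <- vapply(colnames(sub), function(d) {
    v <- sub[, d]
    v <- v[!is.na(v)]
    if (length(v) < 2L || mean(v) == 0) NA_real_ else cv_percent(v)
  }, numeric(1))
  grp <- ifelse(datasets_meta$technique %in% c("MS_absolute", "MS_normalized"),
                "MS", datasets_meta$technique)
  grp <- grp[match(names(per_ds), datasets_meta$dataset_id)]
  out <- do.call(rbind, lapply(unique(grp), function(g) {
    v <- per_ds[grp == g]
    data.frame(group = g, mean_cv_percent = mean(v, na.rm = TRUE),
               n_datasets = sum(!is.na(v)), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Welch two-sample t-test (two-sided)
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom,
#' delegated to [stats::t.test()]. Degenerate inputs follow the convention:
#' both samples constant with equal means gives p = 1 (no evidence of a
#' difference); both constant with different means is treated as extreme
#' (p = 0) with a warning.
#'
#' @param x,y numeric vectors, each with >= 2 non-missing values.
#' @return list(t, df, p).
#' @export
welch_t_test <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("both samples need at least 2 non-missing values", call. = FALSE)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    warning("both samples constant with different means; p set to 0",
            call. = FALSE)
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

# U statistic of the first sample from midranks
.u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test (two-sided)
#'
#' U of the first sample from midranks. The p-value is exact -- by full
#' enumeration of the choose(m+n, m) group assignments, so ties are handled
#' correctly -- when the combined sample size is at most `exact_limit`, and
#' uses the normal approximation with tie correction (no continuity
#' correction) otherwise.
#'
#' @param x,y numeric vectors, each non-empty.
#' @param exact_limit combined-size cutoff for the exact enumeration.
#' @return list(U, p, exact).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mann_whitney_u <- function(x, y, exact_limit = 20L) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  m <- length(x); n <- length(y)
  if (m < 1L || n < 1L) stop("both samples must be non-empty", call. = FALSE)
  u <- .u_statistic(x, y)
  mu <- m * n / 2
  if (m + n <= exact_limit) {
    pooled <- c(x, y)
    idx <- utils::combn(m + n, m)
    us <- apply(idx, 2L, function(i) .u_statistic(pooled[i], pooled[-i]))
    # two-sided: as or more extreme in distance from the null mean
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    return(list(U = u, p = p, exact = TRUE))
  }
  nt <- table(c(x, y))
  tie_term <- sum(nt^3 - nt) / ((m + n) * (m + n - 1))
  sigma2 <- m * n / 12 * ((m + n + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = u, p = 1, exact = FALSE))
  z <- (u - mu) / sqrt(sigma2)
  list(U = u, p = 2 * stats::pnorm(-abs(z)), exact = FALSE)
}

#' Pairwise test matrix across datasets with multiplicity control
#'
#' Runs the chosen two-sample test on every unordered pair of sample
#' vectors, then applies two multiple-testing controls to the family of all
#' pair p-values: the Bonferroni rule (significant iff raw p < alpha divided
#' by the number of pairs) and the Benjamini-Hochberg step-up adjustment
#' (significant iff adjusted p < alpha).
#'
#' @param samples named list of numeric vectors, one per dataset; entries
#'   that are NULL or shorter than 2 are skipped as unavailable.
#' @param test `"welch"` or `"mannwhitney"`.
#' @param alpha family-wise alpha (default 0.05).
#' @return data.frame in long format (dataset_a, dataset_b, p_raw,
#'   bonferroni_sig, p_bh, bh_sig) with attributes `n_pairs` and
#'   `bonferroni_alpha`.
#' @export
pairwise_matrix <- function(samples, test = c("welch", "mannwhitney"),
                            alpha = 0.05) {
  test <- match.arg(test)
  keep <- vapply(samples, function(v) length(v[!is.na(v)]) >= 2L, logical(1))
  samples <- samples[keep]
  ids <- names(samples)
  if (length(ids) < 2L) stop("need at least 2 datasets with samples", call. = FALSE)
  pairs <- utils::combn(ids, 2L)
  n_pairs <- ncol(pairs)
  p_raw <- vapply(seq_len(n_pairs), function(k) {
    a <- samples[[pairs[1L, k]]]
    b <- samples[[pairs[2L, k]]]
    if (test == "welch") welch_t_test(a, b)$p else mann_whitney_u(a, b)$p
  }, numeric(1))
  p_bh <- stats::p.adjust(p_raw, method = "BH")
  out <- data.frame(
    dataset_a = pairs[1L, ], dataset_b = pairs[2L, ],
    p_raw = p_raw,
    bonferroni_sig = p_raw < alpha / n_pairs,
    p_bh = p_bh,
    bh_sig = p_bh < alpha,
    stringsAsFactors = FALSE
  )
  attr(out, "n_pairs") <- n_pairs
  attr(out, "bonferroni_alpha") <- alpha / n_pairs
  out
}

#' Gene-ontology class profiles of top protein lists
#'
#' Counts, for each dataset's top-by-mass protein list, how many listed
#' proteins carry each functional ontology class; a protein counts toward
#' every class it is annotated with.
#'
#' @param top_lists named list (one per dataset) of protein id vectors.
#' @param go_classes named list mapping protein id to a character vector of
#'   classes (possibly empty).
#' @return named list of named integer count vectors (the profile support is
#'   exactly the classes with positive counts).
#' @export
ontology_profiles <- function(top_lists, go_classes) {
  lapply(top_lists, function(ids) {
    missing <- setdiff(ids, names(go_classes))
    if (length(missing)) {
      stop("no ontology annotation for: ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    }
    cls <- unlist(go_classes[ids], use.names = FALSE)
    if (!length(cls)) return(integer(0))
    tab <- table(cls)
    stats::setNames(as.integer(tab), names(tab))
  })
}

#' Pearson correlation between two ontology profiles
#'
#' Profiles are aligned on the union of their classes (absent class = count
#' 0) before computing Pearson's r. Zero variance on either side leaves r
#' undefined (NA).
#'
#' @param p1,p2 named count vectors from [ontology_profiles()].
#' @return correlation in [-1, 1], or NA when undefined.
#' @export
profile_pearson <- function(p1, p2) {
  classes <- union(names(p1), names(p2))
  if (length(classes) < 2L) {
    stop("need at least 2 classes across the two profiles", call. = FALSE)
  }
  v1 <- ifelse(classes %in% names(p1), p1[classes], 0)
  v2 <- ifelse(classes %in% names(p2), p2[classes], 0)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) return(NA_real_)
  stats::cor(v1, v2, method = "pearson")
}

#' Jaccard index of two class sets
#'
#' |intersection| / |union|; both sets empty gives 1 by convention.
#'
#' @param set1,set2 character vectors (treated as sets).
#' @return value in [0, 1].
#' @examples
#' ontology_jaccard(c("a", "b", "c"), c("b", "c", "d"))  # 0.5
#' @export
ontology_jaccard <- function(set1, set2) {
  set1 <- unique(set1); set2 <- unique(set2)
  u <- length(union(set1, set2))
  if (u == 0L) return(1)
  length(intersect(set1, set2)) / u
}

#' Fraction of proteins whose group medians diverge
#'
#' Compares two aligned vectors of per-protein medians (e.g. GFP-group vs
#' MS-group medians). A protein is divergent when the symmetric relative
#' difference |mA - mB| / ((mA + mB)/2) exceeds `threshold`; with
#' `denominator = "a"` or `"b"` the difference is taken relative to that
#' group's median instead. Two zero medians are never divergent.
#'
#' @param medians_a,medians_b aligned numeric vectors (same proteins, same
#'   order); pairs with a missing value are dropped.
#' @param threshold relative-difference cutoff in (0, 1); may be 0 to flag
#'   any inequality.
#' @param denominator `"symmetric"` (default), `"a"` or `"b"`.
#' @return list(fraction, divergent = logical flags, n).
#' @export
median_divergence <- function(medians_a, medians_b, threshold = 0.25,
                              denominator = c("symmetric", "a", "b")) {
  denominator <- match.arg(denominator)
  stopifnot(length(medians_a) == length(medians_b))
  if (threshold < 0 || threshold >= 1) {
    stop("threshold must lie in [0, 1)", call. = FALSE)
  }
  ok <- !is.na(medians_a) & !is.na(medians_b)
  a <- medians_a[ok]; b <- medians_b[ok]
  den <- switch(denominator,
                symmetric = (a + b) / 2,
                a = a,
                b = b)
  rel <- ifelse(a == 0 & b == 0, 0, abs(a - b) / den)
  flags <- rel > threshold
  list(fraction = if (length(flags)) mean(flags) else 0,
       divergent = flags, n = length(flags))
}

#' Compare ribosomal proteins with and without extra-ribosomal roles
#'
#' Splits the ribosomal proteins into two sets (e.g. those with reported
#' extra-ribosomal functions vs the rest), summarises each protein by its
#' mean (and, separately, median) abundance across datasets, and Welch-tests
#' the two sets of per-protein summaries. Similar abundance distributions
#' argue that moonlighting does not inflate the ribosome-count estimate.
#'
#' @param set1_ids,set2_ids protein id vectors, each of size >= 2, rows of
#'   `abundance`.
#' @param abundance abundance matrix (proteins x datasets).
#' @return list(p_means, p_medians, summary = per-protein data.frame).
#' @export
extra_ribosomal_comparison <- function(set1_ids, set2_ids, abundance) {
  if (length(set1_ids) < 2L || length(set2_ids) < 2L) {
    stop("both sets need at least 2 proteins", call. = FALSE)
  }
  all_ids <- c(set1_ids, set2_ids)
  missing <- setdiff(all_ids, rownames(abundance))
  if (length(missing)) {
    stop("ids absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  summarise <- function(ids, fun) {
    apply(abundance[ids, , drop = FALSE], 1L, function(v) fun(v[!is.na(v)]))
  }
  m1 <- summarise(set1_ids, mean);        m2 <- summarise(set2_ids, mean)
  md1 <- summarise(set1_ids, stats::median); md2 <- summarise(set2_ids, stats::median)
  list(
    p_means = welch_t_test(m1, m2)$p,
    p_medians = welch_t_test(md1, md2)$p,
    summary = data.frame(
      protein_id = all_ids,
      set = rep(c("set1", "set2"), c(length(set1_ids), length(set2_ids))),
      mean_abundance = c(m1, m2),
      median_abundance = c(md1, md2),
      stringsAsFactors = FALSE
    )
  )
}
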