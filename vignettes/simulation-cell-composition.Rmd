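---
title: "Defining the contents of a crowded yeast-cytoplasm simulation cell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining the contents of a crowded yeast-cytoplasm simulation cell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytocell)
```

## The problem

Molecular simulations of the cytoplasm need a periodic box whose contents
reproduce the crowded environment of a living cell: which protein species to
include, at what copy numbers, how many tRNAs, and how large the box should
be. For budding yeast, the raw material is a collection of genome-wide
protein-abundance datasets measured by different techniques (absolute and
normalized mass spectrometry, GFP-fusion microscopy, TAP immunoblotting)
under different growth conditions. These datasets disagree substantially, so
defining a simulation cell involves three stages, each implemented as a
package module:

1. **Concordance analysis** — quantify how well the datasets agree, decide
   which to trust.
2. **Physical cell model** — convert agreed-on abundances into ribosome
   counts, volumes, masses and densities.
3. **Composition building** — search for the smallest abundance scaling
   that yields an integer-copy-number box satisfying the physical
   constraints.

Because the full multi-study compendium is external data, the package also
ships a first-class synthetic generator (`generate_dataset()`) whose ground
truth makes every downstream stage testable.

## Ribosomes as an internal yardstick

The ribosome's protein composition is fixed: 79 distinct proteins, each
present once per 80S particle. Every reported ribosomal-protein abundance is
therefore an independent observation of the cellular ribosome count, and the
spread of these observations within a dataset measures its internal
consistency (`ribosome_estimates()`, `group_ribosomal_cv()`). Treating the
per-dataset ribosomal abundances as samples, all dataset pairs are compared
with two-sided Welch tests (unequal variances, Welch–Satterthwaite degrees
of freedom) and, without the normality assumption, Mann–Whitney U tests.
Both multiplicity controls are reported side by side
(`pairwise_matrix()`): the Bonferroni rule divides the family alpha by the
number of unordered pairs — 190 when 20 datasets are compared — and the
Benjamini–Hochberg step-up adjustment controls the false-discovery rate. By
construction every Bonferroni-significant pair is also BH-significant at
the same alpha, which the tests assert as an invariant.

Two further concordance views do not depend on abundance scale at all: the
gene-ontology class profiles of each dataset's top-200-by-mass proteins,
compared by Pearson correlation of class counts and by the Jaccard index of
class sets, and the fraction of proteins whose GFP-group and MS-group
median abundances diverge by more than 25%. For the divergence we use the
symmetric relative difference |mA − mB| / ((mA + mB)/2), which is
direction-free; one-sided denominators are available via the `denominator`
argument.

## The physical cell model

Constants with defaults (all overridable in `cell_parameters()`):

| parameter | default | unit | meaning |
|---|---|---|---|
| `cell_volume` | 42 | µm³ | haploid cell volume |
| `cytoplasm_fraction` | 0.65 | — | cytoplasmic share of cell volume |
| `n_trna_cell` | 3×10⁶ | copies | tRNA pool per cell |
| `trna_nucleotides` | 75 | nt | average tRNA length |
| `nucleotide_mass` | 340 | Da | average nucleotide mass |
| `target_rib_cyt` | 0.2229 | — | ribosomal-to-cytoplasmic protein mass ratio |
| `target_density` | 90 | g/L | macromolecular density target |

The rib/cyt ratio is treated as a growth-rate-determined constant of the
cell: ribosome concentration tracks growth rate, so at a fixed growth rate
the mass of ribosomal protein is a fixed multiple of the cytoplasmic
protein mass, and the one-ribosome box must inherit that ratio. The two
per-ribosome masses (`ribosome_protein_mass`, protein moiety only, the
rib/cyt numerator; `ribosome_total_mass`, rRNA-inclusive, the density
contribution) have **no defaults**: published figures differ and the
density budget is sensitive to them, so they must be supplied explicitly.
The packaged `cell_params_example.json` carries literature-derived
approximations (1.4 MDa / 3.3 MDa) clearly labeled as example values.

Unit conversions use 1 Da = 1/6.0221408×10²³ g (inverse Avogadro, so a
mole of daltons weighs exactly one gram) and 1 µm³ = 10⁻¹⁵ L. Scaling the
27.3 µm³ cytoplasm to one ribosome gives a cubic box edge of
(V_cyt/N_rib)^(1/3); with ~126,000–150,000 ribosomes per cell this is
560–600 Å. Counts (box tRNAs, protein copies) are rounded **half away from
zero** everywhere; `box_length()` and `trna_count_box()` accept explicit
overrides for externally fixed geometries.

## The composition search

Whole-cell abundances are scaled to one ribosome's share
(`per_ribosome_abundance()`: n_i / N_rib), ranked by per-cell mass
(molecular mass × abundance, ties broken alphabetically), and converted to
integer copies c_i = round(s · a_i). Rounding drops every species below
0.5/s copies per box, which collectively removes a large slice of protein
mass; the scaling factor s compensates. The search
(`search_min_scaling()`) asks, for the top K ranked types:

* rib/cyt constraint: |m_rib,prot / Σc_i m_i − r*| / r* ≤ 2%
* density constraint: |(Σc_i m_i + m_ribosome + n_tRNA·m_tRNA)/V_box − ρ*| / ρ* ≤ 2%

and returns the smallest s on an ascending grid (default 1.000–5.000 by
0.001) with a feasible K, then the smallest such K. Minimising s first
keeps the composition closest to the measured relative abundances; a large
s would reach the mass targets with only a handful of dominant species.
Grid search is used deliberately: the objective is stepwise in s because
of rounding, so root-finding has no gradient to follow, and refining the
grid step can only lower the returned s (asserted as a property test). The
tolerances are relative bands (default 2%, configurable in
`builder_config()`); with exact equality almost no integer composition
would be admissible. Infeasibility is reported with the binding constraint
named.

When the targets themselves are derived from the same proteome
(`derive_targets()` — the ratio and density implied by the data at hand),
the search must succeed: this self-consistency is the package's strongest
end-to-end check and holds for 1,000 generator seeds in the test suite.

## What the synthetic generator emulates

`synth_params()` defaults describe a compendium-scale study: 5,391 proteins
(79 ribosomal) × 21 datasets (5 absolute MS, 6 normalized MS, 9 GFP, 1
TAP), true ribosome count 150,000 (mid-range of classical estimates),
log-normal copy numbers (median ≈ 3,000 copies/cell, sdlog 2, spanning the
observed 1–10⁶ range), and 10% missing entries. Technique effects are
multiplicative: GFP tagging under-reports ribosomal proteins (bias 0.4,
reproducing ~60,000-ribosome GFP estimates against an unbiased MS pool)
and normalized MS shrinks them further (0.24); GFP noise (CV 1.03) exceeds
MS noise (0.69). With those dispersions the generated compendium reproduces
the expected qualitative pattern — per-protein CVs near 80% for cytoplasmic
and ~100% for ribosomal proteins under GFP — which the acceptance tests
verify as an ordering, not as exact values.

Noise is log-normal with **unit median** (meanlog 0, sdlog chosen so the
noise CV equals `technique_cv`). The unit-median choice makes median-based
estimators unbiased under noise, matching the pipeline's pooled-median
ribosome estimator; a unit-mean parameterisation would bias medians low by
~10% at CV 0.5. Missingness is completely at random per matrix cell;
molecular masses are uniform over `mass_range` (they only enter through
products, so the distribution shape is immaterial to correctness);
compartments are assigned so that 70% of non-ribosomal proteins are
non-cytoplasmic, matching the share removed by compartment filtering in a
full proteome.

What the generator does **not** model: correlated missingness (real GFP
libraries miss specific protein classes), condition-dependent expression
differences between media and growth phases, abundance-correlated
annotation depth, and mechanistic effects of tagging on protein stability.
Passing tests therefore demonstrate the statistical machinery and the
constraint search are correct, not that any particular real compendium
satisfies the generator's assumptions.

## Filtering and ranking conventions

A protein is excluded from the cytoplasmic set when **any** of its GO-slim
compartments is in the exclusion list (nucleus, cell wall, ribosome,
mitochondrion, ER, vacuole by default): conservative exclusion avoids
counting organellar mass in the cytoplasmic budget even for dually
localised proteins. Ribosomal proteins are partitioned separately — they
are never cytoplasmic "protein types" because the box already contains the
assembled ribosome. The abundance statistic for ranking is the per-protein
median across the selected datasets (robust to a single outlier dataset);
proteins with no abundance in the selected columns are excluded with a
warning. Identifier matching is case-insensitive with no alias resolution.

## Numerical and degenerate-input conventions

* Welch test with two constant samples: p = 1 at equal means (no evidence),
  p = 0 with a warning otherwise; fewer than 2 values per side is an error.
* Mann–Whitney: exact p by full enumeration of group assignments (ties
  handled correctly) up to combined n = 20, tie-corrected normal
  approximation beyond; U is reported for the first sample from midranks.
* CV requires ≥ 2 values and non-zero mean; it is scale-invariant.
* Pearson profile correlation aligns on the class union with zero fill and
  is undefined (NA) for zero-variance profiles; Jaccard of two empty sets
  is 1.
* Median divergence with both medians zero is non-divergent.
* All counts round half away from zero.

## Problem sizes used in the checks

The test-suite and acceptance-script replicate counts are the package's
validation design: 200 randomized small systems (≤ 10 types) for the
search-vs-enumeration equivalence, 500 seeds for ribosome-count recovery
(79 ribosomal proteins, 5 unbiased MS datasets, noise CV 0.3 — moderate
dispersion, chosen so the pooled median's sampling error is well inside
the 5% recovery band), 1,000 seeds (500 in the script) for builder
self-consistency at 1,000 proteins, 10,000 null replicates for the Welch
type-I rate, and 200 seeds for the GFP-vs-MS dispersion ordering at 5 + 5
datasets.

## Known limitations

* The composition always takes a prefix of the mass ranking; skipping
  mid-ranking species is not explored.
* The box contains proteins, tRNAs and one ribosome only — no mRNA, DNA,
  lipids, metabolites or water chemistry — and no 3D coordinates are
  produced.
* GO-class profiles count local annotations; no enrichment statistics are
  computed.
* Whether the density budget should use the protein-only or rRNA-inclusive
  ribosome mass is genuinely ambiguous in the literature this workflow
  descends from; both masses are explicit config so either convention is
  one argument away.
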