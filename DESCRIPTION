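Package: cytocell
Title: Defining the Macromolecular Contents of a Yeast Cytoplasm Simulation Cell
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for deriving the minimal molecular contents of a
    crowded yeast-cytoplasm simulation box from integrated proteomics
    copy-number data. Provides a synthetic proteomics generator with
    known ground truth, ingestion and GO-slim compartment filtering of
    abundance tables, cross-dataset concordance statistics (coefficients
    of variation, ribosome-count estimates from ribosomal-protein
    stoichiometry, pairwise Welch and Mann-Whitney test matrices with
    Bonferroni and Benjamini-Hochberg control, ontology-profile
    similarity), physical cell-parameter calculations (cytoplasm volume,
    macromolecular density, box size, tRNA scaling), and a
    constraint-based search for the smallest abundance scaling factor
    that satisfies target density and ribosomal-to-cytoplasmic mass
    ratio in a one-ribosome simulation cell.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
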