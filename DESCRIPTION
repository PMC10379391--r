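Package: PaleoVar
Title: Cross-Species and Paleogenomic Archaeology of Germline Variants
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to trace the evolutionary origin of human germline
    variants along two complementary axes. First, a ClinVar-style catalog of
    pathogenic and benign variants is projected through a multi-species
    whole-genome alignment (MAF) to score cross-species allele sharing per
    species and per clade. Second, a damage-aware pileup genotyper calls the
    same locus in ancient-human samples, intersects calls with the catalog,
    and dates each variant by its oldest ancient carrier. Per-species sharing
    rates of the pathogenic and benign classes are compared with an exact
    (tie-aware) Mann-Whitney U test. A seeded synthetic-data module evolves
    sequences along a phylogeny, emits MAF alignments with strand-annotated
    rows, plants variant catalogs with known sharing truth, and simulates
    ancient pileups with terminal cytosine-deamination damage, so that every
    stage is testable end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    ape,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, Phylogenetics, VariantAnnotation, Alignment
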