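Package: plastomics
Title: Plastome Assembly Finishing, Structural Variants, and Organellar HGT Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for finishing circular plastid genome (plastome) assemblies and
    analysing their structure and evolution. Includes a seeded synthetic-data
    generator that emulates grass plastomes (quadripartite LSC/IRb/SSC/IRa layout,
    AT-rich base composition, planted structural variants, Illumina-style reads),
    anchored scaffolding and exact-overlap gap closure with read re-mapping
    assessment, inverted-repeat detection and quadripartite canonicalization,
    annotation transfer by local alignment, anchored pairwise alignment with
    detection of large indels and inversions and their stem-loop flanking repeats,
    synapomorphy mapping onto a phylogeny, verification of putative
    mitochondrion-to-plastid horizontal transfers (origin classification, junction
    coverage, base-composition contrast, in-silico PCR), and phylogenomic
    supermatrix construction with inverted-repeat exclusion, inversion masking and
    gap-column stripping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
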