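Package: EFPcontext
Title: Comparative Genomic Context Analysis of EF-P Modification Gene Families
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Comparative-genomics pipeline for predicting post-translational
    modification partners of bacterial elongation factor P (EF-P). Assigns
    protein-coding genes to the efp, yjeA, yjeK, ablA (lysine 2,3-aminomutase)
    and ablB families by local alignment, classifies per-genome physical
    clustering of efp/yjeA/yjeK (operon, pairwise, none), builds phyletic
    presence/absence profiles with co-occurrence summaries, measures
    motif-anchored conservation of the EF-P Lys34 residue with sequence-logo
    information content, and disambiguates the YjeK and LAM subfamilies with
    neighbor-joining trees on Jones-Taylor-Thornton maximum-likelihood
    distances, column bootstrap and genomic-context labels. Includes a
    synthetic annotated-genome generator with known ground truth so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse,
    withr
biocViews: ComparativeGenomics, Phylogenetics, SequenceMatching, Alignment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
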