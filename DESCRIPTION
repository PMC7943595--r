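Package: uorfsel
Title: Selection Analysis of Variants in Translated Upstream Open Reading Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reading-frame-aware consequence annotation of single-nucleotide
    variants in translated upstream open reading frames (uORFs) and other
    non-canonical ORFs, together with the population-genetic and phenotypic
    analyses used to detect selection on them: the mutability-adjusted
    proportion of singletons (MAPS) statistic with trinucleotide-context
    calibration and bootstrap inference, stop-codon usage permutation tests,
    phyloP conserved-base-proportion analyses with distance-matched controls,
    and a covariate-adjusted logistic PheWAS / gene-burden association layer
    with inverse-variance-weighted meta-analysis. A synthetic-data module
    generates every input format with known ground truth so each stage has a
    parameter-recovery test and the full pipeline runs end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    S4Vectors,
    IRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
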