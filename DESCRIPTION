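Package: pedflow
Title: Genome-Flow Analysis of Crop Breeding Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing the flow of genomic segments through a crop
    breeding pedigree from multi-sample SNP data. Implements sliding-window
    identity-by-descent (IBD) detection by SNP identity ratio, origin tracing
    and per-ancestor genomic contribution accounting, common-IBD intersection
    across descendants and overlap with trait loci; windowed nucleotide
    diversity, Fst, SNP density, zero-diversity segments, LD decay and
    neighbour-joining trees; selective-sweep scans by between-group pi ratio
    confirmed with cross-population extended haplotype homozygosity (XP-EHH);
    SNP effect annotation with dN/dS; and candidate-SNP association under a
    PCA + kinship mixed model. A pedigree genotype simulator with recorded
    recombination ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    ape,
    vcfR,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
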