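Package: genetriage
Title: Candidate Disease Gene Prioritization from Phenotype-Associated Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts and prioritizes candidate disease genes within
    phenotype-associated genetic loci (linkage intervals or GWAS SNPs).
    Two complementary engines are provided: common pathway scanning,
    which scores pathway and protein-complex membership shared with known
    disease genes (or across loci, ab initio) by the one-sided Fisher's
    exact test and direct protein-protein interaction evidence; and
    common module profiling, which scores shared protein-domain content
    by Smith-Waterman similarity of same-family domain instances (seeded)
    or by a conservative chi-square over-representation statistic across
    loci (ab initio). Includes SNP-to-gene search-space construction
    (adjacent and windowed bystander mappings), readers for BED/GMT/TSV/
    FASTA reference data, a deterministic synthetic-reference generator
    with planted-truth cases for offline validation, and a pipeline that
    writes ranked tab-separated prediction reports.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
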