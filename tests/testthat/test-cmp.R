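# Common module profiling: alignment scores, domain similarity and
# ab initio over-representation.

test_that("local alignment handles hand cases exactly", {
  sch <- scoring_scheme("BLOSUM62", 11, 1)
  expect_equal(smith_waterman("", "ACDEF", sch), 0)
  expect_equal(smith_waterman("ACDEF", "", sch), 0)
  # ungapped identity: 4 + 9 + 6 on the BLOSUM62 diagonal
  expect_equal(smith_waterman("ACD", "ACD", sch), 19)
  expect_equal(smith_waterman("ACD", "AXD", sch),
               smith_waterman("AXD", "ACD", sch))
})

test_that("DP scores equal exhaustive enumeration on random tiny pairs", {
  sch <- toy_scheme()
  set.seed(31)
  for (i in 1:300) {
    a <- paste(sample(c("A", "C", "D"), sample(0:5, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "D"), sample(0:5, 1), TRUE),
               collapse = "")
    expect_equal(smith_waterman(a, b, sch),
                 smith_waterman_enumerate(a, b, sch))
  }
})

test_that("DP scores are symmetric and agree with an independent aligner", {
  sch <- scoring_scheme("BLOSUM62", 11, 1)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(13)
  for (i in 1:25) {
    a <- paste(sample(aa, sample(8:30, 1), TRUE), collapse = "")
    b <- paste(sample(aa, sample(8:30, 1), TRUE), collapse = "")
    got <- smith_waterman(a, b, sch)
    expect_equal(smith_waterman(b, a, sch), got)
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = BLOSUM62,
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(got, ref)
  }
})

test_that("scoring schemes validate their inputs and read NCBI files", {
  m <- matrix(c(1, 2, 3, 1), 2, 2, dimnames = list(c("A", "C"),
                                                   c("A", "C")))
  expect_error(scoring_scheme(m), "symmetric")
  expect_error(toy_scheme(gap_open = 1, gap_extend = 2), "gap_extend")
  expect_error(scoring_scheme("NOSUCHMATRIX"), "unknown")
  dir <- withr::local_tempdir()
  writeLines(c("# toy matrix", "   A  C  D",
               "A  3 -2 -2", "C -2  3 -2", "D -2 -2  3"),
             file.path(dir, "toy.mat"))
  sch <- scoring_scheme(file.path(dir, "toy.mat"), gap_open = 2,
                        gap_extend = 1)
  expect_equal(smith_waterman("ACD", "ACD", sch), 9)
})

test_that("domain similarity is self-normalized to [0, 1]", {
  b <- toy_bundle()
  d <- b$domains
  hit <- function(pid) d[d$protein_id == pid, , drop = FALSE]
  # P01 and P03 carry identical FA instances ("AAAA")
  s <- domain_similarity(hit("P01"), hit("P03"), b)
  expect_equal(s$s_norm, 1.0)
  # P02 vs P04 share FB with one substitution: 0 < s_norm < 1
  s2 <- domain_similarity(hit("P02"), hit("P04"), b)
  expect_gt(s2$s_norm, 0)
  expect_lt(s2$s_norm, 1)
  expect_equal(s2$raw_score / max(s2$self_a, s2$self_b), s2$s_norm)
  expect_error(domain_similarity(hit("P01"), hit("P02"), b),
               "different families")
  ghost <- hit("P01")
  ghost$protein_id <- "P99"
  expect_error(domain_similarity(ghost, hit("P03"), b), "missing protein")
})

test_that("seeded CMP takes the maximum over shared families and seeds", {
  genes <- toy_genes()
  proteins <- data.frame(
    protein_id = c("PA", "PB"), gene_id = c("G01", "G09"),
    residues = c("AAAACCCC", "AAAACCDC"), stringsAsFactors = FALSE)
  domains <- data.frame(
    protein_id = c("PA", "PA", "PB", "PB"),
    family_id = c("F1", "F2", "F1", "F2"),
    ali_start = c(0, 4, 0, 4), ali_end = c(4, 8, 4, 8),
    bit_score = 1, stringsAsFactors = FALSE)
  b <- reference_bundle(genes, proteins = proteins, domains = domains)
  space <- build_search_space(
    list(L1 = interval_spec("explicit", chrom = "chr1", start = 0,
                            end = 250)), "intervals", b)
  res <- cmp_seeded(space, "G09", b)
  expect_equal(res$gene_id, "G01")
  # F1 instances are identical (S = 1); F2 differ; the max rule reports F1
  expect_equal(res$statistic, 1.0)
  expect_equal(res$evidence_id, "F1")
  expect_equal(res$seed_genes, "G09")
  # s_min above the best score suppresses the prediction
  expect_equal(nrow(cmp_seeded(space, "G09", b, s_min = 1.01)), 0)
  # no shared family with any seed: nothing predicted
  res2 <- cmp_seeded(space, "G10", b)
  expect_equal(nrow(res2), 0)
})

test_that("seeded CMP is invariant to seed and hit order", {
  b <- toy_bundle()
  space <- build_search_space(
    list(L1 = interval_spec("explicit", chrom = "chr1", start = 0,
                            end = 1000)), "intervals", b)
  r1 <- cmp_seeded(space, c("G09", "G10"), b)
  r2 <- cmp_seeded(space, c("G10", "G09"), b)
  expect_identical(r1, r2)
  b2 <- b
  perm <- rev(seq_len(nrow(b2$domains)))
  b2$domains <- b2$domains[perm, , drop = FALSE]
  rownames(b2$domains) <- NULL
  r3 <- cmp_seeded(space, c("G09", "G10"), b2)
  expect_identical(r1$gene_id, r3$gene_id)
  expect_identical(r1$statistic, r3$statistic)
})

test_that("chi-square components follow the defining arithmetic", {
  expect_equal(chi2_component(5, 5), 0)
  expect_equal(chi2_component(5, 1), 16)
  expect_equal(chi2_component(2, 1), 1)
  expect_error(chi2_component(3, 0), "expected count")
})

# 250 regular genes, 10 disjoint 5-gene loci; three planted families with
# exactly known counts: F_GOOD (5 bearers in 5 loci), F_PARA (5 bearers
# in one locus), F_UNDER (50 bearers, 2 in the space).
cmp_fixture <- function() {
  i <- 1:250
  genes <- data.frame(
    gene_id = sprintf("R%03d", i), symbol = sprintf("r%03d", i),
    chrom = "chr1", start = (i - 1) * 1000, end = (i - 1) * 1000 + 500,
    strand = rep(c("+", "-"), 125), stringsAsFactors = FALSE)
  # loci j = 1..10 cover genes 10(j-1)+1 .. 10(j-1)+5
  locus_gene <- function(j, k) sprintf("R%03d", 10 * (j - 1) + k)
  bearers <- c(
    vapply(1:5, function(j) locus_gene(j, 1), ""),     # F_GOOD
    vapply(1:5, function(k) locus_gene(1, k), ""),     # F_PARA
    sprintf("R%03d", 101:150),                          # F_UNDER outside
    locus_gene(6, 2), locus_gene(7, 2))                 # F_UNDER inside
  fams <- c(rep("F_GOOD", 5), rep("F_PARA", 5), rep("F_UNDER", 52))
  prot <- unique(bearers)
  proteins <- data.frame(
    protein_id = paste0("p_", prot), gene_id = prot,
    residues = "AAAAAAAAAA", stringsAsFactors = FALSE)
  domains <- data.frame(
    protein_id = paste0("p_", bearers), family_id = fams,
    ali_start = 0, ali_end = 5, bit_score = 1, stringsAsFactors = FALSE)
  b <- reference_bundle(genes, proteins = proteins, domains = domains)
  specs <- lapply(1:10, function(j)
    interval_spec("explicit", chrom = "chr1",
                  start = (10 * (j - 1)) * 1000,
                  end = (10 * (j - 1) + 4) * 1000 + 500))
  names(specs) <- sprintf("L%02d", 1:10)
  space <- build_search_space(specs, "intervals", b)
  list(bundle = b, space = space)
}

test_that("ab initio CMP scores planted families with exact arithmetic", {
  fx <- cmp_fixture()
  expect_equal(fx$space$universe_n, 50)
  res <- cmp_ab_initio(fx$space, fx$bundle)
  e <- res$enrichments
  good <- e[e$family_id == "F_GOOD", ]
  # K = 5, e = 50 * 5 / 250 = 1; o_gene = o_locus = 5 -> chi2 = 16
  expect_equal(good$e, 1)
  expect_equal(good$o_gene, 5)
  expect_equal(good$o_locus, 5)
  expect_equal(good$chi2_min, 16)
  expect_equal(good$direction, "over")
  expect_true(good$retained)
  # the within-locus paralog cluster collapses to one observation
  para <- e[e$family_id == "F_PARA", ]
  expect_equal(para$o_gene, 5)
  expect_equal(para$o_locus, 1)
  expect_equal(para$chi2_locus, 0)
  expect_equal(para$chi2_min, 0)
  expect_false(para$retained)
  # under-represented families are never predicted
  und <- e[e$family_id == "F_UNDER", ]
  expect_equal(und$direction, "under")
  expect_false(und$retained)
  expect_setequal(res$predictions$gene_id,
                  vapply(1:5, function(j) sprintf("R%03d", 10 * (j - 1) + 1),
                         ""))
  expect_true(all(res$predictions$statistic == 16))
  # component inequality holds everywhere
  expect_true(all(e$chi2_min <= e$chi2_gene + 1e-12))
  expect_true(all(e$chi2_min <= e$chi2_locus + 1e-12))
})

test_that("promiscuous families can be filtered by universe frequency", {
  fx <- cmp_fixture()
  res <- cmp_ab_initio(fx$space, fx$bundle,
                       max_family_universe_freq = 0.05)
  expect_false("F_UNDER" %in% res$enrichments$family_id)  # 52/250 > 5%
  expect_true("F_GOOD" %in% res$enrichments$family_id)
})

test_that("family-pair combinations count same-protein co-occurrence", {
  genes <- toy_genes()
  proteins <- data.frame(
    protein_id = c("PA", "PB", "PC"),
    gene_id = c("G01", "G03", "G09"),
    residues = "AAAAAAAA", stringsAsFactors = FALSE)
  domains <- data.frame(
    protein_id = c("PA", "PA", "PB", "PB", "PC"),
    family_id = c("F1", "F2", "F1", "F2", "F1"),
    ali_start = c(0, 4, 0, 4, 0), ali_end = c(4, 8, 4, 8, 4),
    bit_score = 1, stringsAsFactors = FALSE)
  b <- reference_bundle(genes, proteins = proteins, domains = domains)
  space <- build_search_space(
    list(A = interval_spec("explicit", chrom = "chr1", start = 0,
                           end = 250),
         B = interval_spec("explicit", chrom = "chr1", start = 450,
                           end = 750)), "intervals", b)
  res <- cmp_ab_initio(space, b, chi2_threshold = 0, combinations = "pairs")
  e <- res$enrichments
  expect_equal(e$family_id, "F1+F2")
  expect_equal(e$K, 2)        # only PA and PB carry both on one protein
  expect_equal(e$o_gene, 2)
  expect_equal(e$o_locus, 2)
})
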