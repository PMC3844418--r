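# Locus construction and SNP-to-gene mappings.

test_that("marker-pair intervals are order-insensitive and cover both ends", {
  b <- toy_bundle()
  s1 <- interval_spec("marker_pair", marker_start_id = "M1",
                      marker_end_id = "M2")
  s2 <- interval_spec("marker_pair", marker_start_id = "M2",
                      marker_end_id = "M1")
  iv1 <- resolve_interval(s1, b)
  iv2 <- resolve_interval(s2, b)
  expect_equal(iv1, iv2)
  expect_equal(iv1$start, 600)
  expect_equal(iv1$end, 1001)
})

test_that("center-width intervals use floor halves and clip at zero", {
  g <- data.frame(gene_id = "GX", symbol = "gx", chrom = "chr1",
                  start = 10, end = 20, strand = "+",
                  stringsAsFactors = FALSE)
  m <- data.frame(marker_id = c("C1", "C2"), kind = "snp", chrom = "chr1",
                  pos = c(500000, 2000000), stringsAsFactors = FALSE)
  b <- reference_bundle(g, markers = m)
  iv <- resolve_interval(interval_spec("center_width",
                                       center_marker_id = "C1",
                                       width_bp = 1e6), b)
  expect_equal(c(iv$start, iv$end), c(0, 1e6))
  iv2 <- resolve_interval(interval_spec("center_width",
                                        center_marker_id = "C2",
                                        width_bp = 1e6), b)
  expect_equal(c(iv2$start, iv2$end), c(1500000, 2500000))
  expect_error(resolve_interval(interval_spec("center_width",
                                              center_marker_id = "C1",
                                              width_bp = 0), b), "width")
  expect_error(resolve_interval(interval_spec("marker_pair",
                                              marker_start_id = "C1",
                                              marker_end_id = "nope"), b),
               "unknown marker")
})

test_that("cross-chromosome marker pairs are rejected", {
  b <- toy_bundle()
  expect_error(resolve_interval(
    interval_spec("marker_pair", marker_start_id = "M1",
                  marker_end_id = "M5"), b), "different chromosomes")
})

test_that("build_locus collects exactly the overlapping genes", {
  b <- toy_bundle()
  loc <- build_locus(interval_spec("explicit", chrom = "chr1", start = 350,
                                   end = 1050), b, "L1")
  expect_equal(loc$gene_ids, c("G02", "G03", "G04", "G05"))
  expect_warning(
    empty <- build_locus(interval_spec("explicit", chrom = "chr1",
                                       start = 210, end = 290), b, "L2"),
    "no genes")
  expect_length(empty$gene_ids, 0)
})

test_that("random interval specs match the brute-force scan", {
  set.seed(77)
  g <- random_gene_table(60)
  mk <- data.frame(marker_id = sprintf("K%02d", 1:20), kind = "snp",
                   chrom = paste0("chr", sample(2, 20, replace = TRUE)),
                   pos = sample(50000, 20), stringsAsFactors = FALSE)
  b <- reference_bundle(g, markers = mk)
  for (i in 1:30) {
    chrom <- paste0("chr", sample(2, 1))
    st <- sample(50000, 1)
    en <- st + sample(5000, 1)
    loc <- suppressWarnings(build_locus(
      interval_spec("explicit", chrom = chrom, start = st, end = en),
      b, "L"))
    expect_identical(loc$gene_ids,
                     oracle_interval(b$genes, chrom, st, en)$gene_id)
  }
})

test_that("adjacent mapping returns containing gene plus four flankers", {
  b <- toy_bundle()
  # M1 at 600 sits inside G03; flankers: L+ G01, L- G02, R+ G05, R- G04
  got <- map_snp_adjacent("M1", b)
  expect_equal(got$gene_id, c("G01", "G02", "G03", "G04", "G05"))
  # intergenic SNP at 950: no containing gene, exactly 4 flankers
  got2 <- map_snp_adjacent("M3", b)
  expect_equal(got2$gene_id, c("G03", "G04", "G05", "G06"))
})

test_that("adjacent mapping degrades gracefully on sparse chromosomes", {
  g <- data.frame(gene_id = c("GA", "GB"), symbol = c("ga", "gb"),
                  chrom = "chr1", start = c(100, 300),
                  end = c(200, 400), strand = "+",
                  stringsAsFactors = FALSE)
  m <- data.frame(marker_id = "S", kind = "snp", chrom = "chr1",
                  pos = 1000, stringsAsFactors = FALSE)
  b <- reference_bundle(g, markers = m)
  # both genes upstream on +: only the nearest is returned
  expect_equal(map_snp_adjacent("S", b)$gene_id, "GB")
  m2 <- data.frame(marker_id = "S", kind = "snp", chrom = "chrEmpty",
                   pos = 10, stringsAsFactors = FALSE)
  expect_warning(none <- map_snp_adjacent(m2, b), "no genes")
  expect_equal(nrow(none), 0)
})

test_that("adjacent and bystander mappings equal brute-force scans", {
  set.seed(99)
  for (trial in 1:20) {
    g <- random_gene_table(50)
    b <- reference_bundle(g)
    for (q in 1:10) {
      snp <- data.frame(marker_id = "S", kind = "snp",
                        chrom = paste0("chr", sample(2, 1)),
                        pos = sample(52000, 1), stringsAsFactors = FALSE)
      got <- suppressWarnings(map_snp_adjacent(snp, b))
      exp <- oracle_adjacent(b$genes, snp$chrom, snp$pos)
      expect_identical(got$gene_id, exp$gene_id)
      # flanker cap: at most 4 genes not containing the SNP
      ncont <- sum(!(got$start <= snp$pos & got$end > snp$pos))
      expect_lte(ncont, 4)
      loc <- suppressWarnings(
        map_snp_bystander(snp, 4000, b, "L"))
      expect_identical(
        loc$gene_ids,
        oracle_interval(b$genes, snp$chrom,
                        max(0, snp$pos - 2000), snp$pos + 2000)$gene_id)
    }
  }
})

test_that("bystander gene sets are nested in the window size", {
  set.seed(5)
  g <- random_gene_table(60)
  b <- reference_bundle(g)
  snp <- data.frame(marker_id = "S", kind = "snp", chrom = "chr1",
                    pos = 25000, stringsAsFactors = FALSE)
  prev <- character()
  for (w in c(1000, 5000, 20000, 60000)) {
    cur <- suppressWarnings(map_snp_bystander(snp, w, b, "L"))$gene_ids
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("search spaces keep multi-membership and are deterministic", {
  b <- toy_bundle()
  snps <- data.frame(marker_id = c("SA", "SB"), kind = "snp",
                     chrom = "chr1", pos = c(600, 950),
                     stringsAsFactors = FALSE)
  sp <- build_search_space(snps, "adjacent", b)
  expect_equal(nrow(sp$loci), 2)
  # G03/G04/G05 fall in both loci
  expect_setequal(sp$gene_to_loci[["G04"]], c("SA", "SB"))
  expect_equal(sp$universe_n, length(sp$gene_to_loci))
  sp2 <- build_search_space(snps, "adjacent", b)
  expect_identical(sp, sp2)
  # permutation invariance of the membership map
  sp3 <- build_search_space(snps[2:1, ], "adjacent", b)
  expect_identical(sp$gene_to_loci[sort(names(sp$gene_to_loci))],
                   sp3$gene_to_loci[sort(names(sp3$gene_to_loci))])
})

test_that("adjacent-mode spaces respect the per-SNP cardinality bound", {
  set.seed(17)
  g <- random_gene_table(120, n_chrom = 2)
  b <- reference_bundle(g)
  snps <- data.frame(marker_id = sprintf("S%02d", 1:29), kind = "snp",
                     chrom = paste0("chr", sample(2, 29, replace = TRUE)),
                     pos = sample(50000, 29), stringsAsFactors = FALSE)
  sp <- suppressWarnings(build_search_space(snps, "adjacent", b))
  expect_lte(sp$universe_n, 29 * 5)
})

test_that("a space with no mappable input is fatal", {
  g <- toy_genes()
  b <- reference_bundle(g)
  snps <- data.frame(marker_id = "S", kind = "snp", chrom = "chrZ",
                     pos = 5, stringsAsFactors = FALSE)
  expect_error(suppressWarnings(build_search_space(snps, "adjacent", b)),
               "no input locus")
})

test_that("SNP and interval batch files parse into usable inputs", {
  dir <- withr::local_tempdir()
  b <- toy_bundle()
  writeLines(c("# pasted GWAS list", "M1", "chr1:950", ""),
             file.path(dir, "snps.txt"))
  snps <- read_snp_batch(file.path(dir, "snps.txt"), b)
  expect_equal(nrow(snps), 2)
  expect_equal(snps$pos, c(600, 950))
  writeLines(c("L1\tchr1\t350\t1050", "L2\tM1\tM2", "L3\tM1\t800"),
             file.path(dir, "iv.tsv"))
  specs <- read_interval_batch(file.path(dir, "iv.tsv"), b)
  expect_equal(specs$L1$mode, "explicit")
  expect_equal(specs$L2$mode, "marker_pair")
  expect_equal(specs$L3$mode, "center_width")
  sp <- build_search_space(specs, "intervals", b)
  expect_equal(sp$locus_genes$L1, c("G02", "G03", "G04", "G05"))
})

test_that("search-space export writes loci BED and membership TSV", {
  dir <- withr::local_tempdir()
  b <- toy_bundle()
  snps <- data.frame(marker_id = c("SA", "SB"), kind = "snp",
                     chrom = "chr1", pos = c(600, 950),
                     stringsAsFactors = FALSE)
  sp <- build_search_space(snps, "adjacent", b)
  write_search_space(sp, b, file.path(dir, "ss.bed"),
                     file.path(dir, "ss.tsv"))
  bed <- readLines(file.path(dir, "ss.bed"))
  expect_length(bed, 2)
  tsv <- read.table(file.path(dir, "ss.tsv"), sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  expect_true(all(grepl("SA|SB", tsv$locus_ids)))
})
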