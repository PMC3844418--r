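# Hand-built fixtures and independent brute-force oracles shared across
# the test files.  Fixtures are constructed in code; nothing is read from
# disk except files the tests themselves write.

toy_genes <- function() {
  data.frame(
    gene_id = sprintf("G%02d", 1:10),
    symbol = sprintf("sym%02d", 1:10),
    chrom = c(rep("chr1", 8), "chr2", "chr2"),
    start = c(100, 300, 500, 800, 1000, 1200, 1400, 1600, 100, 400),
    end   = c(200, 400, 700, 900, 1100, 1300, 1500, 1700, 300, 500),
    strand = c("+", "-", "+", "-", "+", "-", "+", "+", "+", "-"),
    stringsAsFactors = FALSE
  )
}

toy_bundle <- function() {
  genes <- toy_genes()
  gene_sets <- list(
    sets = data.frame(set_id = c("S1", "S2"),
                      source_db = c("KEGG", "BioCarta"),
                      name = c("Set one", "Set two"),
                      stringsAsFactors = FALSE),
    members = list("KEGG:S1" = c("G01", "G03", "G05"),
                   "BioCarta:S2" = c("G02", "G04"))
  )
  edges <- data.frame(gene_a = c("G01", "G02", "G05"),
                      gene_b = c("G03", "G04", "G09"),
                      source = "test", stringsAsFactors = FALSE)
  proteins <- data.frame(
    gene_id = genes$gene_id,
    protein_id = sub("G", "P", genes$gene_id),
    residues = c("MKLVAAAA", "MKLVCCCC", "MKLVAAAA", "MKLVCCDC",
                 "MWWWAAAA", "MKLVGGGG", "MKLVHHHH", "MKLVKKKK",
                 "MKLVAAAC", "MKLVLLLL"),
    stringsAsFactors = FALSE)
  # one 4-residue domain per protein starting at position 4 (0-based)
  domains <- data.frame(
    protein_id = proteins$protein_id,
    family_id = c("FA", "FB", "FA", "FB", "FA", "FC", "FC", "FD",
                  "FA", "FD"),
    ali_start = 4, ali_end = 8, bit_score = 100,
    stringsAsFactors = FALSE)
  markers <- data.frame(
    marker_id = c("M1", "M2", "M3", "M4", "M5"),
    kind = c("snp", "sts", "snp", "sts", "snp"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    pos = c(600, 1000, 950, 5000, 350),
    stringsAsFactors = FALSE)
  phenotypes <- list(
    phenotypes = data.frame(
      phenotype_id = c("PH1", "PH2", "PH3"),
      name = c("Alzheimer disease 1", "Alzheimer disease, type 3",
               "Cardiomyopathy, dilated"),
      stringsAsFactors = FALSE),
    seeds = list(PH1 = c("G01"), PH2 = c("G01", "G03"), PH3 = c("G04")))
  reference_bundle(genes, proteins = proteins, domains = domains,
                   gene_sets = gene_sets, edges = edges, markers = markers,
                   phenotypes = phenotypes)
}

# linear-scan interval oracle (any-base-overlap, half-open)
oracle_interval <- function(genes, chrom, start, end) {
  hit <- genes$chrom == chrom & genes$start < end & genes$end > start
  out <- genes[hit, , drop = FALSE]
  out <- out[order(out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force adjacent mapping: containing genes plus nearest
# non-containing gene per (strand, side), ties by start then gene_id
oracle_adjacent <- function(genes, chrom, pos) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  keep <- g$gene_id[g$start <= pos & g$end > pos]
  rest <- g[!(g$start <= pos & g$end > pos), , drop = FALSE]
  for (str in c("+", "-")) {
    for (sd in c("L", "R")) {
      cand <- rest[rest$strand == str, , drop = FALSE]
      cand <- if (sd == "L") cand[cand$end <= pos, , drop = FALSE] else
        cand[cand$start > pos, , drop = FALSE]
      if (!nrow(cand)) next
      d <- if (sd == "L") pos - (cand$end - 1) else cand$start - pos
      o <- order(d, cand$start, cand$gene_id)
      keep <- c(keep, cand$gene_id[o[1]])
    }
  }
  out <- g[g$gene_id %in% unique(keep), , drop = FALSE]
  out <- out[order(out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random gene layouts (possibly overlapping genes) for oracle trials
random_gene_table <- function(n, n_chrom = 2, span = 50000) {
  data.frame(
    gene_id = sprintf("R%03d", seq_len(n)),
    symbol = sprintf("r%03d", seq_len(n)),
    chrom = paste0("chr", sample(n_chrom, n, replace = TRUE)),
    start = st <- sample(span, n, replace = TRUE),
    end = st + sample(100:2000, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# exact hypergeometric upper tail from first principles (choose products)
hyper_tail_oracle <- function(k, n, K, N) {
  js <- k:min(n, K)
  js <- js[js >= max(0, n + K - N)]
  if (!length(js)) return(if (k <= max(0, n + K - N)) 1 else 0)
  if (k <= max(0, n + K - N)) return(1)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# 3-letter toy scoring scheme for exhaustive alignment checks
toy_scheme <- function(match = 3, mismatch = -2, gap_open = 2,
                       gap_extend = 1) {
  m <- matrix(mismatch, 3, 3,
              dimnames = list(c("A", "C", "D"), c("A", "C", "D")))
  diag(m) <- match
  scoring_scheme(m, gap_open = gap_open, gap_extend = gap_extend)
}

write_toy_reference <- function(dir) {
  write_reference(toy_bundle(), dir)
}
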