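## Deterministic synthetic reference bundles and planted-truth cases:
## a complete offline stand-in for curated gene, pathway, interaction,
## protein-domain, marker and phenotype resources.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Simulation parameters
#'
#' Defaults describe a compact two-chromosome genome of 200 genes with
#' 30 pathways of 5-15 genes, a 40-family domain vocabulary (1-3 domains
#' per protein, 40 residues per domain, ~10% point noise around each
#' family consensus) and 250 interaction edges.
#'
#' @param rng_seed Integer seed; the generator is fully reproducible.
#' @param n_chrom,genes_per_chrom Genome layout.
#' @param gene_len_range,intergap_range Gene length / intergenic gap
#'   ranges in bp.
#' @param strand_prob Probability of the + strand.
#' @param n_pathways,pathway_size_range Pathway collection.
#' @param domain_vocab_size,domains_per_gene_range,protein_len_per_domain
#'   Domain annotation layout (one protein per gene).
#' @param domain_noise Per-position probability of mutating a family
#'   consensus residue in each domain instance.
#' @param ppi_edge_count Number of undirected interaction edges.
#' @param n_markers Number of background markers (mixed SNP/STS).
#' @param n_phenotypes Number of phenotype records (seeded from the first
#'   pathways).
#' @return A \code{sim_params} list.
#' @export
sim_params <- function(rng_seed = 1L, n_chrom = 2L, genes_per_chrom = 100L,
                       gene_len_range = c(20000L, 80000L),
                       intergap_range = c(10000L, 60000L),
                       strand_prob = 0.5, n_pathways = 30L,
                       pathway_size_range = c(5L, 15L),
                       domain_vocab_size = 40L,
                       domains_per_gene_range = c(1L, 3L),
                       protein_len_per_domain = 40L, domain_noise = 0.1,
                       ppi_edge_count = 250L, n_markers = 30L,
                       n_phenotypes = 3L) {
  p <- list(rng_seed = rng_seed, n_chrom = n_chrom,
            genes_per_chrom = genes_per_chrom,
            gene_len_range = gene_len_range,
            intergap_range = intergap_range, strand_prob = strand_prob,
            n_pathways = n_pathways,
            pathway_size_range = pathway_size_range,
            domain_vocab_size = domain_vocab_size,
            domains_per_gene_range = domains_per_gene_range,
            protein_len_per_domain = protein_len_per_domain,
            domain_noise = domain_noise, ppi_edge_count = ppi_edge_count,
            n_markers = n_markers, n_phenotypes = n_phenotypes)
  stopifnot(p$gene_len_range[1] <= p$gene_len_range[2],
            p$intergap_range[1] <= p$intergap_range[2],
            p$pathway_size_range[1] <= p$pathway_size_range[2],
            p$domains_per_gene_range[1] <= p$domains_per_gene_range[2],
            p$strand_prob >= 0, p$strand_prob <= 1,
            p$domain_noise >= 0, p$domain_noise <= 1)
  if (p$pathway_size_range[2] > p$n_chrom * p$genes_per_chrom) {
    stop("pathway size exceeds gene count", call. = FALSE)
  }
  class(p) <- "sim_params"
  p
}

rand_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

mutate_aa <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(ch)) < rate
  if (any(hit)) ch[hit] <- sample(AA20, sum(hit), replace = TRUE)
  paste(ch, collapse = "")
}

runit <- function(range) {
  if (range[1] == range[2]) range[1] else
    sample(seq(range[1], range[2]), 1L)
}

#' Simulate a complete reference bundle
#'
#' Genes are laid out left to right per chromosome with sampled lengths
#' and gaps; each gene gets one protein whose residues are random except
#' on domain spans, which carry a per-family consensus sequence with
#' point noise (so same-family instances align well and cross-family
#' instances do not).  Pathways are random gene subsets, interaction
#' edges random gene pairs, and a few phenotype records are seeded from
#' the first pathways.  Fully reproducible from \code{params$rng_seed}.
#'
#' @param params A \code{\link{sim_params}} list.
#' @param dir Optional directory; when given, all reference files are
#'   written there via \code{\link{write_reference}}.
#' @return A \code{\link{reference_bundle}}.
#' @export
simulate_reference <- function(params = sim_params(), dir = NULL) {
  set.seed(params$rng_seed)
  ng <- params$n_chrom * params$genes_per_chrom
  wid <- max(4L, nchar(as.character(ng)))

  rows <- vector("list", params$n_chrom)
  idx <- 0L
  for (ci in seq_len(params$n_chrom)) {
    cursor <- 0
    starts <- numeric(params$genes_per_chrom)
    ends <- numeric(params$genes_per_chrom)
    for (gi in seq_len(params$genes_per_chrom)) {
      cursor <- cursor + runit(params$intergap_range)
      starts[gi] <- cursor
      cursor <- cursor + runit(params$gene_len_range)
      ends[gi] <- cursor
    }
    ids <- sprintf(paste0("G%0", wid, "d"), idx + seq_len(params$genes_per_chrom))
    idx <- idx + params$genes_per_chrom
    rows[[ci]] <- data.frame(
      gene_id = ids, symbol = tolower(ids), chrom = paste0("chr", ci),
      start = starts, end = ends,
      strand = ifelse(runif(params$genes_per_chrom) < params$strand_prob,
                      "+", "-"),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows)

  ## domain vocabulary and proteins (one per gene)
  vocab <- sprintf("PF%04d", seq_len(params$domain_vocab_size))
  consensus <- stats::setNames(
    vapply(vocab, function(f) rand_aa(params$protein_len_per_domain), ""),
    vocab)
  L <- params$protein_len_per_domain
  prot_rows <- vector("list", ng)
  dom_rows <- vector("list", ng)
  for (i in seq_len(ng)) {
    nd <- runit(params$domains_per_gene_range)
    fams <- sample(vocab, nd)
    segs <- vapply(fams, function(f)
      mutate_aa(consensus[[f]], params$domain_noise), "")
    pid <- sub("^G", "P", genes$gene_id[i])
    prot_rows[[i]] <- data.frame(protein_id = pid,
                                 gene_id = genes$gene_id[i],
                                 residues = paste(segs, collapse = ""),
                                 stringsAsFactors = FALSE)
    dom_rows[[i]] <- data.frame(protein_id = pid, family_id = fams,
                                ali_start = (seq_len(nd) - 1L) * L,
                                ali_end = seq_len(nd) * L,
                                bit_score = round(runif(nd, 50, 200), 1),
                                stringsAsFactors = FALSE)
  }
  proteins <- do.call(rbind, prot_rows)
  domains <- do.call(rbind, dom_rows)
  rownames(domains) <- NULL

  ## pathways
  if (params$n_pathways > 0) {
    src <- rep(c("KEGG", "BioCarta"), length.out = params$n_pathways)
    sets <- data.frame(
      set_id = sprintf("PW%03d", seq_len(params$n_pathways)),
      source_db = src,
      name = sprintf("Pathway %03d", seq_len(params$n_pathways)),
      stringsAsFactors = FALSE)
    members <- lapply(seq_len(params$n_pathways), function(i)
      sort(sample(genes$gene_id, runit(params$pathway_size_range))))
    names(members) <- paste(sets$source_db, sets$set_id, sep = ":")
    gene_sets <- list(sets = sets, members = members)
  } else {
    gene_sets <- NULL
  }

  ## interaction edges (canonical, deduplicated)
  edges <- NULL
  if (params$ppi_edge_count > 0) {
    a <- sample(genes$gene_id, 3 * params$ppi_edge_count, replace = TRUE)
    b <- sample(genes$gene_id, 3 * params$ppi_edge_count, replace = TRUE)
    keep <- a != b
    lo <- pmin(a[keep], b[keep])
    hi <- pmax(a[keep], b[keep])
    uq <- !duplicated(paste(lo, hi))
    take <- which(uq)[seq_len(min(params$ppi_edge_count, sum(uq)))]
    edges <- data.frame(gene_a = lo[take], gene_b = hi[take],
                        source = "SIMPPI", stringsAsFactors = FALSE)
  }

  ## background markers
  markers <- NULL
  if (params$n_markers > 0) {
    mi <- seq_len(params$n_markers)
    chrom <- paste0("chr", sample(params$n_chrom, params$n_markers,
                                  replace = TRUE))
    span <- tapply(genes$end, genes$chrom, max)
    markers <- data.frame(
      marker_id = sprintf("MK%03d", mi),
      kind = rep(c("snp", "sts"), length.out = params$n_markers),
      chrom = chrom,
      pos = floor(runif(params$n_markers) * span[chrom]),
      stringsAsFactors = FALSE)
    rownames(markers) <- NULL
  }

  ## phenotypes seeded from the first pathways
  phenotypes <- NULL
  if (params$n_phenotypes > 0 && params$n_pathways > 0) {
    np <- min(params$n_phenotypes, params$n_pathways)
    df <- data.frame(
      phenotype_id = sprintf("PH%02d", seq_len(np)),
      name = sprintf("Synthetic syndrome %d, type %s", seq_len(np),
                     letters[seq_len(np)]),
      stringsAsFactors = FALSE)
    seeds <- lapply(seq_len(np), function(i) {
      m <- gene_sets$members[[i]]
      m[seq_len(min(2L, length(m)))]
    })
    names(seeds) <- df$phenotype_id
    phenotypes <- list(phenotypes = df, seeds = seeds)
  }

  bundle <- reference_bundle(genes, proteins = proteins, domains = domains,
                             gene_sets = gene_sets, edges = edges,
                             markers = markers, phenotypes = phenotypes)
  attr(bundle, "consensus") <- consensus
  if (!is.null(dir)) write_reference(bundle, dir)
  bundle
}

# Sample one SNP position for a host gene: in the flanking intergenic
# half-gap ("intergenic") or inside the gene span ("genic").
place_snp <- function(genes, gi, placement) {
  g <- genes[gi, ]
  if (placement == "genic") {
    return(g$start + sample.int(g$end - g$start, 1L) - 1L)
  }
  same <- which(genes$chrom == g$chrom)
  k <- match(gi, same)
  gap_l <- if (k > 1) g$start - genes$end[same[k - 1]] else g$start
  gap_r <- if (k < length(same)) genes$start[same[k + 1]] - g$end else 2e5
  side <- if (runif(1) < 0.5) "L" else "R"
  if (side == "L" && gap_l >= 2) {
    g$start - sample.int(max(1L, floor(gap_l / 2)), 1L)
  } else if (gap_r >= 2) {
    g$end + sample.int(max(1L, floor(gap_r / 2)), 1L) - 1L
  } else {
    g$start - sample.int(max(1L, floor(gap_l / 2)), 1L)
  }
}

#' Plant a ground-truth module in a simulated bundle
#'
#' Selects well-separated host genes, places one SNP adjacent to (or
#' inside) each truth host and each decoy host, and plants a module
#' connecting the truth genes: a new pathway, a new domain family on the
#' truth proteins, or an interaction clique.  Optional seed genes are
#' additional module members placed outside every locus.  Loci are
#' rejected and re-sampled until each SNP's adjacent mapping has exactly
#' 4 genes (intergenic placement; 5 for genic) including its host, and
#' all loci are pairwise disjoint, so the search-space size is fixed by
#' design.  Uses the current RNG state; seed it for reproducibility.
#'
#' @param bundle A simulated \code{\link{reference_bundle}}.
#' @param module_kind "pathway", "domain", "ppi", or "none" (decoy-only
#'   layouts for null calibration).
#' @param k_loci Number of truth loci (0 allowed for "none").
#' @param n_decoy_loci Number of decoy loci around random non-members.
#' @param params The \code{\link{sim_params}} used to build the bundle.
#' @param n_seeds Number of designated seed members outside the loci
#'   (0-3; ab initio designs use 0).
#' @param genes_per_locus Planted members per truth locus (default 1;
#'   e.g. 4 plants a within-locus paralog cluster).
#' @param placement "intergenic" (SNP in the half-gap flanking the host;
#'   4-gene loci) or "genic" (SNP inside the host; 5-gene loci).
#' @return list(bundle, snps, seed_gene_ids, truth); \code{bundle} is the
#'   input bundle with the planted module added, \code{snps} a marker
#'   data.frame (truth then decoy), and \code{truth} records the planted
#'   module, members, seeds and per-SNP target genes.
#' @export
plant_case <- function(bundle, module_kind = c("pathway", "domain", "ppi",
                                               "none"),
                       k_loci = 4L, n_decoy_loci = 6L,
                       params = sim_params(), n_seeds = 1L,
                       genes_per_locus = 1L,
                       placement = c("intergenic", "genic")) {
  module_kind <- match.arg(module_kind)
  placement <- match.arg(placement)
  stopifnot(n_seeds >= 0, n_seeds <= 3, genes_per_locus >= 1)
  if (module_kind == "none") k_loci <- 0L
  genes <- bundle$genes
  margin <- 12L
  sep <- 6L
  expect_n <- if (placement == "intergenic") 4L else 5L
  chrom_idx <- split(seq_len(nrow(genes)), genes$chrom)

  eligible <- unlist(lapply(chrom_idx, function(ix)
    ix[(margin + 1):(length(ix) - margin)]), use.names = FALSE)

  used_idx <- integer()     # host indices already claimed
  used_genes <- character() # genes claimed by accepted loci
  pick_host <- function() {
    ok <- eligible[!eligible %in% used_idx &
                     !genes$gene_id[eligible] %in% used_genes]
    ok <- ok[vapply(ok, function(i) all(abs(i - used_idx) >= sep |
                                          genes$chrom[i] !=
                                            genes$chrom[used_idx]), TRUE)]
    if (!length(ok)) stop("cannot place further separated loci",
                          call. = FALSE)
    ok[sample.int(length(ok), 1L)]
  }

  n_loci <- k_loci + n_decoy_loci
  hosts <- integer(n_loci)
  snp_pos <- numeric(n_loci)
  locus_genes <- vector("list", n_loci)
  for (li in seq_len(n_loci)) {
    placed <- FALSE
    for (try in 1:200) {
      gi <- pick_host()
      pos <- place_snp(genes, gi, placement)
      snp <- data.frame(marker_id = "tmp", kind = "snp",
                        chrom = genes$chrom[gi], pos = pos,
                        stringsAsFactors = FALSE)
      mapped <- suppressWarnings(map_snp_adjacent(snp, bundle))
      if (nrow(mapped) == expect_n &&
          genes$gene_id[gi] %in% mapped$gene_id &&
          !any(mapped$gene_id %in% used_genes)) {
        hosts[li] <- gi
        snp_pos[li] <- pos
        locus_genes[[li]] <- mapped$gene_id
        used_idx <- c(used_idx, gi)
        used_genes <- c(used_genes, mapped$gene_id)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("cannot place ", n_loci, " well-separated loci",
                      call. = FALSE)
  }

  ## planted members: genes_per_locus genes from each truth locus
  members <- character()
  if (k_loci > 0) {
    members <- unlist(lapply(seq_len(k_loci), function(li) {
      lg <- locus_genes[[li]]
      stopifnot(genes_per_locus <= length(lg))
      if (genes_per_locus == 1L) genes$gene_id[hosts[li]] else
        lg[seq_len(genes_per_locus)]
    }), use.names = FALSE)
  }

  ## seed members outside every locus
  seed_ids <- character()
  if (n_seeds > 0) {
    for (si in seq_len(n_seeds)) {
      gi <- pick_host()
      used_idx <- c(used_idx, gi)
      used_genes <- c(used_genes, genes$gene_id[gi])
      seed_ids <- c(seed_ids, genes$gene_id[gi])
    }
  }
  disease <- c(members, seed_ids)

  ## mutate the bundle with the planted module
  planted_id <- NA_character_
  gs <- list(sets = bundle$gene_sets, members = bundle$set_members)
  proteins <- bundle$proteins
  domains <- bundle$domains
  edges <- bundle$edges
  consensus_new <- NULL
  if (module_kind == "pathway") {
    planted_id <- "PW_PLANTED"
    gs$sets <- rbind(gs$sets, data.frame(set_id = planted_id,
                                         source_db = "KEGG",
                                         name = "Planted pathway",
                                         stringsAsFactors = FALSE))
    gs$members <- c(gs$members,
                    stats::setNames(list(sort(disease)),
                                    paste("KEGG", planted_id, sep = ":")))
  } else if (module_kind == "domain") {
    planted_id <- "PF_PLANTED"
    L <- params$protein_len_per_domain
    consensus_new <- rand_aa(L)
    for (gid in disease) {
      pi <- which(proteins$gene_id == gid)[1]
      old_len <- nchar(proteins$residues[pi])
      proteins$residues[pi] <- paste0(
        proteins$residues[pi], mutate_aa(consensus_new, params$domain_noise))
      domains <- rbind(domains, data.frame(
        protein_id = proteins$protein_id[pi], family_id = planted_id,
        ali_start = old_len, ali_end = old_len + L, bit_score = 150,
        stringsAsFactors = FALSE))
    }
  } else if (module_kind == "ppi") {
    planted_id <- "PPI_PLANTED"
    if (length(disease) >= 2) {
      cm <- utils::combn(sort(disease), 2)
      edges <- rbind(edges, data.frame(gene_a = cm[1, ], gene_b = cm[2, ],
                                       source = "PLANTED",
                                       stringsAsFactors = FALSE))
    }
  }

  snps <- data.frame(
    marker_id = c(if (k_loci > 0) sprintf("RS_T%02d", seq_len(k_loci)),
                  if (n_decoy_loci > 0) sprintf("RS_D%02d",
                                                seq_len(n_decoy_loci))),
    kind = "snp",
    chrom = genes$chrom[hosts],
    pos = snp_pos,
    stringsAsFactors = FALSE)

  markers <- rbind(bundle$markers, snps)
  new_bundle <- reference_bundle(
    genes = genes, proteins = proteins, domains = domains,
    gene_sets = gs, edges = edges, markers = markers,
    phenotypes = list(phenotypes = bundle$phenotypes,
                      seeds = bundle$phenotype_seeds))
  attr(new_bundle, "consensus") <- attr(bundle, "consensus")

  truth <- list(
    module_kind = module_kind, planted_id = planted_id,
    disease_gene_ids = disease, seed_gene_ids = seed_ids,
    snp_markers = data.frame(
      marker_id = snps$marker_id,
      target_gene = genes$gene_id[hosts],
      is_truth = c(rep(TRUE, k_loci), rep(FALSE, n_decoy_loci)),
      stringsAsFactors = FALSE),
    decoy_genes = genes$gene_id[hosts[seq_len(n_decoy_loci) + k_loci]],
    planted_consensus = consensus_new)

  list(bundle = new_bundle, snps = snps, seed_gene_ids = seed_ids,
       truth = truth)
}

#' Write a planted case directory
#'
#' Emits the reference files plus snps.txt (one marker id per line),
#' seeds.txt, truth.tsv and a flat key=value params.cfg, forming a
#' self-contained case consumable by the pipeline.
#'
#' @param case A list from \code{\link{plant_case}}.
#' @param dir Output directory.
#' @param params The \code{\link{sim_params}} used (recorded in
#'   params.cfg).
#' @return Invisibly, the directory path.
#' @export
write_case <- function(case, dir, params = sim_params()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_reference(case$bundle, dir)
  writeLines(case$snps$marker_id, file.path(dir, "snps.txt"))
  writeLines(case$seed_gene_ids, file.path(dir, "seeds.txt"))
  tr <- case$truth
  writeLines(c(
    "key\tvalue",
    paste0("module_kind\t", tr$module_kind),
    paste0("planted_id\t", tr$planted_id),
    paste0("disease_genes\t", paste(tr$disease_gene_ids, collapse = ",")),
    paste0("seed_genes\t", paste(tr$seed_gene_ids, collapse = ",")),
    sprintf("snp\t%s=%s", tr$snp_markers$marker_id,
            tr$snp_markers$target_gene)),
    file.path(dir, "truth.tsv"))
  flat <- params[!vapply(params, is.null, TRUE)]
  writeLines(sprintf("%s=%s", names(flat),
                     vapply(flat, function(v) paste(v, collapse = ","), "")),
             file.path(dir, "params.cfg"))
  invisible(dir)
}
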