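## The reference bundle: an in-memory, indexed store of genes, gene sets,
## interactions, proteins, domain assignments, markers and phenotype seed
## sets.  It is the statistical universe for every engine.

#' Assemble and validate a reference bundle
#'
#' Cross-references are resolved against the gene table: records naming
#' unknown genes or proteins are dropped with a warning (never silently),
#' self-edges are removed, and undirected edges are stored with a
#' canonical gene ordering.  Genes are indexed per chromosome for
#' overlap queries.
#'
#' @param genes data.frame with columns gene_id, symbol, chrom, start,
#'   end, strand (0-based half-open coordinates).
#' @param proteins data.frame protein_id, gene_id, residues (optional).
#' @param domains data.frame protein_id, family_id, ali_start, ali_end,
#'   bit_score (optional).
#' @param gene_sets list with elements \code{sets} (data.frame set_id,
#'   source_db, name) and \code{members} (list keyed "source_db:set_id");
#'   optional.
#' @param edges data.frame gene_a, gene_b, source (optional).
#' @param markers data.frame marker_id, kind, chrom, pos (optional).
#' @param phenotypes list with elements \code{phenotypes} (data.frame
#'   phenotype_id, name) and \code{seeds} (list keyed by phenotype_id);
#'   optional.
#' @return An object of class \code{reference_bundle}.
#' @export
reference_bundle <- function(genes, proteins = NULL, domains = NULL,
                             gene_sets = NULL, edges = NULL,
                             markers = NULL, phenotypes = NULL) {
  stopifnot(is.data.frame(genes), nrow(genes) > 0)
  req <- c("gene_id", "symbol", "chrom", "start", "end", "strand")
  if (!all(req %in% names(genes))) {
    stop("genes table must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id in gene table")
  if (any(genes$start >= genes$end)) stop("gene with start >= end")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  known <- genes$gene_id
  sym2id <- stats::setNames(genes$gene_id, genes$symbol)

  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  names(gr) <- genes$gene_id

  ## proteins
  if (is.null(proteins)) {
    proteins <- data.frame(protein_id = character(), gene_id = character(),
                           residues = character(), stringsAsFactors = FALSE)
  } else {
    bad <- !(proteins$gene_id %in% known) | is.na(proteins$gene_id) |
      !nzchar(proteins$residues)
    if (any(bad)) {
      warning(sum(bad), " protein record(s) dropped (unresolved gene_id ",
              "or empty sequence)", call. = FALSE)
      proteins <- proteins[!bad, , drop = FALSE]
    }
    rownames(proteins) <- NULL
  }
  plen <- stats::setNames(nchar(proteins$residues), proteins$protein_id)

  ## domain hits
  if (is.null(domains)) {
    domains <- data.frame(protein_id = character(), family_id = character(),
                          ali_start = numeric(), ali_end = numeric(),
                          bit_score = numeric(), stringsAsFactors = FALSE)
  } else {
    badp <- !(domains$protein_id %in% names(plen))
    badc <- !badp & (domains$ali_start < 0 |
                       domains$ali_start >= domains$ali_end |
                       domains$ali_end > plen[domains$protein_id])
    bad <- badp | badc
    if (any(bad)) {
      warning(sum(bad), " domain hit(s) dropped (unknown protein or ",
              "out-of-range coordinates)", call. = FALSE)
      domains <- domains[!bad, , drop = FALSE]
    }
    rownames(domains) <- NULL
  }

  ## gene sets: resolve members, drop unknowns with warning
  if (is.null(gene_sets)) {
    gene_sets <- list(sets = data.frame(set_id = character(),
                                        source_db = character(),
                                        name = character(),
                                        stringsAsFactors = FALSE),
                      members = list())
  } else {
    dropped <- 0L
    members <- lapply(gene_sets$members, function(m) {
      m <- ifelse(m %in% known, m,
                  ifelse(m %in% names(sym2id), unname(sym2id[m]), NA))
      dropped <<- dropped + sum(is.na(m))
      unique(m[!is.na(m)])
    })
    if (dropped > 0) {
      warning(dropped, " gene-set member(s) dropped (unresolved gene id)",
              call. = FALSE)
    }
    empty <- lengths(members) == 0L
    if (any(empty)) {
      warning(sum(empty), " gene set(s) dropped (no resolvable members)",
              call. = FALSE)
    }
    gene_sets$members <- members[!empty]
    gene_sets$sets <- gene_sets$sets[!empty, , drop = FALSE]
    rownames(gene_sets$sets) <- NULL
  }

  ## edges: canonical order, no self-edges, resolve, dedupe
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        source = character(), stringsAsFactors = FALSE)
  } else {
    unknown <- !(edges$gene_a %in% known) | !(edges$gene_b %in% known)
    if (any(unknown)) {
      warning(sum(unknown), " edge(s) dropped (unresolved gene id)",
              call. = FALSE)
      edges <- edges[!unknown, , drop = FALSE]
    }
    edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
    if (nrow(edges)) {
      a <- pmin(edges$gene_a, edges$gene_b)
      b <- pmax(edges$gene_a, edges$gene_b)
      edges$gene_a <- a
      edges$gene_b <- b
      edges <- edges[!duplicated(paste(a, b)), , drop = FALSE]
      edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
    }
    rownames(edges) <- NULL
  }
  adjacency <- list()
  if (nrow(edges)) {
    adjacency <- c(split(edges$gene_b, edges$gene_a),
                   split(edges$gene_a, edges$gene_b))
    adjacency <- tapply(unlist(adjacency, use.names = FALSE),
                        rep(names(adjacency), lengths(adjacency)),
                        function(x) sort(unique(x)), simplify = FALSE)
    adjacency <- as.list(adjacency)
  }

  ## markers
  if (is.null(markers)) {
    markers <- data.frame(marker_id = character(), kind = character(),
                          chrom = character(), pos = numeric(),
                          stringsAsFactors = FALSE)
  }
  if (nrow(markers) && anyDuplicated(markers$marker_id)) {
    stop("duplicated marker_id in marker table")
  }

  ## phenotypes: resolve seed genes (ids or symbols)
  if (is.null(phenotypes)) {
    phenotypes <- list(phenotypes = data.frame(phenotype_id = character(),
                                               name = character(),
                                               stringsAsFactors = FALSE),
                       seeds = list())
  } else {
    dropped <- 0L
    phenotypes$seeds <- lapply(phenotypes$seeds, function(s) {
      s <- ifelse(s %in% known, s,
                  ifelse(s %in% names(sym2id), unname(sym2id[s]), NA))
      dropped <<- dropped + sum(is.na(s))
      unique(s[!is.na(s)])
    })
    if (dropped > 0) {
      warning(dropped, " phenotype seed gene(s) dropped (unresolved id)",
              call. = FALSE)
    }
  }

  structure(list(
    genes = genes,
    gr = gr,
    proteins = proteins,
    domains = domains,
    gene_sets = gene_sets$sets,
    set_members = gene_sets$members,
    edges = edges,
    adjacency = adjacency,
    markers = markers,
    phenotypes = phenotypes$phenotypes,
    phenotype_seeds = phenotypes$seeds
  ), class = "reference_bundle")
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat("reference_bundle:",
      nrow(x$genes), "genes on", length(unique(x$genes$chrom)),
      "chromosome(s);", nrow(x$proteins), "proteins;",
      nrow(x$domains), "domain hits;",
      nrow(x$gene_sets), "gene sets;",
      nrow(x$edges), "edges;",
      nrow(x$markers), "markers;",
      nrow(x$phenotypes), "phenotypes\n")
  invisible(x)
}

#' Load a reference bundle from files
#'
#' @param paths Named list/vector of file paths.  Role \code{genes} (BED)
#'   is required; \code{gene_sets} (GMT), \code{edges}, \code{domains},
#'   \code{markers}, \code{phenotypes} (TSV) and \code{proteins} (FASTA)
#'   are optional.
#' @return A validated \code{\link{reference_bundle}}.
#' @export
load_reference <- function(paths) {
  paths <- as.list(paths)
  if (is.null(paths$genes)) stop("paths$genes (BED) is required")
  reference_bundle(
    genes = read_genes_bed(paths$genes),
    proteins = if (!is.null(paths$proteins)) read_proteins_fasta(paths$proteins),
    domains = if (!is.null(paths$domains)) read_domains_tsv(paths$domains),
    gene_sets = if (!is.null(paths$gene_sets)) read_gmt(paths$gene_sets),
    edges = if (!is.null(paths$edges)) read_edges_tsv(paths$edges),
    markers = if (!is.null(paths$markers)) read_markers_tsv(paths$markers),
    phenotypes = if (!is.null(paths$phenotypes)) read_phenotypes_tsv(paths$phenotypes)
  )
}

#' Genes overlapping a genomic interval
#'
#' Returns every gene with at least one base of overlap with the 0-based
#' half-open interval \code{[start, end)}, i.e. gene.start < end and
#' gene.end > start, sorted by start position then gene_id.
#'
#' @param bundle A \code{\link{reference_bundle}}.
#' @param chrom Chromosome name.
#' @param start,end Interval bounds, 0-based half-open; start < end.
#' @return data.frame of gene rows (possibly empty).
#' @export
genes_in_interval <- function(bundle, chrom, start, end) {
  stopifnot(start < end)
  if (!(chrom %in% GenomeInfoDb_seqlevels(bundle$gr))) {
    warning("unknown chromosome '", chrom, "'", call. = FALSE)
    return(bundle$genes[0, , drop = FALSE])
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  hits <- GenomicRanges::findOverlaps(q, bundle$gr, ignore.strand = TRUE)
  ids <- names(bundle$gr)[S4Vectors::subjectHits(hits)]
  out <- bundle$genes[bundle$genes$gene_id %in% ids, , drop = FALSE]
  out <- out[order(out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# seqlevels() without importing all of GenomeInfoDb
GenomeInfoDb_seqlevels <- function(gr) {
  as.character(GenomicRanges::seqnames(GenomicRanges::seqinfo(gr)))
}

#' Merge phenotype records by shared name roots
#'
#' Phenotype names are case-folded and punctuation-stripped; records
#' sharing a supplied root token (matched as a whole word) are merged into
#' one cluster and their seed sets are unioned.  Without root tokens,
#' records sharing their leading word (of at least 4 characters) are
#' merged.  Unmatched records form singleton clusters.  Every phenotype
#' belongs to exactly one cluster.
#'
#' @param phenotypes data.frame with columns phenotype_id, name, or a
#'   \code{\link{reference_bundle}} (its phenotype table is used).
#' @param seeds Named list of seed gene vectors keyed by phenotype_id
#'   (ignored when \code{phenotypes} is a bundle).
#' @param root_tokens Optional character vector of root tokens; the first
#'   matching token claims the record.
#' @return A list of clusters of class \code{phenotype_clusters}; each
#'   cluster has \code{cluster_id}, \code{name}, \code{phenotype_ids} and
#'   \code{seed_genes} (the union over members).
#' @export
cluster_phenotypes <- function(phenotypes, seeds = NULL, root_tokens = NULL) {
  if (inherits(phenotypes, "reference_bundle")) {
    seeds <- phenotypes$phenotype_seeds
    phenotypes <- phenotypes$phenotypes
  }
  if (nrow(phenotypes) == 0) {
    return(structure(list(), class = "phenotype_clusters",
                     member_seeds = list()))
  }
  norm <- tolower(phenotypes$name)
  norm <- gsub("[^a-z0-9 ]", " ", norm)
  norm <- gsub("[[:space:]]+", " ", trimws(norm))
  words <- strsplit(norm, " ", fixed = TRUE)

  key <- character(nrow(phenotypes))
  if (!is.null(root_tokens)) {
    toks <- tolower(root_tokens)
    for (i in seq_along(key)) {
      hit <- toks[toks %in% words[[i]]]
      key[i] <- if (length(hit)) paste0("root:", hit[1]) else
        paste0("self:", phenotypes$phenotype_id[i])
    }
  } else {
    lead <- vapply(words, function(w) if (length(w)) w[1] else "", "")
    for (i in seq_along(key)) {
      key[i] <- if (nchar(lead[i]) >= 4) paste0("lead:", lead[i]) else
        paste0("self:", phenotypes$phenotype_id[i])
    }
  }

  member_seeds <- if (is.null(seeds)) {
    stats::setNames(rep(list(character()), nrow(phenotypes)),
                    phenotypes$phenotype_id)
  } else {
    stats::setNames(lapply(phenotypes$phenotype_id, function(p)
      unique(seeds[[p]])), phenotypes$phenotype_id)
  }

  groups <- split(seq_len(nrow(phenotypes)), key)
  groups <- groups[order(vapply(groups, min, 0L))]  # stable, input-ordered
  clusters <- lapply(seq_along(groups), function(ci) {
    idx <- groups[[ci]]
    ids <- phenotypes$phenotype_id[idx]
    label <- sub("^(root:|lead:|self:)", "", names(groups)[ci])
    if (startsWith(names(groups)[ci], "self:")) {
      label <- phenotypes$name[idx[1]]
    }
    list(cluster_id = paste0("PC", ci),
         name = label,
         phenotype_ids = ids,
         seed_genes = sort(unique(unlist(member_seeds[ids], use.names = FALSE))))
  })
  structure(clusters, class = "phenotype_clusters",
            member_seeds = member_seeds)
}

#' Remove phenotypes from clusters (cluster deconstruction)
#'
#' Drops the given phenotype records from their clusters and recomputes
#' each cluster's seed union; clusters left without members are removed.
#'
#' @param clusters A \code{phenotype_clusters} object.
#' @param phenotype_ids Character vector of phenotype ids to deselect.
#' @return The updated \code{phenotype_clusters} object.
#' @export
deselect_phenotypes <- function(clusters, phenotype_ids) {
  ms <- attr(clusters, "member_seeds")
  out <- lapply(clusters, function(cl) {
    keep <- setdiff(cl$phenotype_ids, phenotype_ids)
    if (!length(keep)) return(NULL)
    cl$phenotype_ids <- keep
    cl$seed_genes <- sort(unique(unlist(ms[keep], use.names = FALSE)))
    cl
  })
  out <- out[!vapply(out, is.null, TRUE)]
  structure(out, class = "phenotype_clusters", member_seeds = ms)
}
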