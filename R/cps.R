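## Common pathway scanning (CPS): pathway/complex association by the
## one-sided Fisher's exact test, in seeded and ab initio modes, plus
## direct protein-protein interaction evidence.

#' Upper-tail Fisher's exact (hypergeometric) probability
#'
#' Probability of observing \code{k} or more pathway genes among the
#' \code{n} search-space genes, when \code{K} of the \code{N} universe
#' genes belong to the pathway: \eqn{P(X \ge k)} for
#' \eqn{X \sim Hypergeom(N, K, n)}.  Computed exactly by log-space
#' summation of the hypergeometric mass over the upper tail.
#'
#' @param k Search-space genes in the pathway (0 <= k <= min(n, K)).
#' @param n Distinct genes in the search space.
#' @param K Pathway genes in the universe.
#' @param N Universe size.
#' @return p-value in (0, 1].
#' @export
fisher_exact_greater <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || n > N || K > N) {
    stop("invalid contingency counts: k=", k, " n=", n, " K=", K, " N=", N,
         call. = FALSE)
  }
  lo <- max(0, n + K - N)
  if (k <= lo) return(1)
  js <- k:min(n, K)
  lt <- lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)
  m <- max(lt)
  min(1, exp(m + log(sum(exp(lt - m)))))
}

# Resolve a vector of gene ids or symbols against the bundle.
resolve_gene_ids <- function(x, bundle, what = "gene") {
  ids <- ifelse(x %in% bundle$genes$gene_id, x,
                bundle$genes$gene_id[match(x, bundle$genes$symbol)])
  if (anyNA(ids)) {
    warning(sum(is.na(ids)), " ", what, "(s) dropped (unresolved id)",
            call. = FALSE)
  }
  unique(ids[!is.na(ids)])
}

empty_predictions <- function() {
  data.frame(locus_id = character(), gene_id = character(),
             symbol = character(), method = character(),
             evidence_id = character(), evidence_name = character(),
             statistic = numeric(), seed_genes = character(),
             relative_rank = integer(), stringsAsFactors = FALSE)
}

# One prediction row per locus the gene belongs to.
expand_by_locus <- function(space, bundle, gene_ids, method, evidence_id,
                            evidence_name, statistic, seed_genes) {
  rows <- lapply(seq_along(gene_ids), function(i) {
    gid <- gene_ids[i]
    data.frame(locus_id = space$gene_to_loci[[gid]], gene_id = gid,
               symbol = bundle$genes$symbol[match(gid, bundle$genes$gene_id)],
               method = method, evidence_id = evidence_id[i],
               evidence_name = evidence_name[i], statistic = statistic[i],
               seed_genes = seed_genes[i], relative_rank = NA_integer_,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) return(empty_predictions())
  do.call(rbind, rows)
}

# Shared Fisher machinery for both CPS modes.
cps_associations <- function(space, bundle, sources, universe) {
  if (is.null(universe)) universe <- bundle$genes$gene_id
  sp <- intersect(space_genes(space), universe)
  n <- length(sp)
  N <- length(universe)
  sets <- bundle$gene_sets
  if (!is.null(sources)) {
    sets <- sets[sets$source_db %in% sources, , drop = FALSE]
  }
  if (nrow(sets) == 0) {
    return(list(assoc = NULL, n = n, N = N, sp = sp))
  }
  key <- paste(sets$source_db, sets$set_id, sep = ":")
  rows <- lapply(seq_len(nrow(sets)), function(i) {
    mem <- intersect(bundle$set_members[[key[i]]], universe)
    K <- length(mem)
    if (K == 0) return(NULL)
    ov <- intersect(mem, sp)
    k <- length(ov)
    loci_hit <- length(unique(unlist(space$gene_to_loci[ov],
                                     use.names = FALSE)))
    data.frame(set_id = sets$set_id[i], source_db = sets$source_db[i],
               name = sets$name[i], k = k, n = n, K = K, N = N,
               p_value = fisher_exact_greater(k, n, K, N),
               loci_hit = loci_hit,
               overlap_genes = paste(sort(ov), collapse = ","),
               seed_members = "", stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  assoc <- if (length(rows)) do.call(rbind, rows) else NULL
  list(assoc = assoc, n = n, N = N, sp = sp)
}

# Turn retained associations into per-gene predictions: each gene is
# scored by the smallest p among its retained pathways.
pathway_predictions <- function(space, bundle, retained, candidates,
                                method, seeds) {
  if (is.null(retained) || nrow(retained) == 0 || !length(candidates)) {
    return(empty_predictions())
  }
  retained <- retained[order(retained$p_value, retained$set_id), , drop = FALSE]
  key <- paste(retained$source_db, retained$set_id, sep = ":")
  memb <- lapply(key, function(k) bundle$set_members[[k]])
  rows <- lapply(candidates, function(gid) {
    in_set <- which(vapply(memb, function(m) gid %in% m, TRUE))
    if (!length(in_set)) return(NULL)
    best <- in_set[1]  # retained is sorted by p then set_id
    sd <- sort(intersect(memb[[best]], seeds))
    data.frame(gene_id = gid, evidence_id = retained$set_id[best],
               evidence_name = retained$name[best],
               statistic = retained$p_value[best],
               seed_genes = paste(sd, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty_predictions())
  df <- do.call(rbind, rows)
  expand_by_locus(space, bundle, df$gene_id, method, df$evidence_id,
                  df$evidence_name, df$statistic, df$seed_genes)
}

#' Seeded common pathway scanning
#'
#' Pathways containing at least one seed gene are tested for association
#' with the search space by \code{\link{fisher_exact_greater}}; pathways
#' with p below \code{alpha} are retained, and every non-seed
#' search-space gene belonging to a retained pathway is predicted,
#' prioritized by the lowest p-value among its retained pathways.
#'
#' @param space A \code{search_space}.
#' @param seeds Seed gene ids or symbols (non-empty).
#' @param bundle A \code{\link{reference_bundle}}.
#' @param alpha Retention threshold on the pathway p-value (default 0.05).
#' @param sources Optional gene-set source filter (e.g. "KEGG").
#' @param universe Optional universe gene ids (default: all bundle genes).
#' @param bonferroni Divide alpha by the number of tested pathways
#'   (default off: the raw threshold is the documented default).
#' @return list(associations, predictions).  \code{associations} holds
#'   one row per tested seed pathway (counts k/n/K/N, p_value, loci_hit,
#'   overlap and seed members, and a \code{retained} flag);
#'   \code{predictions} holds ranked candidate rows.
#' @export
cps_seeded <- function(space, seeds, bundle, alpha = 0.05, sources = NULL,
                       universe = NULL, bonferroni = FALSE) {
  stopifnot(length(seeds) > 0, nrow(space$loci) > 0)
  seeds <- resolve_gene_ids(seeds, bundle, "seed gene")
  if (!length(seeds)) stop("no seed gene could be resolved", call. = FALSE)
  ca <- cps_associations(space, bundle, sources, universe)
  assoc <- ca$assoc
  if (!is.null(assoc)) {
    key <- paste(assoc$source_db, assoc$set_id, sep = ":")
    seeded <- vapply(key, function(k)
      length(intersect(bundle$set_members[[k]], seeds)) > 0, TRUE)
    assoc <- assoc[seeded, , drop = FALSE]
  }
  if (is.null(assoc) || nrow(assoc) == 0) {
    warning("no seed gene occurs in any gene set", call. = FALSE)
    return(list(associations = NULL, predictions = empty_predictions()))
  }
  key <- paste(assoc$source_db, assoc$set_id, sep = ":")
  assoc$seed_members <- vapply(key, function(k)
    paste(sort(intersect(bundle$set_members[[k]], seeds)), collapse = ","),
    "")
  thr <- if (bonferroni) alpha / nrow(assoc) else alpha
  assoc$retained <- assoc$p_value < thr
  assoc <- assoc[order(assoc$p_value, assoc$set_id), , drop = FALSE]
  rownames(assoc) <- NULL
  candidates <- setdiff(ca$sp, seeds)
  preds <- pathway_predictions(space, bundle,
                               assoc[assoc$retained, , drop = FALSE],
                               candidates, "CPS-s", seeds)
  list(associations = assoc, predictions = rank_predictions(preds))
}

#' Ab initio common pathway scanning
#'
#' With multiple loci and no seed knowledge, pathways whose search-space
#' overlap spans at least \code{min_loci} distinct loci are tested and
#' ranked exactly as in seeded mode; all search-space genes in retained
#' pathways are predicted.
#'
#' @inheritParams cps_seeded
#' @param min_loci Minimum number of distinct loci a pathway's overlap
#'   must span (default 2).
#' @return list(associations, predictions) as in \code{\link{cps_seeded}}.
#' @export
cps_ab_initio <- function(space, bundle, alpha = 0.05, min_loci = 2,
                          sources = NULL, universe = NULL,
                          bonferroni = FALSE) {
  if (nrow(space$loci) < 2) {
    stop("ab initio mode requires at least 2 loci", call. = FALSE)
  }
  ca <- cps_associations(space, bundle, sources, universe)
  assoc <- ca$assoc
  if (!is.null(assoc)) {
    assoc <- assoc[assoc$loci_hit >= min_loci, , drop = FALSE]
  }
  if (is.null(assoc) || nrow(assoc) == 0) {
    return(list(associations = NULL, predictions = empty_predictions()))
  }
  thr <- if (bonferroni) alpha / nrow(assoc) else alpha
  assoc$retained <- assoc$p_value < thr
  assoc <- assoc[order(assoc$p_value, assoc$set_id), , drop = FALSE]
  rownames(assoc) <- NULL
  preds <- pathway_predictions(space, bundle,
                               assoc[assoc$retained, , drop = FALSE],
                               ca$sp, "CPS-ab", character())
  list(associations = assoc, predictions = rank_predictions(preds))
}

#' Seeded protein-interaction evidence
#'
#' Predicts every non-seed search-space gene with a direct interaction
#' edge to a seed gene; the statistic is the number of distinct seed
#' interactors.
#'
#' @inheritParams cps_seeded
#' @return Ranked predictions data.frame (method "PPI-s", evidence
#'   "PPIN").
#' @export
ppi_seeded <- function(space, seeds, bundle) {
  stopifnot(length(seeds) > 0)
  seeds <- resolve_gene_ids(seeds, bundle, "seed gene")
  cand <- setdiff(space_genes(space), seeds)
  hits <- lapply(cand, function(gid) {
    partners <- sort(intersect(bundle$adjacency[[gid]], seeds))
    if (!length(partners)) return(NULL)
    list(gid = gid, partners = partners)
  })
  hits <- hits[!vapply(hits, is.null, TRUE)]
  if (!length(hits)) return(empty_predictions())
  preds <- expand_by_locus(
    space, bundle,
    gene_ids = vapply(hits, `[[`, "", "gid"),
    method = "PPI-s", evidence_id = rep("PPIN", length(hits)),
    evidence_name = rep("PPIN", length(hits)),
    statistic = vapply(hits, function(h) length(h$partners), 0),
    seed_genes = vapply(hits, function(h) paste(h$partners, collapse = ","), "")
  )
  rank_predictions(preds)
}

#' Ab initio protein-interaction evidence
#'
#' Predicts pairs of search-space genes located in distinct loci that are
#' joined by a direct interaction edge; both partners are emitted, scored
#' by their number of cross-locus partners.
#'
#' @inheritParams cps_seeded
#' @return Ranked predictions data.frame (method "PPI-ab").
#' @export
ppi_ab_initio <- function(space, bundle) {
  if (nrow(space$loci) < 2) {
    stop("ab initio mode requires at least 2 loci", call. = FALSE)
  }
  sp <- space_genes(space)
  hits <- lapply(sp, function(gid) {
    partners <- intersect(bundle$adjacency[[gid]], sp)
    lg <- space$gene_to_loci[[gid]]
    cross <- partners[vapply(partners, function(h) {
      lh <- space$gene_to_loci[[h]]
      length(unique(c(lg, lh))) > 1  # some locus pair differs
    }, TRUE)]
    if (!length(cross)) return(NULL)
    list(gid = gid, n = length(cross), partners = sort(cross))
  })
  hits <- hits[!vapply(hits, is.null, TRUE)]
  if (!length(hits)) return(empty_predictions())
  preds <- expand_by_locus(
    space, bundle,
    gene_ids = vapply(hits, `[[`, "", "gid"),
    method = "PPI-ab", evidence_id = rep("PPIN", length(hits)),
    evidence_name = vapply(hits, function(h)
      paste0("PPIN:", paste(h$partners, collapse = ",")), ""),
    statistic = vapply(hits, function(h) h$n, 0),
    seed_genes = rep("", length(hits))
  )
  rank_predictions(preds)
}

#' Assign within-locus relative ranks
#'
#' Pathway-scored predictions (methods CPS-s/CPS-ab) sort by ascending
#' p-value; similarity- and count-scored predictions (CMP-*, PPI-*) sort
#' by descending statistic; ties break on gene symbol then gene id, so
#' ranking is deterministic under input permutation.  By default ranks
#' are assigned within each (locus, method) stratum; with
#' \code{per_method = FALSE} a mixed frame is ranked within the locus
#' with pathway-scored rows preceding interaction rows, every row of a
#' gene receiving the rank of that gene's best row.
#'
#' @param preds Predictions data.frame.
#' @param per_method Rank within (locus, method) (default) or within
#'   locus across methods.
#' @return The predictions with \code{relative_rank} filled, sorted by
#'   locus, method and rank.
#' @export
rank_predictions <- function(preds, per_method = TRUE) {
  if (nrow(preds) == 0) return(preds)
  ascending <- c("CPS-s", "CPS-ab")
  keyval <- ifelse(preds$method %in% ascending,
                   preds$statistic, -preds$statistic)
  if (per_method) {
    grp <- paste(preds$locus_id, preds$method, sep = "\r")
    out <- lapply(split(seq_len(nrow(preds)), grp), function(idx) {
      o <- idx[order(keyval[idx], preds$symbol[idx], preds$gene_id[idx])]
      r <- preds[o, , drop = FALSE]
      r$relative_rank <- seq_along(o)
      r
    })
  } else {
    cls <- ifelse(preds$method %in% c("PPI-s", "PPI-ab"), 1L, 0L)
    out <- lapply(split(seq_len(nrow(preds)), preds$locus_id), function(idx) {
      o <- idx[order(cls[idx], keyval[idx], preds$symbol[idx],
                     preds$gene_id[idx])]
      r <- preds[o, , drop = FALSE]
      pos <- seq_along(o)
      best <- tapply(pos, r$gene_id, min)
      r$relative_rank <- as.integer(best[r$gene_id])
      r
    })
  }
  out <- do.call(rbind, out)
  out <- out[order(out$locus_id, out$method, out$relative_rank,
                   out$symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}
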