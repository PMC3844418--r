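## Common module profiling (CMP): seeded domain-similarity scoring via
## Smith-Waterman over shared-family domain instances, and ab initio
## domain over-representation via a conservative chi-square statistic.

.scheme_cache <- new.env(parent = emptyenv())

#' Build a Smith-Waterman scoring scheme
#'
#' @param matrix A named preset ("BLOSUM45"/"50"/"62"/"80"/"100",
#'   "PAM30"/"40"/"70"/"120"/"250", resolved offline from Biostrings), a
#'   path to an NCBI-format matrix file, or a symmetric numeric matrix
#'   with residue row/column names.
#' @param gap_open,gap_extend Affine gap penalties (>= 0; a gap of length
#'   L costs gap_open + L * gap_extend, i.e. the first gap position pays
#'   open + extend).  Defaults are the SSEARCH-style BLOSUM62 / 11 / 1.
#' @return A \code{scoring_scheme} object.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1) {
  if (is.character(matrix) && length(matrix) == 1) {
    if (file.exists(matrix)) {
      matrix <- read_score_matrix(matrix)
    } else {
      key <- matrix
      if (is.null(.scheme_cache[[key]])) {
        e <- new.env()
        ok <- tryCatch({
          utils::data(list = key, package = "Biostrings", envir = e)
          TRUE
        }, warning = function(w) FALSE, error = function(e) FALSE)
        if (!ok || is.null(e[[key]])) {
          stop("unknown scoring matrix preset '", key, "'", call. = FALSE)
        }
        .scheme_cache[[key]] <- e[[key]]
      }
      matrix <- .scheme_cache[[key]]
    }
  }
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (!isTRUE(all.equal(matrix, t(matrix), check.attributes = FALSE))) {
    stop("substitution matrix must be symmetric", call. = FALSE)
  }
  if (gap_open < 0 || gap_extend < 0 || gap_extend > gap_open) {
    stop("require 0 <= gap_extend <= gap_open", call. = FALSE)
  }
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend), class = "scoring_scheme")
}

#' Read an NCBI-format substitution matrix file
#'
#' Lines starting with \code{#} are comments; the first data line lists
#' the column residues and each following line a row residue and its
#' scores.
#'
#' @param path Path to the matrix file.
#' @return Numeric matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!grepl("^\\s*(#|$)", raw)]
  cols <- strsplit(trimws(raw[1]), "[[:space:]]+")[[1]]
  body <- strsplit(trimws(raw[-1]), "[[:space:]]+")
  rows <- vapply(body, `[`, "", 1L)
  vals <- t(vapply(body, function(x) as.numeric(x[-1]),
                   numeric(length(cols))))
  dimnames(vals) <- list(rows, cols)
  vals
}

# Encode residues as 0-based indices into the matrix alphabet; residues
# outside the alphabet fall back to the X column when present.
encode_residues <- function(seq, alphabet) {
  if (!nzchar(seq)) return(integer())
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(ch, alphabet)
  if (anyNA(idx)) {
    xi <- match("X", alphabet)
    if (is.na(xi)) {
      stop("residue(s) outside the matrix alphabet: ",
           paste(unique(ch[is.na(idx)]), collapse = ""), call. = FALSE)
    }
    idx[is.na(idx)] <- xi
  }
  idx - 1L
}

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score of two residue strings under an affine
#' gap model, by dynamic programming.  Symmetric in its arguments; an
#' empty sequence scores 0 (the empty alignment).
#'
#' @param seq_a,seq_b Residue strings over the matrix alphabet (unknown
#'   residues are scored via the X column).
#' @param scheme A \code{\link{scoring_scheme}}.
#' @return Non-negative alignment score in matrix units.
#' @export
smith_waterman <- function(seq_a, seq_b, scheme = scoring_scheme()) {
  alpha <- rownames(scheme$matrix)
  sw_score_int(encode_residues(seq_a, alpha), encode_residues(seq_b, alpha),
               scheme$matrix, scheme$gap_open, scheme$gap_extend)
}

#' Brute-force local alignment score (validation oracle)
#'
#' Exhaustively enumerates every local alignment path and returns the
#' best score.  Exponential in sequence length; intended only to validate
#' \code{\link{smith_waterman}} on tiny sequences.
#'
#' @inheritParams smith_waterman
#' @return Best local alignment score found by enumeration.
#' @export
smith_waterman_enumerate <- function(seq_a, seq_b, scheme = scoring_scheme()) {
  alpha <- rownames(scheme$matrix)
  sw_enum_int(encode_residues(seq_a, alpha), encode_residues(seq_b, alpha),
              scheme$matrix, scheme$gap_open, scheme$gap_extend)
}

#' Similarity of two same-family domain instances
#'
#' Aligns the two domain subsequences (protein residues
#' \code{[ali_start, ali_end)}) and normalizes the raw Smith-Waterman
#' score by the larger of the two self-alignment scores, yielding
#' \code{s_norm} in [0, 1] with 1 for identical instances.
#'
#' @param hit_a,hit_b One-row domain-hit data.frames (same family_id).
#' @param bundle A \code{\link{reference_bundle}} (protein sequences).
#' @param scheme A \code{\link{scoring_scheme}}.
#' @return list(family_id, protein_a, protein_b, raw_score, self_a,
#'   self_b, s_norm).
#' @export
domain_similarity <- function(hit_a, hit_b, bundle,
                              scheme = scoring_scheme()) {
  if (hit_a$family_id != hit_b$family_id) {
    stop("domain instances belong to different families", call. = FALSE)
  }
  sub_of <- function(h) {
    i <- match(h$protein_id, bundle$proteins$protein_id)
    if (is.na(i)) stop("missing protein sequence for '", h$protein_id, "'",
                       call. = FALSE)
    substring(bundle$proteins$residues[i], h$ali_start + 1, h$ali_end)
  }
  a <- sub_of(hit_a)
  b <- sub_of(hit_b)
  raw <- smith_waterman(a, b, scheme)
  self_a <- smith_waterman(a, a, scheme)
  self_b <- smith_waterman(b, b, scheme)
  denom <- max(self_a, self_b)
  list(family_id = hit_a$family_id, protein_a = hit_a$protein_id,
       protein_b = hit_b$protein_id, raw_score = raw, self_a = self_a,
       self_b = self_b, s_norm = if (denom > 0) raw / denom else 0)
}

# protein -> gene lookup and per-gene family index
protein_gene <- function(bundle) {
  stats::setNames(bundle$proteins$gene_id, bundle$proteins$protein_id)
}

# families borne by each gene (singles), or same-protein unordered family
# pairs (combinations = "pairs")
gene_family_index <- function(bundle, combinations = "singles") {
  pg <- protein_gene(bundle)
  d <- bundle$domains
  if (nrow(d) == 0) return(list())
  if (combinations == "singles") {
    fam <- d$family_id
    gid <- unname(pg[d$protein_id])
  } else {
    per_prot <- lapply(split(d$family_id, d$protein_id),
                       function(f) sort(unique(f)))
    pairs <- lapply(per_prot, function(f) {
      if (length(f) < 2) return(character())
      cm <- utils::combn(f, 2)
      paste(cm[1, ], cm[2, ], sep = "+")
    })
    fam <- unlist(pairs, use.names = FALSE)
    gid <- unname(pg[rep(names(pairs), lengths(pairs))])
    if (!length(fam)) return(list())
  }
  lapply(split(fam, gid), unique)
}

#' Seeded common module profiling
#'
#' Every non-seed search-space gene sharing at least one domain family
#' with a seed gene is scored by S, the maximum normalized
#' Smith-Waterman similarity over all shared-family instance pairs
#' between the gene's proteins and the seed's proteins; predictions with
#' S >= \code{s_min} are reported with the best-scoring seed and family.
#'
#' @inheritParams cps_seeded
#' @param scheme A \code{\link{scoring_scheme}}.
#' @param s_min Minimum S to report (default 0).
#' @return Ranked predictions data.frame (method "CMP-s"; statistic S in
#'   [0, 1], descending within locus).
#' @export
cmp_seeded <- function(space, seeds, bundle, scheme = scoring_scheme(),
                       s_min = 0) {
  stopifnot(length(seeds) > 0)
  seeds <- resolve_gene_ids(seeds, bundle, "seed gene")
  if (nrow(bundle$domains) == 0) {
    warning("no domain assignments loaded", call. = FALSE)
    return(empty_predictions())
  }
  pg <- protein_gene(bundle)
  d <- bundle$domains
  d$gene_id <- unname(pg[d$protein_id])
  seed_hits <- d[d$gene_id %in% seeds, , drop = FALSE]
  if (nrow(seed_hits) == 0) return(empty_predictions())

  sub_cache <- new.env(parent = emptyenv())
  dom_sub <- function(i, tbl) {
    key <- paste0(tbl$protein_id[i], ":", tbl$ali_start[i])
    if (is.null(sub_cache[[key]])) {
      j <- match(tbl$protein_id[i], bundle$proteins$protein_id)
      s <- substring(bundle$proteins$residues[j], tbl$ali_start[i] + 1,
                     tbl$ali_end[i])
      sub_cache[[key]] <- list(seq = s, self = smith_waterman(s, s, scheme))
    }
    sub_cache[[key]]
  }

  cand <- setdiff(space_genes(space), seeds)
  rows <- lapply(cand, function(gid) {
    gh <- d[d$gene_id %in% gid, , drop = FALSE]
    if (nrow(gh) == 0) return(NULL)
    sh <- seed_hits[seed_hits$family_id %in% gh$family_id, , drop = FALSE]
    if (nrow(sh) == 0) return(NULL)
    best <- NULL
    for (i in seq_len(nrow(gh))) {
      js <- which(sh$family_id == gh$family_id[i])
      for (j in js) {
        da <- dom_sub(i, gh)
        db <- dom_sub(j, sh)
        raw <- smith_waterman(da$seq, db$seq, scheme)
        denom <- max(da$self, db$self)
        s <- if (denom > 0) raw / denom else 0
        if (is.null(best) || s > best$s) {
          best <- list(s = s, family = gh$family_id[i],
                       seed = sh$gene_id[j])
        }
      }
    }
    if (is.null(best) || best$s < s_min) return(NULL)
    data.frame(gene_id = gid, family = best$family, seed = best$seed,
               s = best$s, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty_predictions())
  df <- do.call(rbind, rows)
  preds <- expand_by_locus(space, bundle, df$gene_id, "CMP-s", df$family,
                           df$family, df$s, df$seed)
  rank_predictions(preds)
}

#' Chi-square component
#'
#' \eqn{(o - e)^2 / e} for an observed count against its expectation.
#'
#' @param o Observed count.
#' @param e Expected count (> 0).
#' @return The component statistic.
#' @export
chi2_component <- function(o, e) {
  if (any(e <= 0)) stop("expected count must be > 0", call. = FALSE)
  (o - e)^2 / e
}

#' Ab initio common module profiling
#'
#' Each domain family (or same-protein family pair) present in the search
#' space is tested for over-representation against the genome-wide
#' expectation e = n K / N.  Two chi-square components are computed from
#' an anti-conservative gene-level count (every bearing gene counts) and
#' a conservative locus-level count (bearing genes within one locus
#' collapse to a single observation, discounting within-locus paralog
#' clusters); the reported statistic is their minimum.  Families are
#' retained when both counts exceed expectation (over-representation),
#' the locus count spans at least \code{min_loci} loci and chi2_min
#' reaches \code{chi2_threshold}; search-space genes bearing a retained
#' family are predicted with that family's chi2_min.
#'
#' @inheritParams cps_ab_initio
#' @param chi2_threshold Retention threshold on chi2_min (default 3.84,
#'   the df = 1 critical value at p ~ 0.05).
#' @param combinations "singles" (default) tests individual families;
#'   "pairs" tests unordered family pairs co-occurring on one protein.
#' @param max_family_universe_freq Optional filter dropping promiscuous
#'   families present in more than this fraction of the universe.
#' @return list(enrichments, predictions); \code{enrichments} has one row
#'   per tested family with counts, both components, chi2_min, direction
#'   and a retained flag.
#' @export
cmp_ab_initio <- function(space, bundle, chi2_threshold = 3.84,
                          min_loci = 2, combinations = c("singles", "pairs"),
                          max_family_universe_freq = NULL, universe = NULL) {
  combinations <- match.arg(combinations)
  if (nrow(space$loci) < 2) {
    stop("ab initio mode requires at least 2 loci", call. = FALSE)
  }
  if (is.null(universe)) universe <- bundle$genes$gene_id
  gf <- gene_family_index(bundle, combinations)
  gf <- gf[names(gf) %in% universe]
  if (!length(gf)) {
    warning("no domain assignments loaded", call. = FALSE)
    return(list(enrichments = NULL, predictions = empty_predictions()))
  }
  sp <- intersect(space_genes(space), universe)
  n <- length(sp)
  N <- length(universe)
  fam_genes <- split(rep(names(gf), lengths(gf)),
                     unlist(gf, use.names = FALSE))
  sp_fams <- unique(unlist(gf[names(gf) %in% sp], use.names = FALSE))
  rows <- lapply(sp_fams, function(fam) {
    bearers <- fam_genes[[fam]]
    K <- length(bearers)
    if (!is.null(max_family_universe_freq) &&
        K / N > max_family_universe_freq) return(NULL)
    e <- n * K / N
    sp_bear <- intersect(bearers, sp)
    o_gene <- length(sp_bear)
    loci_hit <- unique(unlist(space$gene_to_loci[sp_bear], use.names = FALSE))
    o_locus <- min(length(loci_hit), o_gene)
    chi2_gene <- chi2_component(o_gene, e)
    chi2_locus <- chi2_component(o_locus, e)
    direction <- if (o_gene > e && o_locus > e) "over" else
      if (o_gene < e && o_locus < e) "under" else "ambiguous"
    data.frame(family_id = fam, o_gene = o_gene, o_locus = o_locus,
               K = K, n = n, N = N, e = e, chi2_gene = chi2_gene,
               chi2_locus = chi2_locus,
               chi2_min = min(chi2_gene, chi2_locus),
               direction = direction, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(list(enrichments = NULL,
                                 predictions = empty_predictions()))
  enr <- do.call(rbind, rows)
  enr$retained <- enr$direction == "over" & enr$o_locus >= min_loci &
    enr$chi2_min >= chi2_threshold
  enr <- enr[order(-enr$chi2_min, enr$family_id), , drop = FALSE]
  rownames(enr) <- NULL

  kept <- enr[enr$retained, , drop = FALSE]
  if (nrow(kept) == 0) {
    return(list(enrichments = enr, predictions = empty_predictions()))
  }
  rows <- lapply(sp, function(gid) {
    fams <- intersect(gf[[gid]], kept$family_id)
    if (!length(fams)) return(NULL)
    i <- which(kept$family_id %in% fams)[1]  # kept is sorted by chi2_min desc
    data.frame(gene_id = gid, family = kept$family_id[i],
               chi2 = kept$chi2_min[i], stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  df <- do.call(rbind, rows)
  preds <- expand_by_locus(space, bundle, df$gene_id, "CMP-ab", df$family,
                           df$family, df$chi2, rep("", nrow(df)))
  list(enrichments = enr, predictions = rank_predictions(preds))
}
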