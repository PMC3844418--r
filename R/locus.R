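## Locus construction from marker specifications, and SNP-to-gene search
## spaces via the adjacent and bystander mappings.

#' Specify a genomic interval
#'
#' Three specification modes mirror the usual ways a disease locus is
#' reported: a pair of flanking markers, a central marker with an interval
#' width, or explicit coordinates.
#'
#' @param mode One of \code{"marker_pair"}, \code{"center_width"},
#'   \code{"explicit"}.
#' @param marker_start_id,marker_end_id Marker ids (marker_pair mode).
#' @param center_marker_id Marker id (center_width mode).
#' @param width_bp Interval width in bp (center_width mode; > 0).
#' @param chrom,start,end Explicit 0-based half-open coordinates.
#' @return An \code{interval_spec} object.
#' @export
interval_spec <- function(mode = c("marker_pair", "center_width", "explicit"),
                          marker_start_id = NULL, marker_end_id = NULL,
                          center_marker_id = NULL, width_bp = NULL,
                          chrom = NULL, start = NULL, end = NULL) {
  mode <- match.arg(mode)
  spec <- list(mode = mode, marker_start_id = marker_start_id,
               marker_end_id = marker_end_id,
               center_marker_id = center_marker_id, width_bp = width_bp,
               chrom = chrom, start = start, end = end)
  class(spec) <- "interval_spec"
  spec
}

marker_row <- function(bundle, marker_id) {
  i <- match(marker_id, bundle$markers$marker_id)
  if (is.na(i)) stop("unknown marker_id '", marker_id, "'", call. = FALSE)
  bundle$markers[i, , drop = FALSE]
}

#' Resolve an interval specification to coordinates
#'
#' A marker pair resolves to \code{[min(pos), max(pos) + 1)} so both
#' marker positions are covered regardless of entry order; a central
#' marker with width \code{w} resolves to
#' \code{[max(0, pos - floor(w/2)), pos + floor(w/2))}; explicit
#' coordinates pass through.
#'
#' @param spec An \code{\link{interval_spec}}.
#' @param bundle A \code{\link{reference_bundle}} (for marker lookup).
#' @return list(chrom, start, end), 0-based half-open.
#' @export
resolve_interval <- function(spec, bundle) {
  stopifnot(inherits(spec, "interval_spec"))
  switch(spec$mode,
    marker_pair = {
      a <- marker_row(bundle, spec$marker_start_id)
      b <- marker_row(bundle, spec$marker_end_id)
      if (a$chrom != b$chrom) {
        stop("marker pair on different chromosomes: ",
             spec$marker_start_id, " / ", spec$marker_end_id, call. = FALSE)
      }
      list(chrom = a$chrom, start = min(a$pos, b$pos),
           end = max(a$pos, b$pos) + 1)
    },
    center_width = {
      if (is.null(spec$width_bp) || spec$width_bp <= 0) {
        stop("width_bp must be > 0", call. = FALSE)
      }
      m <- marker_row(bundle, spec$center_marker_id)
      half <- floor(spec$width_bp / 2)
      list(chrom = m$chrom, start = max(0, m$pos - half), end = m$pos + half)
    },
    explicit = {
      if (spec$start >= spec$end) stop("explicit interval with start >= end",
                                       call. = FALSE)
      list(chrom = spec$chrom, start = spec$start, end = spec$end)
    }
  )
}

#' Build a locus from an interval specification
#'
#' @param spec An \code{\link{interval_spec}}.
#' @param bundle A \code{\link{reference_bundle}}.
#' @param locus_id Identifier for the locus.
#' @return A \code{locus}: list(locus_id, chrom, start, end, gene_ids,
#'   provenance).  An empty gene list is allowed (with a warning).
#' @export
build_locus <- function(spec, bundle, locus_id) {
  iv <- resolve_interval(spec, bundle)
  g <- genes_in_interval(bundle, iv$chrom, iv$start, iv$end)
  if (nrow(g) == 0) {
    warning("locus '", locus_id, "' contains no genes", call. = FALSE)
  }
  structure(list(locus_id = locus_id, chrom = iv$chrom, start = iv$start,
                 end = iv$end, gene_ids = g$gene_id, provenance = spec),
            class = "locus")
}

#' Adjacent SNP-to-gene mapping
#'
#' Pools the genes adjacent to a SNP upstream and downstream on both
#' strands: every gene whose span contains the SNP position, plus, for
#' each strand and each side of the position, the nearest non-containing
#' gene whose closest edge lies on that side (at most four flanking
#' genes).  Equidistant candidates are broken by smaller start, then
#' gene id.
#'
#' @param snp A one-row marker data.frame (kind "snp") or marker_id.
#' @param bundle A \code{\link{reference_bundle}}.
#' @return data.frame of gene rows sorted by start (possibly empty).
#' @export
map_snp_adjacent <- function(snp, bundle) {
  if (is.character(snp)) snp <- marker_row(bundle, snp)
  stopifnot(snp$kind == "snp")
  g <- bundle$genes[bundle$genes$chrom == snp$chrom, , drop = FALSE]
  if (nrow(g) == 0) {
    warning("no genes on chromosome '", snp$chrom, "'", call. = FALSE)
    return(bundle$genes[0, , drop = FALSE])
  }
  pos <- snp$pos
  containing <- g$start <= pos & g$end > pos
  picked <- g$gene_id[containing]
  rest <- g[!containing, , drop = FALSE]
  side <- ifelse(rest$end <= pos, "L", "R")  # non-containing: L or R of pos
  dist <- ifelse(side == "L", pos - (rest$end - 1), rest$start - pos)
  for (str in c("+", "-")) {
    for (sd in c("L", "R")) {
      cand <- which(rest$strand == str & side == sd)
      if (!length(cand)) next
      o <- cand[order(dist[cand], rest$start[cand], rest$gene_id[cand])]
      picked <- c(picked, rest$gene_id[o[1]])
    }
  }
  out <- g[g$gene_id %in% unique(picked), , drop = FALSE]
  out <- out[order(out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bystander SNP-to-gene mapping
#'
#' Pools all genes overlapping a window of \code{window_bp} bases centred
#' on the SNP (default 1 Mbp).
#'
#' @param snp A one-row marker data.frame (kind "snp") or marker_id.
#' @param window_bp Window width in bp (> 0).
#' @param bundle A \code{\link{reference_bundle}}.
#' @param locus_id Identifier for the resulting locus.
#' @return A \code{locus} (see \code{\link{build_locus}}).
#' @export
map_snp_bystander <- function(snp, window_bp = 1e6, bundle, locus_id) {
  if (is.character(snp)) snp <- marker_row(bundle, snp)
  stopifnot(window_bp > 0)
  spec <- interval_spec("explicit", chrom = snp$chrom,
                        start = max(0, snp$pos - floor(window_bp / 2)),
                        end = snp$pos + floor(window_bp / 2))
  loc <- build_locus(spec, bundle, locus_id)
  loc$provenance <- list(snp = snp$marker_id, mode = "bystander",
                         window_bp = window_bp)
  loc
}

#' Build a gene search space from SNPs or interval specifications
#'
#' One locus is produced per input; genes belonging to several loci keep
#' their multi-membership (overlapping loci are never merged), and the
#' universe size counts distinct genes once.
#'
#' @param x For modes "adjacent"/"bystander": a marker data.frame (one SNP
#'   per row) or vector of marker ids.  For mode "intervals": a list of
#'   \code{\link{interval_spec}} objects (named to set locus ids).
#' @param mode One of "adjacent", "bystander", "intervals".
#' @param bundle A \code{\link{reference_bundle}}.
#' @param window_bp Window width for bystander mode (default 1 Mbp).
#' @param locus_ids Optional locus identifiers (defaults to marker ids or
#'   names of \code{x}).
#' @return A \code{search_space}: list(loci, locus_genes, gene_to_loci,
#'   universe_n).
#' @export
build_search_space <- function(x, mode = c("adjacent", "bystander", "intervals"),
                               bundle, window_bp = 1e6, locus_ids = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("adjacent", "bystander")) {
    if (is.character(x)) {
      x <- do.call(rbind, lapply(x, marker_row, bundle = bundle))
    }
    stopifnot(is.data.frame(x), nrow(x) > 0)
    if (is.null(locus_ids)) locus_ids <- x$marker_id
  } else {
    stopifnot(length(x) > 0)
    if (is.null(locus_ids)) {
      locus_ids <- if (!is.null(names(x))) names(x) else
        paste0("locus", seq_along(x))
    }
  }

  loci <- list()
  locus_genes <- list()
  for (i in seq_len(if (is.data.frame(x)) nrow(x) else length(x))) {
    lid <- locus_ids[i]
    if (mode == "adjacent") {
      snp <- x[i, , drop = FALSE]
      g <- map_snp_adjacent(snp, bundle)
      if (nrow(g) == 0) {
        warning("SNP '", lid, "' maps to no genes; locus dropped",
                call. = FALSE)
        next
      }
      loci[[lid]] <- data.frame(locus_id = lid, chrom = snp$chrom,
                                start = min(g$start), end = max(g$end),
                                provenance = paste0("snp:", snp$marker_id,
                                                    ":adjacent"),
                                stringsAsFactors = FALSE)
      locus_genes[[lid]] <- g$gene_id
    } else if (mode == "bystander") {
      snp <- x[i, , drop = FALSE]
      loc <- suppressWarnings(
        map_snp_bystander(snp, window_bp, bundle, lid))
      if (!length(loc$gene_ids)) {
        warning("SNP '", lid, "' maps to no genes; locus dropped",
                call. = FALSE)
        next
      }
      loci[[lid]] <- data.frame(locus_id = lid, chrom = loc$chrom,
                                start = loc$start, end = loc$end,
                                provenance = paste0("snp:", snp$marker_id,
                                                    ":bystander:", window_bp),
                                stringsAsFactors = FALSE)
      locus_genes[[lid]] <- loc$gene_ids
    } else {
      loc <- suppressWarnings(build_locus(x[[i]], bundle, lid))
      if (!length(loc$gene_ids)) {
        warning("interval '", lid, "' contains no genes; locus dropped",
                call. = FALSE)
        next
      }
      loci[[lid]] <- data.frame(locus_id = lid, chrom = loc$chrom,
                                start = loc$start, end = loc$end,
                                provenance = "interval",
                                stringsAsFactors = FALSE)
      locus_genes[[lid]] <- loc$gene_ids
    }
  }
  if (!length(loci)) stop("no input locus could be mapped to genes",
                          call. = FALSE)
  loci <- do.call(rbind, loci)
  rownames(loci) <- NULL
  gene_to_loci <- list()
  for (lid in names(locus_genes)) {
    for (gid in locus_genes[[lid]]) {
      gene_to_loci[[gid]] <- c(gene_to_loci[[gid]], lid)
    }
  }
  gene_to_loci <- lapply(gene_to_loci, sort)
  structure(list(loci = loci, locus_genes = locus_genes,
                 gene_to_loci = gene_to_loci,
                 universe_n = length(gene_to_loci)),
            class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat("search_space:", nrow(x$loci), "loci,", x$universe_n,
      "distinct genes\n")
  invisible(x)
}

space_genes <- function(space) names(space$gene_to_loci)

#' Read a pasted SNP batch
#'
#' One entry per line: a marker id known to the bundle, or
#' \code{chrom:pos} (0-based position).  \code{#} comments and blank
#' lines are skipped.
#'
#' @param path Path to the batch file.
#' @param bundle A \code{\link{reference_bundle}}.
#' @return Marker data.frame (kind "snp").
#' @export
read_snp_batch <- function(path, bundle) {
  raw <- readLines(path, warn = FALSE)
  raw <- trimws(sub("#.*$", "", raw))
  raw <- raw[nzchar(raw)]
  if (!length(raw)) stop("empty SNP batch: ", path, call. = FALSE)
  rows <- lapply(raw, function(tok) {
    if (grepl(":", tok, fixed = TRUE)) {
      p <- strsplit(tok, ":", fixed = TRUE)[[1]]
      data.frame(marker_id = tok, kind = "snp", chrom = p[1],
                 pos = as.numeric(p[2]), stringsAsFactors = FALSE)
    } else {
      m <- marker_row(bundle, tok)
      m$kind <- "snp"
      m
    }
  })
  do.call(rbind, rows)
}

#' Read an interval batch table
#'
#' Tab-separated rows in one of three layouts: \code{locus_id chrom start
#' end} (explicit), \code{locus_id marker_a marker_b} (marker pair), or
#' \code{locus_id center_marker width_bp} (center + width; recognized
#' when the third field is numeric and the second is a known marker).
#'
#' @param path Path to the batch file.
#' @param bundle A \code{\link{reference_bundle}}.
#' @return Named list of \code{\link{interval_spec}} objects.
#' @export
read_interval_batch <- function(path, bundle) {
  tl <- read_tab_lines(path, 3L, "interval batch")
  specs <- list()
  for (i in seq_along(tl$fields)) {
    f <- tl$fields[[i]]
    id <- f[1]
    if (length(f) >= 4L &&
        !is.na(suppressWarnings(as.numeric(f[3]))) &&
        !is.na(suppressWarnings(as.numeric(f[4])))) {
      specs[[id]] <- interval_spec("explicit", chrom = f[2],
                                   start = as.numeric(f[3]),
                                   end = as.numeric(f[4]))
    } else if (!is.na(suppressWarnings(as.numeric(f[3]))) &&
               f[2] %in% bundle$markers$marker_id) {
      specs[[id]] <- interval_spec("center_width", center_marker_id = f[2],
                                   width_bp = as.numeric(f[3]))
    } else {
      specs[[id]] <- interval_spec("marker_pair", marker_start_id = f[2],
                                   marker_end_id = f[3])
    }
  }
  specs
}

#' Export a search space to BED and TSV
#'
#' Writes the loci as BED (0-based half-open, as stored) and the gene
#' membership as a TSV of gene_id, symbol and comma-separated locus ids.
#'
#' @param space A \code{search_space}.
#' @param bundle A \code{\link{reference_bundle}} (for symbols).
#' @param bed_path,tsv_path Output paths.
#' @return Invisibly, c(bed_path, tsv_path).
#' @export
write_search_space <- function(space, bundle, bed_path, tsv_path) {
  l <- space$loci
  writeLines(sprintf("%s\t%d\t%d\t%s", l$chrom, as.integer(l$start),
                     as.integer(l$end), l$locus_id), bed_path)
  gid <- sort(space_genes(space))
  sym <- bundle$genes$symbol[match(gid, bundle$genes$gene_id)]
  writeLines(c("gene_id\tsymbol\tlocus_ids",
               sprintf("%s\t%s\t%s", gid, sym,
                       vapply(space$gene_to_loci[gid], paste, "",
                              collapse = ","))), tsv_path)
  invisible(c(bed_path, tsv_path))
}
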