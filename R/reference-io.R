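## File readers and writers for the reference bundle.  All genomic
## coordinates are 0-based half-open internally (BED convention); reports
## print 1-based inclusive.

# Split non-comment lines into fields, keeping original line numbers so
# malformed records can be reported precisely.
read_tab_lines <- function(path, min_fields, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineno <- which(keep)
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  # tolerate space-separated files
  one <- lengths(fields) == 1L & grepl("[ ]", raw[keep])
  fields[one] <- strsplit(trimws(raw[keep][one]), "[[:space:]]+")
  bad <- lengths(fields) < min_fields
  if (any(bad)) {
    stop(sprintf("%s: malformed line %d in '%s' (expected >= %d fields)",
                 what, lineno[which(bad)[1]], path, min_fields),
         call. = FALSE)
  }
  list(fields = fields, lineno = lineno, path = path)
}

as_num_or_die <- function(x, what, path, lineno) {
  y <- suppressWarnings(as.numeric(x))
  if (anyNA(y)) {
    stop(sprintf("%s: non-numeric value at line %d in '%s'",
                 what, lineno[which(is.na(y))[1]], path), call. = FALSE)
  }
  y
}

drop_header <- function(tl, header_words) {
  if (length(tl$fields) &&
      any(tolower(tl$fields[[1]]) %in% header_words)) {
    tl$fields <- tl$fields[-1]
    tl$lineno <- tl$lineno[-1]
  }
  tl
}

#' Read a BED6(+symbol) gene annotation table
#'
#' Columns: chrom, start, end, name (gene_id), score (ignored), strand,
#' and an optional seventh column holding a display symbol.  Coordinates
#' are BED-native 0-based half-open.
#'
#' @param path Path to a BED file.
#' @return data.frame with columns gene_id, symbol, chrom, start, end,
#'   strand.
#' @export
read_genes_bed <- function(path) {
  tl <- read_tab_lines(path, 6L, "genes BED")
  f <- tl$fields
  df <- data.frame(
    gene_id = vapply(f, `[`, "", 4L),
    symbol  = vapply(f, function(x) if (length(x) >= 7L) x[7L] else x[4L], ""),
    chrom   = vapply(f, `[`, "", 1L),
    start   = as_num_or_die(vapply(f, `[`, "", 2L), "genes BED", tl$path, tl$lineno),
    end     = as_num_or_die(vapply(f, `[`, "", 3L), "genes BED", tl$path, tl$lineno),
    strand  = vapply(f, `[`, "", 6L),
    stringsAsFactors = FALSE
  )
  bad <- !(df$start < df$end) | !(df$strand %in% c("+", "-"))
  if (any(bad)) {
    stop(sprintf("genes BED: invalid record at line %d in '%s'",
                 tl$lineno[which(bad)[1]], path), call. = FALSE)
  }
  if (anyDuplicated(df$gene_id)) {
    stop("genes BED: duplicated gene_id '",
         df$gene_id[anyDuplicated(df$gene_id)], "' in ", path, call. = FALSE)
  }
  df
}

#' Read gene sets in GMT format
#'
#' One set per line: set_id, description, then member gene ids.  The
#' description field carries the source database label, optionally as
#' \code{"source|name"}; a bare label is used as the source with the set
#' id reused as the display name.
#'
#' @param path Path to a GMT file.
#' @return list with \code{sets} (data.frame set_id, source_db, name) and
#'   \code{members} (list of character vectors, one per set).
#' @export
read_gmt <- function(path) {
  tl <- read_tab_lines(path, 3L, "GMT")
  f <- tl$fields
  desc <- vapply(f, `[`, "", 2L)
  has_name <- grepl("|", desc, fixed = TRUE)
  source_db <- ifelse(has_name, sub("\\|.*$", "", desc),
                      ifelse(nzchar(desc), desc, "custom"))
  name <- ifelse(has_name, sub("^[^|]*\\|", "", desc),
                 vapply(f, `[`, "", 1L))
  sets <- data.frame(
    set_id = vapply(f, `[`, "", 1L),
    source_db = source_db,
    name = name,
    stringsAsFactors = FALSE
  )
  key <- paste(sets$source_db, sets$set_id, sep = ":")
  if (anyDuplicated(key)) {
    stop("GMT: duplicated set_id within a source in ", path, call. = FALSE)
  }
  members <- lapply(f, function(x) unique(x[-(1:2)][nzchar(x[-(1:2)])]))
  names(members) <- key
  list(sets = sets, members = members)
}

#' Read an undirected interaction edge list
#'
#' Three tab-separated columns (gene_a, gene_b, source); a header line and
#' \code{#} comments are tolerated.
#'
#' @param path Path to a TSV file.
#' @return data.frame gene_a, gene_b, source (un-canonicalized; the bundle
#'   constructor canonicalizes and drops self-edges).
#' @export
read_edges_tsv <- function(path) {
  tl <- drop_header(read_tab_lines(path, 2L, "edges"),
                    c("gene_a", "genea", "from"))
  f <- tl$fields
  data.frame(
    gene_a = vapply(f, `[`, "", 1L),
    gene_b = vapply(f, `[`, "", 2L),
    source = vapply(f, function(x) if (length(x) >= 3L) x[3L] else "ppi", ""),
    stringsAsFactors = FALSE
  )
}

#' Read per-protein domain assignments
#'
#' Five tab-separated columns: protein_id, family_id, ali_start, ali_end
#' (0-based half-open protein coordinates), bit_score.
#'
#' @param path Path to a TSV file.
#' @return data.frame protein_id, family_id, ali_start, ali_end, bit_score.
#' @export
read_domains_tsv <- function(path) {
  tl <- drop_header(read_tab_lines(path, 4L, "domains"),
                    c("protein_id", "protein"))
  f <- tl$fields
  data.frame(
    protein_id = vapply(f, `[`, "", 1L),
    family_id  = vapply(f, `[`, "", 2L),
    ali_start  = as_num_or_die(vapply(f, `[`, "", 3L), "domains", tl$path, tl$lineno),
    ali_end    = as_num_or_die(vapply(f, `[`, "", 4L), "domains", tl$path, tl$lineno),
    bit_score  = suppressWarnings(as.numeric(
      vapply(f, function(x) if (length(x) >= 5L) x[5L] else "NA", ""))),
    stringsAsFactors = FALSE
  )
}

#' Read protein sequences from FASTA
#'
#' Header token 1 is the protein_id; an optional \code{gene=<id>} token
#' links the protein to its gene.
#'
#' @param path Path to a FASTA file.
#' @return data.frame protein_id, gene_id, residues.
#' @export
read_proteins_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  hdr <- names(aa)
  toks <- strsplit(hdr, "[[:space:]]+")
  pid <- vapply(toks, `[`, "", 1L)
  gid <- vapply(toks, function(x) {
    g <- grep("^gene=", x, value = TRUE)
    if (length(g)) sub("^gene=", "", g[1]) else NA_character_
  }, "")
  data.frame(protein_id = pid, gene_id = gid,
             residues = as.character(aa), stringsAsFactors = FALSE)
}

#' Read a marker table
#'
#' Four tab-separated columns: marker_id, kind (snp or sts), chrom, pos
#' (0-based).
#'
#' @param path Path to a TSV file.
#' @return data.frame marker_id, kind, chrom, pos.
#' @export
read_markers_tsv <- function(path) {
  tl <- drop_header(read_tab_lines(path, 4L, "markers"),
                    c("marker_id", "marker"))
  f <- tl$fields
  df <- data.frame(
    marker_id = vapply(f, `[`, "", 1L),
    kind      = tolower(vapply(f, `[`, "", 2L)),
    chrom     = vapply(f, `[`, "", 3L),
    pos       = as_num_or_die(vapply(f, `[`, "", 4L), "markers", tl$path, tl$lineno),
    stringsAsFactors = FALSE
  )
  bad <- !(df$kind %in% c("snp", "sts")) | df$pos < 0
  if (any(bad)) {
    stop(sprintf("markers: invalid record at line %d in '%s'",
                 tl$lineno[which(bad)[1]], path), call. = FALSE)
  }
  df
}

#' Read a phenotype-to-seed-gene table
#'
#' Three tab-separated columns: phenotype_id, free-text phenotype name,
#' comma-separated seed gene ids or symbols (a remediated morbid-map-like
#' table).
#'
#' @param path Path to a TSV file.
#' @return list with \code{phenotypes} (data.frame phenotype_id, name) and
#'   \code{seeds} (list of character vectors keyed by phenotype_id).
#' @export
read_phenotypes_tsv <- function(path) {
  tl <- drop_header(read_tab_lines(path, 2L, "phenotypes"),
                    c("phenotype_id", "phenotype"))
  f <- tl$fields
  df <- data.frame(
    phenotype_id = vapply(f, `[`, "", 1L),
    name         = vapply(f, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
  seeds <- lapply(f, function(x) {
    if (length(x) < 3L || !nzchar(x[3L])) return(character())
    unique(trimws(strsplit(x[3L], ",", fixed = TRUE)[[1]]))
  })
  names(seeds) <- df$phenotype_id
  list(phenotypes = df, seeds = seeds)
}

#' Write a reference bundle back to disk
#'
#' Emits the same plain-text formats the readers consume (genes.bed,
#' sets.gmt, edges.tsv, domains.tsv, proteins.fasta, markers.tsv,
#' phenotypes.tsv), so that a written bundle reloads identically.
#'
#' @param bundle A \code{\link{reference_bundle}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_reference <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genes = file.path(dir, "genes.bed"),
    gene_sets = file.path(dir, "sets.gmt"),
    edges = file.path(dir, "edges.tsv"),
    domains = file.path(dir, "domains.tsv"),
    proteins = file.path(dir, "proteins.fasta"),
    markers = file.path(dir, "markers.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv")
  )
  g <- bundle$genes
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s\t%s", g$chrom, as.integer(g$start),
                     as.integer(g$end), g$gene_id, g$strand, g$symbol),
             paths["genes"])
  s <- bundle$gene_sets
  writeLines(vapply(seq_len(nrow(s)), function(i) {
    key <- paste(s$source_db[i], s$set_id[i], sep = ":")
    paste(c(s$set_id[i], paste0(s$source_db[i], "|", s$name[i]),
            bundle$set_members[[key]]), collapse = "\t")
  }, ""), paths["gene_sets"])
  e <- bundle$edges
  writeLines(c("gene_a\tgene_b\tsource",
               sprintf("%s\t%s\t%s", e$gene_a, e$gene_b, e$source)),
             paths["edges"])
  d <- bundle$domains
  writeLines(c("protein_id\tfamily_id\tali_start\tali_end\tbit_score",
               sprintf("%s\t%s\t%d\t%d\t%s", d$protein_id, d$family_id,
                       as.integer(d$ali_start), as.integer(d$ali_end),
                       ifelse(is.na(d$bit_score), "NA",
                              format(d$bit_score, trim = TRUE)))),
             paths["domains"])
  p <- bundle$proteins
  writeLines(as.vector(rbind(sprintf(">%s gene=%s", p$protein_id, p$gene_id),
                             p$residues)), paths["proteins"])
  m <- bundle$markers
  writeLines(c("marker_id\tkind\tchrom\tpos",
               sprintf("%s\t%s\t%s\t%d", m$marker_id, m$kind, m$chrom,
                       as.integer(m$pos))), paths["markers"])
  ph <- bundle$phenotypes
  writeLines(c("phenotype_id\tname\tseed_genes",
               vapply(seq_len(nrow(ph)), function(i) {
                 sprintf("%s\t%s\t%s", ph$phenotype_id[i], ph$name[i],
                         paste(bundle$phenotype_seeds[[ph$phenotype_id[i]]],
                               collapse = ","))
               }, "")), paths["phenotypes"])
  invisible(paths)
}
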