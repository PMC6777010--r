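# Gene coordinate catalog and rank-order primitives.
#
# All downstream reasoning ("between", "nearest") happens in rank space:
# genes on one chromosome are ordered by (start, end, symbol) and numbered
# 0..n-1. Coordinates are stored 0-based half-open (BED convention).

#' Construct a genome index from gene records
#'
#' A genome index is the catalog the whole inference engine runs on: one
#' record per gene symbol, with a per-chromosome rank (0-based position in
#' the sort by start, end, symbol). Nested or overlapping genes are handled
#' deterministically because every operation downstream is defined on ranks,
#' never on base-pair arithmetic.
#'
#' @param symbol character vector of gene symbols (non-empty, no whitespace).
#' @param chrom chromosome name per gene.
#' @param start,end integer coordinates, 0-based half-open (`start < end`).
#' @param cytoband optional cytogenetic band per gene (e.g. `"11q13.3"`);
#'   `NULL` if unavailable.
#' @return An object of class `genome_index`: a list with element `genes`,
#'   a data frame with columns `symbol`, `chrom`, `start`, `end`,
#'   `cytoband`, `rank`, sorted by chromosome (natural order) then rank,
#'   and element `has_cytoband`.
#' @examples
#' gi <- genome_index(c("A", "B"), c("chr1", "chr1"), c(0L, 100L), c(50L, 200L))
#' gi$genes$rank
#' @export
genome_index <- function(symbol, chrom, start, end, cytoband = NULL) {
  n <- length(symbol)
  stopifnot(length(chrom) == n, length(start) == n, length(end) == n)
  symbol <- as.character(symbol)
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end))) {
    stop("gene coordinates must be integers", call. = FALSE)
  }
  if (any(!nzchar(symbol)) || any(grepl("\\s", symbol))) {
    stop("gene symbols must be non-empty tokens without whitespace", call. = FALSE)
  }
  bad <- which(start >= end)
  if (length(bad) > 0L) {
    stop(sprintf("gene '%s': start (%d) must be < end (%d)",
                 symbol[bad[1L]], start[bad[1L]], end[bad[1L]]), call. = FALSE)
  }
  dup <- unique(symbol[duplicated(toupper(symbol))])
  if (length(dup) > 0L) {
    stop(sprintf("duplicate gene symbol(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(cytoband)) {
    cytoband <- rep(NA_character_, n)
  } else {
    cytoband <- as.character(cytoband)
    stopifnot(length(cytoband) == n)
  }
  genes <- data.frame(symbol = symbol, chrom = chrom, start = start, end = end,
                      cytoband = cytoband, stringsAsFactors = FALSE)
  # rank within chromosome by (start, end, symbol)
  ord <- order(chrom_sort_key(genes$chrom), genes$start, genes$end, genes$symbol)
  genes <- genes[ord, , drop = FALSE]
  genes$rank <- stats::ave(seq_len(nrow(genes)), genes$chrom,
                           FUN = function(i) seq_along(i) - 1L)
  genes$rank <- as.integer(genes$rank)
  rownames(genes) <- NULL
  structure(list(genes = genes,
                 has_cytoband = any(!is.na(genes$cytoband))),
            class = "genome_index")
}

# Natural chromosome ordering: chr1 < chr2 < ... < chr10 < ... < chrX < chrY
# < chrM, any other names after, alphabetically.
chrom_sort_key <- function(chrom) {
  core <- sub("^chr", "", chrom, ignore.case = TRUE)
  num <- suppressWarnings(as.integer(core))
  key <- ifelse(!is.na(num), sprintf("0%04d", num),
         ifelse(toupper(core) == "X", "10000",
         ifelse(toupper(core) == "Y", "10001",
         ifelse(toupper(core) %in% c("M", "MT"), "10002",
                paste0("2", core)))))
  key
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("<genome_index> %d genes on %d chromosome(s)%s\n",
              nrow(x$genes), length(unique(x$genes$chrom)),
              if (x$has_cytoband) ", with cytobands" else ""))
  invisible(x)
}

#' Number of genes in a genome index
#' @param index a `genome_index`.
#' @param chrom optional chromosome name; if given, count genes on it.
#' @return integer count.
#' @export
n_genes <- function(index, chrom = NULL) {
  stopifnot(inherits(index, "genome_index"))
  if (is.null(chrom)) return(nrow(index$genes))
  sum(index$genes$chrom == chrom)
}

#' Load gene coordinates from a file
#'
#' Reads a gene coordinate table and builds a [genome_index()]. Three
#' dialects are accepted:
#' \describe{
#'   \item{`tsv4`}{`symbol<TAB>chrom<TAB>start<TAB>end`, 1-based inclusive
#'     coordinates (UCSC browser text convention); converted to 0-based
#'     half-open on load.}
#'   \item{`tsv5`}{`tsv4` plus a fifth cytoband column.}
#'   \item{`bed4`}{BED: `chrom<TAB>start<TAB>end<TAB>symbol`, already
#'     0-based half-open.}
#' }
#' Blank lines and lines starting with `#` are ignored. The whole load is
#' rejected on the first malformed row (wrong column count, non-integer
#' coordinates, start >= end, reported with its line number) or on a
#' duplicate symbol. A source listing several intervals for one symbol is
#' therefore rejected rather than collapsed: collapsing multi-transcript
#' genes to a single interval is a data-preparation step upstream of this
#' loader.
#'
#' @param source path to the coordinate file, or a character vector of lines.
#' @param dialect one of `"tsv4"`, `"tsv5"`, `"bed4"`.
#' @return a [genome_index()].
#' @export
load_gene_coordinates <- function(source, dialect = c("tsv4", "tsv5", "bed4")) {
  dialect <- match.arg(dialect)
  lines <- read_source_lines(source)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(keep) == 0L) stop("coordinate file has no data rows", call. = FALSE)
  ncol_expect <- switch(dialect, tsv4 = 4L, tsv5 = 5L, bed4 = 4L)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != ncol_expect)
  if (length(bad) > 0L) {
    stop(sprintf("line %d: expected %d tab-separated fields, found %d",
                 keep[bad[1L]], ncol_expect, nf[bad[1L]]), call. = FALSE)
  }
  m <- matrix(trimws(unlist(fields)), ncol = ncol_expect, byrow = TRUE)
  if (dialect == "bed4") {
    symbol <- m[, 4L]; chrom <- m[, 1L]
    start_raw <- m[, 2L]; end_raw <- m[, 3L]
    cytoband <- NULL
  } else {
    symbol <- m[, 1L]; chrom <- m[, 2L]
    start_raw <- m[, 3L]; end_raw <- m[, 4L]
    cytoband <- if (dialect == "tsv5") m[, 5L] else NULL
  }
  start <- suppressWarnings(as.integer(start_raw))
  end <- suppressWarnings(as.integer(end_raw))
  bad <- which(is.na(start) | is.na(end) |
                 start_raw != as.character(start) | end_raw != as.character(end))
  if (length(bad) > 0L) {
    stop(sprintf("line %d: non-integer coordinate ('%s', '%s')",
                 keep[bad[1L]], start_raw[bad[1L]], end_raw[bad[1L]]),
         call. = FALSE)
  }
  if (dialect != "bed4") start <- start - 1L  # 1-based inclusive -> 0-based half-open
  bad <- which(start >= end)
  if (length(bad) > 0L) {
    stop(sprintf("line %d: start must be < end for gene '%s'",
                 keep[bad[1L]], symbol[bad[1L]]), call. = FALSE)
  }
  dup <- unique(symbol[duplicated(toupper(symbol))])
  if (length(dup) > 0L) {
    stop(sprintf("duplicate gene symbol(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  genome_index(symbol, chrom, start, end, cytoband)
}

#' Write gene coordinates to a file
#'
#' Inverse of [load_gene_coordinates()]: serializes an index in any of the
#' accepted dialects so that a reload reproduces the index exactly.
#'
#' @param index a `genome_index`.
#' @param path output file path.
#' @param dialect output dialect, as in [load_gene_coordinates()].
#' @return `path`, invisibly.
#' @export
write_gene_coordinates <- function(index, path,
                                   dialect = c("tsv4", "tsv5", "bed4")) {
  dialect <- match.arg(dialect)
  g <- index$genes
  lines <- switch(dialect,
    tsv4 = sprintf("%s\t%s\t%d\t%d", g$symbol, g$chrom, g$start + 1L, g$end),
    tsv5 = sprintf("%s\t%s\t%d\t%d\t%s", g$symbol, g$chrom, g$start + 1L, g$end,
                   ifelse(is.na(g$cytoband), "", g$cytoband)),
    bed4 = sprintf("%s\t%d\t%d\t%s", g$chrom, g$start, g$end, g$symbol))
  writeLines(lines, path)
  invisible(path)
}

read_source_lines <- function(source) {
  if (length(source) == 1L && !grepl("[\n\t]", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else if (length(source) == 1L && grepl("\n", source)) {
    strsplit(source, "\n", fixed = TRUE)[[1L]]
  } else if (length(source) > 1L || (length(source) == 1L && grepl("\t", source))) {
    as.character(source)
  } else {
    stop(sprintf("cannot read '%s': file not found", source), call. = FALSE)
  }
}

#' Resolve gene symbols against a genome index
#'
#' Case-insensitive exact matching (clinical reports vary in casing, e.g.
#' C15ORF65 vs C15orf65); matched records always carry the index's casing.
#' This is a partition, not a validation: unknown tokens are returned to the
#' caller, which decides severity.
#'
#' @param index a `genome_index`.
#' @param symbols character vector of symbols to look up.
#' @return list with `known` (data frame of matched gene records, input
#'   order) and `unknown` (character vector of unmatched tokens, input
#'   order). Every input token lands in exactly one of the two.
#' @export
resolve_symbols <- function(index, symbols) {
  stopifnot(inherits(index, "genome_index"))
  symbols <- as.character(symbols)
  idx <- match(toupper(symbols), toupper(index$genes$symbol))
  known <- index$genes[idx[!is.na(idx)], , drop = FALSE]
  rownames(known) <- NULL
  list(known = known, unknown = symbols[is.na(idx)])
}

# Single-symbol lookup; NULL if absent.
lookup_gene <- function(index, symbol) {
  i <- match(toupper(symbol), toupper(index$genes$symbol))
  if (is.na(i)) return(NULL)
  index$genes[i, , drop = FALSE]
}

#' Genes within a rank interval on one chromosome
#'
#' @param index a `genome_index`.
#' @param chrom chromosome name.
#' @param lo,hi 0-based ranks, `0 <= lo <= hi <` chromosome gene count;
#'   both endpoints are included.
#' @return data frame of gene records with rank in `[lo, hi]`, rank order.
#' @export
genes_in_rank_span <- function(index, chrom, lo, hi) {
  stopifnot(inherits(index, "genome_index"))
  on_chrom <- index$genes[index$genes$chrom == chrom, , drop = FALSE]
  if (nrow(on_chrom) == 0L) {
    stop(sprintf("unknown chromosome '%s'", chrom), call. = FALSE)
  }
  nmax <- nrow(on_chrom) - 1L
  if (lo < 0L || hi > nmax || lo > hi) {
    stop(sprintf("rank span [%d, %d] invalid on %s (valid ranks 0..%d, lo <= hi)",
                 lo, hi, chrom, nmax), call. = FALSE)
  }
  out <- on_chrom[on_chrom$rank >= lo & on_chrom$rank <= hi, , drop = FALSE]
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach cytoband labels from a UCSC-style cytoBand file
#'
#' Reads a `chrom<TAB>start<TAB>end<TAB>band` table (0-based half-open, as
#' distributed by the UCSC genome browser) and assigns each gene the band
#' containing its start position. Genes on chromosomes absent from the band
#' file keep `NA`.
#'
#' @param index a `genome_index`.
#' @param source path to the cytoband file (or character vector of lines).
#' @return a new `genome_index` with cytobands populated.
#' @export
add_cytobands <- function(index, source) {
  stopifnot(inherits(index, "genome_index"))
  lines <- read_source_lines(source)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(lengths(fields) != 4L)) {
    stop("cytoband file must have 4 tab-separated fields per row", call. = FALSE)
  }
  m <- matrix(trimws(unlist(fields)), ncol = 4L, byrow = TRUE)
  bchrom <- m[, 1L]
  bstart <- as.integer(m[, 2L])
  bend <- as.integer(m[, 3L])
  bname <- m[, 4L]
  g <- index$genes
  band <- rep(NA_character_, nrow(g))
  for (i in seq_len(nrow(g))) {
    hit <- which(bchrom == g$chrom[i] & bstart <= g$start[i] & g$start[i] < bend)
    if (length(hit) > 0L) band[i] <- bname[hit[1L]]
  }
  genome_index(g$symbol, g$chrom, g$start, g$end, band)
}
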