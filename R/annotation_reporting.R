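# Census annotation, region labels, co-amplification counts and rendering.
#
# The report pools core (considered amplified) and boundary (possibly
# amplified) genes: the point is to list everything that may be co-amplified
# with the reported genes, so "co-amplified count" = |core u boundary| minus
# the reported genes themselves, and census membership is evaluated over the
# same pooled extent.

COSMIC_LINK_TEMPLATE <- "https://cancer.sanger.ac.uk/cosmic/gene/analysis?ln={symbol}"
RENDER_FORMATS <- c("text", "tsv", "json", "bed")

#' Construct a cancer census set
#' @param symbols character vector of census gene symbols.
#' @param tier optional per-symbol tier labels (same length as `symbols`).
#' @return object of class `census_set`.
#' @export
census_set <- function(symbols, tier = NULL) {
  symbols <- trimws(as.character(symbols))
  keep <- nzchar(symbols) & !duplicated(toupper(symbols))
  if (!is.null(tier)) {
    stopifnot(length(tier) == length(symbols))
    tier <- as.character(tier)[keep]
  }
  symbols <- symbols[keep]
  if (length(symbols) == 0L) stop("census set has no genes", call. = FALSE)
  structure(list(symbols = symbols, tier = tier), class = "census_set")
}

#' @export
print.census_set <- function(x, ...) {
  cat(sprintf("<census_set> %d genes%s\n", length(x$symbols),
              if (is.null(x$tier)) "" else ", with tiers"))
  invisible(x)
}

#' Load a cancer gene census list
#'
#' One symbol per line, optionally followed by a tab and a tier label
#' (COSMIC cancer gene census style, Tier 1/2). Blank lines and `#`
#' comments are ignored; duplicates collapse.
#'
#' @param source path to the census file (or character vector of lines).
#' @return a [census_set()].
#' @export
load_census <- function(source) {
  lines <- read_source_lines(source)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("census file has no genes", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  symbols <- vapply(fields, `[[`, character(1), 1L)
  tiers <- vapply(fields, function(f) if (length(f) >= 2L) f[[2L]] else NA_character_,
                  character(1))
  census_set(symbols, tier = if (all(is.na(tiers))) NULL else tiers)
}

#' Region label for an amplicon
#'
#' Labels describe the full possibly-amplified extent (boundary + core +
#' boundary), not just the core: the extent is the region a reader should
#' consider amplified. With cytobands loaded, the label is
#' `Chr<band of first extent gene>-<band of last extent gene>`, collapsing
#' to a single band when both ends fall in the same band (e.g. `Chr4q12`).
#' Without cytobands the label falls back to outermost coordinates,
#' `chrom:start-end` (0-based half-open).
#'
#' @param call a completed `amplicon_call`.
#' @param index the [genome_index()] the call was made on.
#' @return label string.
#' @export
region_label <- function(call, index) {
  stopifnot(inherits(call, "amplicon_call"), inherits(index, "genome_index"))
  extent <- call_extent_symbols(call)
  g <- index$genes[match(extent, index$genes$symbol), , drop = FALSE]
  first <- g[1L, ]; last <- g[nrow(g), ]
  if (index$has_cytoband && !is.na(first$cytoband) && !is.na(last$cytoband)) {
    if (first$cytoband == last$cytoband) {
      sprintf("Chr%s", first$cytoband)
    } else {
      sprintf("Chr%s–%s", first$cytoband, last$cytoband)
    }
  } else {
    sprintf("%s:%d-%d", call$chrom, min(g$start), max(g$end))
  }
}

cosmic_link <- function(symbol, template = COSMIC_LINK_TEMPLATE) {
  vapply(symbol, function(s) gsub("{symbol}", s, template, fixed = TRUE),
         character(1), USE.NAMES = TRUE)
}

#' Annotate one amplicon call
#'
#' Computes the census genes within the full extent (reported genes that are
#' census members are included — the report lists them alongside the
#' potentially co-amplified ones), the co-amplified count (extent genes
#' minus reported genes) and one external link per listed gene. Links are
#' string construction only; nothing is fetched.
#'
#' @param call a completed `amplicon_call`.
#' @param census a [census_set()] (or `NULL`).
#' @param index the [genome_index()] the call was made on.
#' @param link_template URL template applied per gene; `{symbol}` is
#'   replaced by the gene symbol.
#' @return object of class `amplicon_report`.
#' @export
annotate_call <- function(call, census, index,
                          link_template = COSMIC_LINK_TEMPLATE) {
  stopifnot(inherits(call, "amplicon_call"))
  extent <- call_extent_symbols(call)
  census_syms <- if (is.null(census)) character(0) else census$symbols
  census_genes <- extent[toupper(extent) %in% toupper(census_syms)]
  coamp <- length(extent) - length(call$reported_genes)
  g <- index$genes[match(extent, index$genes$symbol), , drop = FALSE]
  listed <- unique(c(call$reported_genes, census_genes))
  structure(list(
    call = call,
    region_label = region_label(call, index),
    coamplified_count = coamp,
    census_genes = census_genes,
    links = cosmic_link(listed, link_template),
    reported_locations = stats::setNames(
      index$genes$cytoband[match(call$reported_genes, index$genes$symbol)],
      call$reported_genes),
    chrom = call$chrom,
    core_start = min(g$start[match(call$core_genes, extent)]),
    core_end = max(g$end[match(call$core_genes, extent)]),
    extent_start = min(g$start),
    extent_end = max(g$end),
    extent_genes = extent
  ), class = "amplicon_report")
}

#' Annotate a full set of amplicon calls
#'
#' @param calls `amplicon_calls` from [infer_amplicons()].
#' @param index the [genome_index()] used for inference.
#' @param census a [census_set()] or `NULL`.
#' @param link_template see [annotate_call()].
#' @return object of class `amplicon_reports` (list of `amplicon_report`,
#'   same order as `calls`); the status map travels along for verbose
#'   rendering.
#' @export
annotate_amplicons <- function(calls, index, census = NULL,
                               link_template = COSMIC_LINK_TEMPLATE) {
  stopifnot(inherits(calls, "amplicon_calls"))
  reports <- lapply(calls, annotate_call, census = census, index = index,
                    link_template = link_template)
  structure(reports, class = "amplicon_reports",
            statuses = attr(calls, "statuses"))
}

#' @export
print.amplicon_reports <- function(x, ...) {
  cat(render_reports(x, format = "text"), sep = "\n")
  invisible(x)
}

# ---- rendering ----

#' Render amplicon reports
#'
#' @param reports `amplicon_reports` from [annotate_amplicons()].
#' @param format one of `"text"` (human-readable table: reported genes with
#'   locations, co-amplified count with region label, census genes,
#'   adjacency flags), `"tsv"` (same content, one row per amplicon, fixed
#'   header), `"json"` (full structured calls) or `"bed"` (two tracks:
#'   core extents, and possibly-amplified extensions per non-empty side;
#'   0-based half-open).
#' @param verbose add the full assayed gene list, the identity of all genes
#'   in each inferred amplicon, and the assayed non-amplified genes used to
#'   delimit the boundaries (`text` and `json` formats).
#' @return character vector: the lines of the rendered document.
#' @export
render_reports <- function(reports, format = "text", verbose = FALSE) {
  stopifnot(inherits(reports, "amplicon_reports"))
  if (!is.character(format) || length(format) != 1L ||
      !(format %in% RENDER_FORMATS)) {
    stop(sprintf("unknown format '%s' (available: %s)",
                 paste(format, collapse = ","),
                 paste(RENDER_FORMATS, collapse = ", ")), call. = FALSE)
  }
  switch(format,
         text = render_text(reports, verbose),
         tsv = render_tsv(reports),
         json = render_json(reports, verbose),
         bed = render_bed(reports))
}

fmt_reported <- function(r) {
  loc <- r$reported_locations
  paste(ifelse(is.na(loc),
               names(loc),
               sprintf("%s (Chr%s)", names(loc), loc)),
        collapse = ", ")
}

render_text <- function(reports, verbose) {
  if (length(reports) == 0L) return("No amplicons inferred.")
  rows <- data.frame(
    Amplicon = vapply(reports, function(r) r$call$id, character(1)),
    `Genes reported amplified` = vapply(reports, fmt_reported, character(1)),
    `Co-amplified (region)` = vapply(reports, function(r)
      sprintf("%d (%s)", r$coamplified_count, r$region_label), character(1)),
    `Census genes` = vapply(reports, function(r)
      paste(r$census_genes, collapse = ", "), character(1)),
    Flags = vapply(reports, function(r) {
      f <- character(0)
      if (length(r$call$adjacent_to) > 0L)
        f <- c(f, sprintf("near %s", paste(r$call$adjacent_to, collapse = ",")))
      if (isTRUE(r$call$left_unbounded)) f <- c(f, "left unbounded")
      if (isTRUE(r$call$right_unbounded)) f <- c(f, "right unbounded")
      paste(f, collapse = "; ")
    }, character(1)),
    check.names = FALSE, stringsAsFactors = FALSE)
  widths <- vapply(names(rows), function(cn)
    max(nchar(c(cn, rows[[cn]]), type = "width")), integer(1))
  pad <- function(v, w) formatC(v, width = -w)
  header <- paste(mapply(pad, names(rows), widths), collapse = "  ")
  lines <- c(header, paste(rep("-", nchar(header, type = "width")), collapse = ""))
  for (i in seq_len(nrow(rows))) {
    lines <- c(lines, paste(mapply(function(cn, w) pad(rows[[cn]][i], w),
                                   names(rows), widths), collapse = "  "))
  }
  if (verbose) {
    statuses <- attr(reports, "statuses")
    lines <- c(lines, "")
    if (!is.null(statuses)) {
      assayed <- names(statuses)[statuses != "not_assayed"]
      lines <- c(lines, sprintf("Assayed genes (%d): %s", length(assayed),
                                paste(assayed, collapse = ", ")))
    }
    for (r in reports) {
      lines <- c(lines,
        sprintf("%s: all genes in inferred amplicon (%d): %s",
                r$call$id, length(r$extent_genes),
                paste(r$extent_genes, collapse = ", ")),
        sprintf("%s: boundary non-amplified genes: left=%s right=%s",
                r$call$id,
                if (is.null(r$call$left_boundary_gene)) "(chromosome end)"
                else r$call$left_boundary_gene,
                if (is.null(r$call$right_boundary_gene)) "(chromosome end)"
                else r$call$right_boundary_gene))
    }
  }
  lines
}

TSV_HEADER <- c("amplicon_id", "chrom", "reported_genes", "n_reported",
                "coamplified_count", "region_label", "core_genes",
                "boundary_genes_left", "boundary_genes_right",
                "left_boundary_gene", "right_boundary_gene",
                "census_genes", "adjacent_to")

render_tsv <- function(reports) {
  join <- function(v) paste(v, collapse = ",")
  rows <- vapply(reports, function(r) {
    cl <- r$call
    paste(c(cl$id, cl$chrom, join(cl$reported_genes),
            length(cl$reported_genes), r$coamplified_count, r$region_label,
            join(cl$core_genes), join(cl$boundary_genes_left),
            join(cl$boundary_genes_right),
            if (is.null(cl$left_boundary_gene)) "" else cl$left_boundary_gene,
            if (is.null(cl$right_boundary_gene)) "" else cl$right_boundary_gene,
            join(r$census_genes), join(cl$adjacent_to)),
          collapse = "\t")
  }, character(1))
  c(paste(TSV_HEADER, collapse = "\t"), rows)
}

report_to_list <- function(r, verbose = FALSE) {
  cl <- r$call
  out <- list(
    id = cl$id,
    chrom = cl$chrom,
    reported_genes = as.list(cl$reported_genes),
    core = list(rank_lo = cl$core_lo, rank_hi = cl$core_hi,
                start = r$core_start, end = r$core_end,
                genes = as.list(cl$core_genes)),
    boundary = list(
      left = list(
        boundary_gene = if (is.null(cl$left_boundary_gene)) NULL
                        else cl$left_boundary_gene,
        unbounded = cl$left_unbounded,
        genes = as.list(cl$boundary_genes_left)),
      right = list(
        boundary_gene = if (is.null(cl$right_boundary_gene)) NULL
                        else cl$right_boundary_gene,
        unbounded = cl$right_unbounded,
        genes = as.list(cl$boundary_genes_right))),
    region_label = r$region_label,
    extent = list(start = r$extent_start, end = r$extent_end),
    coamplified_count = r$coamplified_count,
    census_genes = as.list(r$census_genes),
    links = as.list(r$links),
    adjacent_to = as.list(cl$adjacent_to))
  if (verbose) out$extent_genes <- as.list(r$extent_genes)
  out
}

render_json <- function(reports, verbose = FALSE) {
  payload <- list(amplicons = lapply(reports, report_to_list, verbose = verbose))
  if (verbose) {
    statuses <- attr(reports, "statuses")
    if (!is.null(statuses)) {
      payload$assayed_genes <- as.list(names(statuses)[statuses != "not_assayed"])
    }
  }
  strsplit(as.character(jsonlite::toJSON(
    payload, auto_unbox = TRUE, null = "null", digits = NA, pretty = TRUE)),
    "\n", fixed = TRUE)[[1L]]
}

render_bed <- function(reports) {
  core_lines <- vapply(reports, function(r)
    sprintf("%s\t%d\t%d\t%s_core", r$chrom, r$core_start, r$core_end,
            r$call$id), character(1))
  side_lines <- character(0)
  for (r in reports) {
    cl <- r$call
    if (length(cl$boundary_genes_left) > 0L) {
      side_lines <- c(side_lines, sprintf("%s\t%d\t%d\t%s_left",
                                          r$chrom, r$extent_start,
                                          r$core_start, cl$id))
    }
    if (length(cl$boundary_genes_right) > 0L) {
      side_lines <- c(side_lines, sprintf("%s\t%d\t%d\t%s_right",
                                          r$chrom, r$core_end,
                                          r$extent_end, cl$id))
    }
  }
  c("track name=core_regions description=\"amplicon core spans\"",
    core_lines,
    "track name=possibly_amplified description=\"boundary extensions\"",
    side_lines)
}

#' Write a census set to a plain-text file
#' @param x a [census_set()].
#' @param path output path (one symbol per line, tab-separated tier if set).
#' @return `path`, invisibly.
#' @export
write_census <- function(x, path) {
  stopifnot(inherits(x, "census_set"))
  lines <- if (is.null(x$tier)) x$symbols else {
    ifelse(is.na(x$tier), x$symbols, paste(x$symbols, x$tier, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
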