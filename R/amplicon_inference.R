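# Core inference: consolidate reported amplified genes into contiguous
# amplicons and delimit the possibly-amplified boundary regions.
#
# The reasoning is entirely in rank space. A targeted panel observes only a
# sparse subset of genes, so the evidence for an amplicon is: which assayed
# genes were reported amplified, and which assayed genes were not. Genes
# between two reported amplified genes with no intervening assayed
# non-amplified gene are considered amplified (the core); genes between the
# core and the nearest assayed non-amplified gene on each side are possibly
# amplified (the boundary region), exclusive of that delimiting gene.

GENE_STATUSES <- c("reported_amplified", "assayed_not_amplified", "not_assayed")

#' Classify every gene in the genome for one (panel, query) pair
#'
#' Genes in the query are `reported_amplified`; genes assayed by the panel
#' but not in the query are `assayed_not_amplified`; everything else is
#' `not_assayed`. Query genes absent from the panel but present in the
#' genome are treated as both assayed and amplified (the report evidently
#' assayed them, or the list came from an unsupported assay) with a warning.
#' Panel symbols absent from the genome can neither bound nor join an
#' amplicon and are dropped with a warning stating the count.
#'
#' @param index a [genome_index()].
#' @param panel a [panel()] (or `NULL` for a query-only custom assay).
#' @param query an `amplified_query`, a raw comma-delimited string, or a
#'   character vector of symbols.
#' @param skip_unknown if `FALSE` (default), query symbols missing from the
#'   genome are an error listing the offenders; if `TRUE`, they are dropped
#'   with a warning.
#' @return named character vector over all genome symbols (index casing),
#'   values in `reported_amplified`, `assayed_not_amplified`, `not_assayed`.
#' @export
classify_genes <- function(index, panel, query, skip_unknown = FALSE) {
  stopifnot(inherits(index, "genome_index"))
  query <- as_amplified_query(query)
  res_q <- resolve_symbols(index, query$symbols)
  if (length(res_q$unknown) > 0L) {
    msg <- sprintf("query gene(s) not found in genome: %s",
                   paste(res_q$unknown, collapse = ", "))
    if (!skip_unknown) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  if (nrow(res_q$known) == 0L) {
    stop("no query gene could be resolved in the genome", call. = FALSE)
  }
  panel_syms <- if (is.null(panel)) character(0) else {
    stopifnot(inherits(panel, "panel"))
    panel$symbols
  }
  res_p <- resolve_symbols(index, panel_syms)
  if (length(res_p$unknown) > 0L) {
    warning(sprintf(
      "%d panel gene(s) absent from the genome were dropped: %s",
      length(res_p$unknown), paste(res_p$unknown, collapse = ", ")),
      call. = FALSE)
  }
  off_panel <- setdiff(toupper(res_q$known$symbol), toupper(res_p$known$symbol))
  if (length(off_panel) > 0L && length(panel_syms) > 0L) {
    warning(sprintf(
      "query gene(s) not on panel '%s' treated as assayed and amplified: %s",
      panel$name, paste(off_panel, collapse = ", ")), call. = FALSE)
  }
  statuses <- stats::setNames(rep("not_assayed", nrow(index$genes)),
                              index$genes$symbol)
  statuses[res_p$known$symbol] <- "assayed_not_amplified"
  statuses[res_q$known$symbol] <- "reported_amplified"
  statuses
}

# internal: data frame of genes + status, one chromosome, rank order
chrom_status_df <- function(index, statuses, chrom) {
  g <- index$genes[index$genes$chrom == chrom, , drop = FALSE]
  g <- g[order(g$rank), , drop = FALSE]
  g$status <- unname(statuses[g$symbol])
  g
}

new_amplicon_call <- function(chrom, reported_genes, core_lo, core_hi,
                              core_genes) {
  structure(list(
    id = NA_character_,
    chrom = chrom,
    reported_genes = reported_genes,
    core_lo = as.integer(core_lo),
    core_hi = as.integer(core_hi),
    core_genes = core_genes,
    left_boundary_gene = NULL,
    right_boundary_gene = NULL,
    boundary_genes_left = NULL,
    boundary_genes_right = NULL,
    left_unbounded = NA,
    right_unbounded = NA,
    adjacent_to = character(0)
  ), class = "amplicon_call")
}

#' @export
print.amplicon_call <- function(x, ...) {
  cat(sprintf("<amplicon_call %s> %s ranks %d..%d: %s\n",
              if (is.na(x$id)) "" else x$id, x$chrom, x$core_lo, x$core_hi,
              paste(x$reported_genes, collapse = ", ")))
  invisible(x)
}

#' Consolidate reported amplified genes into amplicons
#'
#' On each chromosome, reported amplified genes are scanned in rank order.
#' Two consecutive reported genes join the same amplicon if and only if no
#' assayed non-amplified gene lies strictly between them in rank: an assayed
#' gene that was not called amplified is positive evidence of a copy-number
#' break. Each amplicon's core span runs from its leftmost to its rightmost
#' reported gene, and every gene inside the span is considered amplified.
#'
#' @param index a [genome_index()].
#' @param statuses status map from [classify_genes()].
#' @return object of class `amplicon_calls`: list of `amplicon_call`s sorted
#'   by (chromosome natural order, core start rank), ids `amp1`, `amp2`, ...
#'   Boundary fields are unset; see [extend_boundaries()].
#' @export
build_amplicons <- function(index, statuses) {
  stopifnot(inherits(index, "genome_index"))
  chroms <- unique(index$genes$chrom)  # already in natural order
  calls <- list()
  for (chrom in chroms) {
    g <- chrom_status_df(index, statuses, chrom)
    rep_ranks <- g$rank[g$status == "reported_amplified"]
    if (length(rep_ranks) == 0L) next
    assayed_neg <- g$rank[g$status == "assayed_not_amplified"]
    # split reported ranks where an assayed non-amplified gene intervenes
    grp <- integer(length(rep_ranks))
    grp[1L] <- 1L
    if (length(rep_ranks) > 1L) {
      for (i in 2L:length(rep_ranks)) {
        separated <- any(assayed_neg > rep_ranks[i - 1L] &
                           assayed_neg < rep_ranks[i])
        grp[i] <- grp[i - 1L] + as.integer(separated)
      }
    }
    for (k in unique(grp)) {
      rr <- rep_ranks[grp == k]
      lo <- min(rr); hi <- max(rr)
      core <- genes_in_rank_span(index, chrom, lo, hi)
      rep_syms <- g$symbol[match(rr, g$rank)]
      calls[[length(calls) + 1L]] <-
        new_amplicon_call(chrom, rep_syms, lo, hi, core$symbol)
    }
  }
  # chroms iterated in natural order and groups in rank order, so calls are
  # already sorted by (chrom, core_lo)
  for (i in seq_along(calls)) calls[[i]]$id <- sprintf("amp%d", i)
  structure(calls, class = "amplicon_calls")
}

#' @export
print.amplicon_calls <- function(x, ...) {
  cat(sprintf("<amplicon_calls> %d amplicon(s)\n", length(x)))
  for (call in x) print(call)
  invisible(x)
}

#' Extend an amplicon to its possibly-amplified boundary regions
#'
#' The left (right) boundary gene is the nearest assayed non-amplified gene
#' below (above) the core span on the same chromosome. Genes strictly
#' between a boundary gene and the core — up to, but not including, the
#' boundary gene — are possibly amplified. When no assayed non-amplified
#' gene exists on a side, the possibly-amplified region runs to the
#' chromosome end and the side is marked unbounded.
#'
#' @param call an `amplicon_call` from [build_amplicons()].
#' @param index a [genome_index()].
#' @param statuses status map from [classify_genes()].
#' @return the completed `amplicon_call`.
#' @export
extend_boundaries <- function(call, index, statuses) {
  stopifnot(inherits(call, "amplicon_call"))
  g <- chrom_status_df(index, statuses, call$chrom)
  assayed_neg <- g$rank[g$status == "assayed_not_amplified"]
  n <- nrow(g)

  left_cand <- assayed_neg[assayed_neg < call$core_lo]
  if (length(left_cand) > 0L) {
    lb_rank <- max(left_cand)
    call$left_boundary_gene <- g$symbol[match(lb_rank, g$rank)]
    call$left_unbounded <- FALSE
    left_lo <- lb_rank + 1L
  } else {
    call$left_boundary_gene <- NULL
    call$left_unbounded <- TRUE
    left_lo <- 0L
  }
  call$boundary_genes_left <- if (left_lo <= call$core_lo - 1L) {
    genes_in_rank_span(index, call$chrom, left_lo, call$core_lo - 1L)$symbol
  } else character(0)

  right_cand <- assayed_neg[assayed_neg > call$core_hi]
  if (length(right_cand) > 0L) {
    rb_rank <- min(right_cand)
    call$right_boundary_gene <- g$symbol[match(rb_rank, g$rank)]
    call$right_unbounded <- FALSE
    right_hi <- rb_rank - 1L
  } else {
    call$right_boundary_gene <- NULL
    call$right_unbounded <- TRUE
    right_hi <- n - 1L
  }
  call$boundary_genes_right <- if (call$core_hi + 1L <= right_hi) {
    genes_in_rank_span(index, call$chrom, call$core_hi + 1L, right_hi)$symbol
  } else character(0)

  call
}

#' Flag closely co-located amplicons
#'
#' When two amplicons on one chromosome are separated by very few assayed
#' non-amplified genes, the separating gene may be erroneously uncalled and
#' a single regional amplification may span both. Such pairs are flagged
#' symmetrically so report readers can weigh that possibility.
#'
#' @param calls completed `amplicon_calls` (boundaries extended), sorted.
#' @param index a [genome_index()].
#' @param statuses status map from [classify_genes()].
#' @param max_gap flag a consecutive same-chromosome pair when the count of
#'   assayed non-amplified genes strictly between their core spans is at
#'   most this (default 1, the shared-boundary-gene situation). Must be
#'   >= 1: distinct amplicons always have at least one separator.
#' @return `amplicon_calls` with `adjacent_to` populated (ids, symmetric).
#' @export
flag_adjacent <- function(calls, index, statuses, max_gap = 1L) {
  stopifnot(inherits(calls, "amplicon_calls"))
  if (max_gap < 1L) {
    stop("max_gap must be >= 1 (separated amplicons always have >= 1 separating assayed gene)",
         call. = FALSE)
  }
  if (length(calls) < 2L) return(calls)
  for (i in seq_len(length(calls) - 1L)) {
    a <- calls[[i]]; b <- calls[[i + 1L]]
    if (a$chrom != b$chrom) next
    g <- chrom_status_df(index, statuses, a$chrom)
    n_sep <- sum(g$status == "assayed_not_amplified" &
                   g$rank > a$core_hi & g$rank < b$core_lo)
    if (n_sep <= max_gap) {
      calls[[i]]$adjacent_to <- union(calls[[i]]$adjacent_to, b$id)
      calls[[i + 1L]]$adjacent_to <- union(calls[[i + 1L]]$adjacent_to, a$id)
    }
  }
  calls
}

#' Run the full amplicon inference pipeline
#'
#' Composition of [classify_genes()], [build_amplicons()],
#' [extend_boundaries()] and [flag_adjacent()]. Deterministic: identical
#' inputs give identical calls.
#'
#' @inheritParams classify_genes
#' @inheritParams flag_adjacent
#' @return completed `amplicon_calls`; the status map is attached as
#'   attribute `"statuses"` for reporting.
#' @examples
#' fx <- figure1_fixture()
#' infer_amplicons(fx$index, fx$panel, fx$query)
#' @export
infer_amplicons <- function(index, panel, query, max_gap = 1L,
                            skip_unknown = FALSE) {
  statuses <- classify_genes(index, panel, query, skip_unknown = skip_unknown)
  calls <- build_amplicons(index, statuses)
  for (i in seq_along(calls)) {
    calls[[i]] <- extend_boundaries(calls[[i]], index, statuses)
  }
  calls <- flag_adjacent(calls, index, statuses, max_gap = max_gap)
  attr(calls, "statuses") <- statuses
  calls
}

# Full possibly-amplified extent of a call (boundary-left, core,
# boundary-right), as gene symbols in rank order.
call_extent_symbols <- function(call) {
  c(call$boundary_genes_left, call$core_genes, call$boundary_genes_right)
}
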