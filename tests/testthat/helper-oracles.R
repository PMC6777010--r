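# Brute-force oracles, kept independent of the implementation paths they
# check: pairwise O(n^2) reasoning and direct enumeration only.

# Status map built directly from a panel symbol set and a reported symbol
# set, bypassing classify_genes().
make_statuses <- function(index, panel_syms, reported_syms) {
  statuses <- stats::setNames(rep("not_assayed", nrow(index$genes)),
                              index$genes$symbol)
  statuses[panel_syms] <- "assayed_not_amplified"
  statuses[reported_syms] <- "reported_amplified"
  statuses
}

# O(n^2) amplicon oracle: two reported genes are connected iff no assayed
# non-amplified gene lies strictly between them in rank; amplicons are the
# connected components, found by breadth-first search over the pairwise
# connectivity matrix.
oracle_amplicons <- function(index, statuses) {
  out <- list()
  for (chrom in unique(index$genes$chrom)) {
    g <- index$genes[index$genes$chrom == chrom, , drop = FALSE]
    g <- g[order(g$rank), , drop = FALSE]
    st <- unname(statuses[g$symbol])
    rep_idx <- which(st == "reported_amplified")
    if (length(rep_idx) == 0L) next
    neg_ranks <- g$rank[st == "assayed_not_amplified"]
    m <- length(rep_idx)
    conn <- matrix(FALSE, m, m)
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        a <- g$rank[rep_idx[i]]; b <- g$rank[rep_idx[j]]
        lo <- min(a, b); hi <- max(a, b)
        conn[i, j] <- !any(neg_ranks > lo & neg_ranks < hi)
      }
    }
    seen <- rep(FALSE, m)
    for (s in seq_len(m)) {
      if (seen[s]) next
      comp <- s
      frontier <- s
      seen[s] <- TRUE
      while (length(frontier) > 0L) {
        nxt <- which(apply(conn[frontier, , drop = FALSE], 2, any) & !seen)
        seen[nxt] <- TRUE
        comp <- c(comp, nxt)
        frontier <- nxt
      }
      ranks <- g$rank[rep_idx[sort(comp)]]
      out[[length(out) + 1L]] <- list(
        chrom = chrom,
        reported = g$symbol[rep_idx[sort(comp)]],
        lo = min(ranks), hi = max(ranks))
    }
  }
  ord <- order(vapply(out, function(x) panelamp:::chrom_sort_key(x$chrom),
                      character(1)),
               vapply(out, function(x) x$lo, numeric(1)))
  out[ord]
}

# Direct enumeration of assayed non-amplified genes strictly between two
# core spans on one chromosome.
oracle_separators <- function(index, statuses, chrom, hi_left, lo_right) {
  g <- index$genes[index$genes$chrom == chrom, , drop = FALSE]
  st <- unname(statuses[g$symbol])
  sum(st == "assayed_not_amplified" & g$rank > hi_left & g$rank < lo_right)
}

# Extent of a call as a rank set on its chromosome.
call_extent_ranks <- function(call, index) {
  ext <- c(call$boundary_genes_left, call$core_genes, call$boundary_genes_right)
  sort(index$genes$rank[match(ext, index$genes$symbol)])
}

# Random instance generator for property tests: toy genome plus directly
# constructed panel/reported sets (no reliance on simulate_profile).
random_instance <- function(seed, max_genes = 200L) {
  set.seed(seed)
  n <- sample(20:max_genes, 1L)
  n_chrom <- sample(1:3, 1L)
  genome <- make_toy_genome(n, n_chrom, seed = seed + 7L)
  syms <- genome$genes$symbol
  panel_syms <- sample(syms, max(2L, round(0.3 * n)))
  reported_syms <- sample(panel_syms, sample(1:min(8L, length(panel_syms)), 1L))
  panel_syms <- setdiff(panel_syms, reported_syms)
  list(genome = genome,
       statuses = make_statuses(genome, panel_syms, reported_syms),
       panel_syms = panel_syms, reported_syms = reported_syms)
}

# Extent symbols of a completed call (test-side copy of the accessor).
call_extent_symbols_test <- function(call) {
  c(call$boundary_genes_left, call$core_genes, call$boundary_genes_right)
}

# Bijection precondition: every true amplicon contains >= 1 assayed gene and
# every gap between same-chromosome truths contains >= 1 assayed gene.
truth_condition_holds <- function(truth) {
  g <- truth$genome$genes
  assayed <- g$symbol %in% truth$panel$symbols
  tr <- truth$true_amplicons
  for (i in seq_len(nrow(tr))) {
    inside <- g$chrom == tr$chrom[i] & g$rank >= tr$lo[i] & g$rank <= tr$hi[i]
    if (!any(assayed & inside)) return(FALSE)
  }
  for (chrom in unique(tr$chrom)) {
    same <- tr[tr$chrom == chrom, , drop = FALSE]
    same <- same[order(same$lo), , drop = FALSE]
    if (nrow(same) < 2L) next
    for (i in seq_len(nrow(same) - 1L)) {
      gap <- g$chrom == chrom & g$rank > same$hi[i] & g$rank < same$lo[i + 1L]
      if (!any(assayed & gap)) return(FALSE)
    }
  }
  TRUE
}

# build + extend without flagging, for monotonicity checks.
infer_and_extend <- function(genome, statuses) {
  calls <- build_amplicons(genome, statuses)
  structure(lapply(calls, extend_boundaries, index = genome,
                   statuses = statuses), class = "amplicon_calls")
}
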