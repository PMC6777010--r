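fx <- figure1_fixture()

test_that("gene classification partitions the genome", {
  st <- classify_genes(fx$index, fx$panel, fx$query)
  expect_setequal(names(st), fx$index$genes$symbol)
  expect_equal(sort(names(st)[st == "reported_amplified"]),
               sort(c("g8", "g13", "g20")))
  expect_equal(sort(names(st)[st == "assayed_not_amplified"]),
               sort(c("g4", "g27")))
  expect_equal(sum(st == "not_assayed"), 25L)
})

test_that("query genes off the panel are treated as assayed and amplified", {
  # gene in genome only: warned about, but reported amplified
  expect_warning(
    st <- classify_genes(fx$index, fx$panel, "g10"),
    "not on panel")
  expect_equal(unname(st[["g10"]]), "reported_amplified")

  # no panel at all (pure custom list): no warning, query is the assay
  st <- classify_genes(fx$index, NULL, "g10")
  expect_equal(unname(st[["g10"]]), "reported_amplified")
  expect_equal(sum(st == "assayed_not_amplified"), 0L)
})

test_that("query equal to the whole panel leaves no non-amplified gene", {
  st <- classify_genes(fx$index, fx$panel, paste(fx$panel$symbols, collapse = ","))
  expect_equal(sum(st == "assayed_not_amplified"), 0L)
  expect_equal(sum(st == "reported_amplified"), 5L)
})

test_that("unknown query genes error by default and warn with skip_unknown", {
  expect_error(classify_genes(fx$index, fx$panel, "g8,NOTAGENE"), "NOTAGENE")
  expect_warning(
    st <- classify_genes(fx$index, fx$panel, "g8,NOTAGENE", skip_unknown = TRUE),
    "NOTAGENE")
  expect_equal(unname(st[["g8"]]), "reported_amplified")
})

test_that("panel genes missing from the genome are dropped with a warning", {
  p <- panel(c("g4", "g8", "g27", "GHOST1"), name = "leaky")
  expect_warning(st <- classify_genes(fx$index, p, "g8"), "GHOST1")
  expect_equal(sum(st == "assayed_not_amplified"), 2L)
})

test_that("the schematic scenario consolidates to a single amplicon", {
  st <- classify_genes(fx$index, fx$panel, fx$query)
  calls <- build_amplicons(fx$index, st)
  expect_length(calls, 1L)
  expect_equal(calls[[1]]$reported_genes, c("g8", "g13", "g20"))
  expect_equal(calls[[1]]$core_genes, paste0("g", 8:20))

  done <- extend_boundaries(calls[[1]], fx$index, st)
  expect_equal(done$left_boundary_gene, "g4")
  expect_equal(done$right_boundary_gene, "g27")
  expect_equal(done$boundary_genes_left, paste0("g", 5:7))
  expect_equal(done$boundary_genes_right, paste0("g", 21:26))
  expect_false(done$left_unbounded)
  expect_false(done$right_unbounded)
})

test_that("reported genes on different chromosomes never merge", {
  genome <- genome_index(c("a1", "a2", "b1", "b2"),
                         c("chr1", "chr1", "chr2", "chr2"),
                         c(0L, 100L, 0L, 100L), c(50L, 150L, 50L, 150L))
  st <- make_statuses(genome, character(0), c("a2", "b1"))
  calls <- build_amplicons(genome, st)
  expect_length(calls, 2L)
  expect_equal(vapply(calls, function(x) x$chrom, ""), c("chr1", "chr2"))
})

test_that("chromosome ends leave a side unbounded with the extent to the end", {
  # amplified gene first on its chromosome, no assayed gene to its left
  genome <- figure1_fixture()$index
  st <- make_statuses(genome, "g27", "g1")
  calls <- build_amplicons(genome, st)
  done <- extend_boundaries(calls[[1]], genome, st)
  expect_null(done$left_boundary_gene)
  expect_true(done$left_unbounded)
  expect_equal(done$boundary_genes_left, character(0))
  expect_equal(done$boundary_genes_right, paste0("g", 2:26))

  # boundary gene immediately adjacent to the core: empty boundary set
  st2 <- make_statuses(genome, c("g7", "g21"), c("g8", "g20"))
  calls2 <- build_amplicons(genome, st2)
  done2 <- extend_boundaries(calls2[[1]], genome, st2)
  expect_equal(done2$left_boundary_gene, "g7")
  expect_equal(done2$boundary_genes_left, character(0))
  expect_equal(done2$boundary_genes_right, character(0))
})

test_that("amplicon consolidation matches the O(n^2) oracle on random instances", {
  for (seed in 1:40) {
    inst <- random_instance(seed, max_genes = 150L)
    calls <- build_amplicons(inst$genome, inst$statuses)
    oracle <- oracle_amplicons(inst$genome, inst$statuses)
    expect_equal(length(calls), length(oracle), info = paste("seed", seed))
    for (k in seq_along(calls)) {
      expect_equal(calls[[k]]$chrom, oracle[[k]]$chrom)
      expect_equal(calls[[k]]$reported_genes, oracle[[k]]$reported)
      expect_equal(calls[[k]]$core_lo, oracle[[k]]$lo)
      expect_equal(calls[[k]]$core_hi, oracle[[k]]$hi)
    }
  }
})

test_that("every reported gene lands in exactly one call and cores are separated", {
  for (seed in 41:60) {
    inst <- random_instance(seed, max_genes = 150L)
    calls <- build_amplicons(inst$genome, inst$statuses)
    seen <- unlist(lapply(calls, function(x) x$reported_genes))
    expect_setequal(seen, inst$reported_syms)
    expect_equal(anyDuplicated(seen), 0L)
    # same-chromosome cores disjoint with >= 1 separating assayed gene
    for (chrom in unique(vapply(calls, function(x) x$chrom, ""))) {
      cc <- Filter(function(x) x$chrom == chrom, calls)
      if (length(cc) < 2L) next
      for (i in seq_len(length(cc) - 1L)) {
        expect_true(cc[[i]]$core_hi < cc[[i + 1L]]$core_lo)
        expect_gte(oracle_separators(inst$genome, inst$statuses, chrom,
                                     cc[[i]]$core_hi, cc[[i + 1L]]$core_lo), 1L)
      }
    }
  }
})

test_that("adjacency flags match direct separator enumeration", {
  # shared-boundary-gene situation: exactly one separator -> mutual flag
  genome <- figure1_fixture()$index
  st <- make_statuses(genome, c("g5", "g15", "g25"), c("g10", "g20"))
  calls <- build_amplicons(genome, st)
  calls <- structure(lapply(calls, extend_boundaries, index = genome,
                            statuses = st), class = "amplicon_calls")
  flagged <- flag_adjacent(calls, genome, st, max_gap = 1L)
  expect_equal(flagged[[1]]$adjacent_to, "amp2")
  expect_equal(flagged[[2]]$adjacent_to, "amp1")

  # different chromosomes: never flagged
  genome2 <- genome_index(c("a1", "a2", "b1", "b2"),
                          c("chr1", "chr1", "chr2", "chr2"),
                          c(0L, 100L, 0L, 100L), c(50L, 150L, 50L, 150L))
  st2 <- make_statuses(genome2, character(0), c("a1", "b1"))
  calls2 <- build_amplicons(genome2, st2)
  calls2 <- structure(lapply(calls2, extend_boundaries, index = genome2,
                             statuses = st2), class = "amplicon_calls")
  flagged2 <- flag_adjacent(calls2, genome2, st2, max_gap = 5L)
  expect_length(flagged2[[1]]$adjacent_to, 0L)
  expect_length(flagged2[[2]]$adjacent_to, 0L)

  expect_error(flag_adjacent(calls, genome, st, max_gap = 0L), "max_gap")

  # random instances, several thresholds
  for (seed in 61:80) {
    inst <- random_instance(seed, max_genes = 150L)
    calls <- build_amplicons(inst$genome, inst$statuses)
    calls <- structure(lapply(calls, extend_boundaries, index = inst$genome,
                              statuses = inst$statuses),
                       class = "amplicon_calls")
    for (gap in c(1L, 2L, 3L)) {
      flagged <- flag_adjacent(calls, inst$genome, inst$statuses, max_gap = gap)
      for (i in seq_along(flagged)) {
        for (j in seq_along(flagged)) {
          if (j != i + 1L) next
          a <- flagged[[i]]; b <- flagged[[j]]
          if (a$chrom != b$chrom) next
          n_sep <- oracle_separators(inst$genome, inst$statuses, a$chrom,
                                     a$core_hi, b$core_lo)
          expect_equal(b$id %in% a$adjacent_to, n_sep <= gap)
          expect_equal(a$id %in% b$adjacent_to, n_sep <= gap)
        }
      }
    }
  }
})

test_that("inference is sound and complete when assayed genes cover truths and gaps", {
  n_checked <- 0L
  for (seed in 1:40) {
    genome <- make_toy_genome(300, 2, seed = seed)
    truth <- simulate_profile(genome, panel_density = 0.4, n_amplicons = 3,
                              seed = seed + 1000L)
    if (!truth_condition_holds(truth)) next
    n_checked <- n_checked + 1L
    calls <- infer_amplicons(genome, truth$panel, truth$reported)
    expect_equal(length(calls), nrow(truth$true_amplicons))
    g <- genome$genes
    for (call in calls) {
      ranks <- g$rank[match(call$core_genes, g$symbol)]
      tr <- truth$true_amplicons[truth$true_amplicons$chrom == call$chrom &
                                   truth$true_amplicons$lo <= min(ranks) &
                                   truth$true_amplicons$hi >= max(ranks), ]
      expect_equal(nrow(tr), 1L)  # cores nest inside their truth
    }
    # every truly amplified gene is recovered in core or boundary
    ext <- unlist(lapply(calls, call_extent_symbols_test))
    for (i in seq_len(nrow(truth$true_amplicons))) {
      tr <- truth$true_amplicons[i, ]
      truly <- g$symbol[g$chrom == tr$chrom & g$rank >= tr$lo & g$rank <= tr$hi]
      expect_true(all(truly %in% ext))
    }
  }
  expect_gte(n_checked, 10L)
})

test_that("adding an assayed non-amplified gene never widens any extent", {
  for (seed in 81:100) {
    inst <- random_instance(seed, max_genes = 120L)
    genome <- inst$genome
    calls_before <- infer_and_extend(genome, inst$statuses)
    candidates <- names(inst$statuses)[inst$statuses == "not_assayed"]
    if (length(candidates) == 0L) next
    set.seed(seed)
    added <- sample(candidates, 1L)
    st2 <- inst$statuses
    st2[added] <- "assayed_not_amplified"
    calls_after <- infer_and_extend(genome, st2)
    for (cl in calls_after) {
      ranks_new <- call_extent_ranks(cl, genome)
      covering <- Filter(function(old)
        old$chrom == cl$chrom &&
          all(ranks_new %in% call_extent_ranks(old, genome)), calls_before)
      expect_gte(length(covering), 1L)
    }
  }
})

test_that("the full pipeline is deterministic and composes the stages", {
  calls <- infer_amplicons(fx$index, fx$panel, fx$query)
  expect_length(calls, 1L)
  expect_equal(calls[[1]]$core_genes, paste0("g", 8:20))
  expect_equal(calls[[1]]$left_boundary_gene, "g4")
  expect_equal(calls[[1]]$right_boundary_gene, "g27")
  expect_length(calls[[1]]$adjacent_to, 0L)
  expect_identical(calls, infer_amplicons(fx$index, fx$panel, fx$query))
  expect_error(infer_amplicons(fx$index, fx$panel, ""), "no gene names")
})
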