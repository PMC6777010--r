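# Synthetic genomes, panels, census sets and ground-truth amplification
# profiles. Everything here is deterministic for a fixed seed and
# serializable through the same file dialects the loaders read, so
# integration tests can exercise the real I/O path without downloads.

# Run expr with a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' The 30-gene schematic fixture
#'
#' A model chromosomal region with 30 numbered genes `g1..g30` on chromosome
#' `chrT` (gene `gK` spans `[K*1000, K*1000 + 500)`). Five genes are assayed
#' by the toy panel (`g4`, `g8`, `g13`, `g20`, `g27`); three of them are
#' reported amplified (`g8`, `g13`, `g20`). Seven genes are cancer-relevant:
#' the five assayed genes plus two unassayed census genes (`g10`, `g23`)
#' placed inside the inferred extent — the schematic does not pin down which
#' unassayed genes are cancer-relevant, so the fixture places them where the
#' annotation step has something to find.
#'
#' The expected inference result: one amplicon with core `g8..g20`
#' (everything between reported amplified genes is considered amplified),
#' left/right boundary genes `g4`/`g27` (nearest assayed non-amplified), and
#' possibly-amplified genes `g5..g7` and `g21..g26` (up to, but not
#' including, the boundary genes).
#'
#' @return list with `index` ([genome_index()]), `panel` ([panel()]),
#'   `census` ([census_set()]), `query` (`amplified_query`), and `expected`
#'   (list describing the expected single amplicon).
#' @export
figure1_fixture <- function() {
  k <- 1:30
  index <- genome_index(symbol = paste0("g", k),
                        chrom = rep("chrT", 30L),
                        start = k * 1000L,
                        end = k * 1000L + 500L)
  pnl <- panel(paste0("g", c(4L, 8L, 13L, 20L, 27L)), name = "toy5")
  census <- census_set(paste0("g", c(4L, 8L, 10L, 13L, 20L, 23L, 27L)))
  query <- parse_amplified_list("g8,g13,g20")
  expected <- list(
    chrom = "chrT",
    reported_genes = c("g8", "g13", "g20"),
    core_genes = paste0("g", 8:20),
    left_boundary_gene = "g4",
    right_boundary_gene = "g27",
    boundary_genes_left = paste0("g", 5:7),
    boundary_genes_right = paste0("g", 21:26))
  list(index = index, panel = pnl, census = census, query = query,
       expected = expected)
}

#' Packaged synthetic clinical fixture
#'
#' Loads the synthetic hg38-like mini genome, panel and census shipped under
#' `inst/extdata/`. These files are a hand-built synthetic stand-in for real
#' annotation data: 69 real gene symbols on chromosomes 1, 4, 5, 7, 11, 12
#' and 15, in their true relative order with approximate coordinates and
#' cytobands, plus a 29-gene panel modeled on a vendor assay and a 36-gene
#' census subset. They are sized so that the worked clinical queries in the
#' package documentation consolidate into realistic amplicons.
#'
#' @return list with `index`, `panel`, `census`.
#' @export
synthetic_clinical_fixture <- function() {
  ext <- function(f) system.file("extdata", f, package = "panelamp")
  index <- load_gene_coordinates(ext("genome_synthetic_hg38_mini.tsv"),
                                 dialect = "tsv5")
  pnl <- load_panel("synthetic_foundation_mini")
  census <- load_census(ext("census_synthetic_cosmic_mini.txt"))
  list(index = index, panel = pnl, census = census)
}

#' Generate a toy genome
#'
#' Genes `g1..g<n_genes>` are distributed round-robin over `n_chroms`
#' chromosomes (`chr1..chr<n_chroms>`) with random non-overlapping
#' intervals. Reproducible: identical seeds give identical indices.
#'
#' @param n_genes total gene count (`>= n_chroms`).
#' @param n_chroms chromosome count (`>= 1`).
#' @param seed integer RNG seed.
#' @return a [genome_index()].
#' @export
make_toy_genome <- function(n_genes, n_chroms, seed) {
  if (n_chroms < 1L || n_genes < n_chroms) {
    stop("need n_genes >= n_chroms >= 1", call. = FALSE)
  }
  with_local_seed(seed, {
    chrom_of <- paste0("chr", ((seq_len(n_genes) - 1L) %% n_chroms) + 1L)
    start <- integer(n_genes)
    end <- integer(n_genes)
    for (ch in unique(chrom_of)) {
      idx <- which(chrom_of == ch)
      gaps <- sample(100:2000, length(idx), replace = TRUE)
      widths <- sample(100:900, length(idx), replace = TRUE)
      s <- cumsum(gaps + c(0L, widths[-length(widths)]))
      start[idx] <- s
      end[idx] <- s + widths
    }
    genome_index(paste0("g", seq_len(n_genes)), chrom_of, start, end)
  })
}

#' Simulate a ground-truth amplification profile
#'
#' Samples a panel at the given density (uniformly without replacement over
#' all genes), places `n_amplicons` disjoint true amplicons (rank intervals
#' separated by at least one gene) uniformly over the genome, and derives
#' the reported query: exactly the assayed genes whose rank lies in a true
#' amplicon. A gene is truly amplified iff its rank lies in a true amplicon,
#' matching the inference engine's rank-space convention.
#'
#' @param genome a [genome_index()].
#' @param panel_density fraction of genes assayed, in (0, 1].
#' @param n_amplicons number of true amplicons (`>= 0`).
#' @param seed integer RNG seed.
#' @param max_len maximum amplicon length in genes (default: a quarter of
#'   the largest chromosome).
#' @return object of class `truth_profile`: list with `genome`, `panel`,
#'   `true_amplicons` (data frame `chrom`, `lo`, `hi` in ranks), `reported`
#'   (character vector, the implied query), plus the generation parameters.
#' @export
simulate_profile <- function(genome, panel_density, n_amplicons, seed,
                             max_len = NULL) {
  stopifnot(inherits(genome, "genome_index"))
  if (!(panel_density > 0 && panel_density <= 1)) {
    stop("panel_density must be in (0, 1]", call. = FALSE)
  }
  if (n_amplicons < 0L) stop("n_amplicons must be >= 0", call. = FALSE)
  g <- genome$genes
  chrom_sizes <- table(g$chrom)
  if (is.null(max_len)) max_len <- max(1L, floor(max(chrom_sizes) / 4))
  with_local_seed(seed, {
    n <- nrow(g)
    n_panel <- max(1L, ceiling(panel_density * n))
    panel_syms <- sort(sample(g$symbol, n_panel))
    truths <- data.frame(chrom = character(0), lo = integer(0), hi = integer(0))
    attempts <- 0L
    while (nrow(truths) < n_amplicons) {
      attempts <- attempts + 1L
      if (attempts > 5000L) {
        stop(sprintf("could not place %d disjoint amplicons on this genome",
                     n_amplicons), call. = FALSE)
      }
      ch <- sample(names(chrom_sizes), 1L,
                   prob = as.numeric(chrom_sizes) / sum(chrom_sizes))
      nc <- as.integer(chrom_sizes[[ch]])
      len <- sample(seq_len(min(max_len, nc)), 1L)
      lo <- sample(0:(nc - len), 1L)
      hi <- lo + len - 1L
      same <- truths[truths$chrom == ch, , drop = FALSE]
      # require >= 1 gene of separation so truths are distinct amplicons
      if (nrow(same) == 0L ||
          all(hi < same$lo - 1L | lo > same$hi + 1L)) {
        truths <- rbind(truths,
                        data.frame(chrom = ch, lo = lo, hi = hi))
      }
    }
    truths <- truths[order(chrom_sort_key(truths$chrom), truths$lo), ,
                     drop = FALSE]
    rownames(truths) <- NULL
    amplified <- rep(FALSE, n)
    for (i in seq_len(nrow(truths))) {
      amplified <- amplified | (g$chrom == truths$chrom[i] &
                                  g$rank >= truths$lo[i] &
                                  g$rank <= truths$hi[i])
    }
    assayed <- g$symbol %in% panel_syms
    reported <- g$symbol[amplified & assayed]
    structure(list(genome = genome,
                   panel = panel(panel_syms, name = sprintf(
                     "simulated_density_%g", panel_density)),
                   true_amplicons = truths,
                   reported = reported,
                   panel_density = panel_density,
                   n_amplicons = as.integer(n_amplicons),
                   seed = as.integer(seed)),
              class = "truth_profile")
  })
}

#' @export
print.truth_profile <- function(x, ...) {
  cat(sprintf("<truth_profile> %d true amplicon(s), panel density %g, %d reported gene(s)\n",
              nrow(x$true_amplicons), x$panel_density, length(x$reported)))
  invisible(x)
}

#' Boundary recovery error of inferred calls against the truth
#'
#' For every inferred amplicon, the overshoot per side is how many genes the
#' possibly-amplified extent extends beyond the true amplicon, in rank
#' units. When every true amplicon contains at least one assayed gene and
#' every gap between true amplicons contains at least one assayed gene,
#' calls and truths are in bijection and overshoot is non-negative (the
#' extent always covers the truth on each side). A call whose reported genes
#' do not fall inside exactly one true amplicon signals an inference bug and
#' raises an error.
#'
#' @param truth a `truth_profile` from [simulate_profile()].
#' @param calls `amplicon_calls` inferred from the truth's implied query.
#' @return object of class `boundary_error_summary`: list with
#'   `per_amplicon` (data frame: chrom, truth ranks, call id, per-side
#'   overshoot), `mean_overshoot`, `max_overshoot` (per-side values pooled)
#'   and `n_matched`. Empty call sets give an empty summary.
#' @export
boundary_error <- function(truth, calls) {
  stopifnot(inherits(truth, "truth_profile"))
  g <- truth$genome$genes
  per <- data.frame(chrom = character(0), truth_lo = integer(0),
                    truth_hi = integer(0), call_id = character(0),
                    overshoot_left = integer(0), overshoot_right = integer(0),
                    stringsAsFactors = FALSE)
  for (call in calls) {
    rep_ranks <- g$rank[match(call$reported_genes, g$symbol)]
    t_idx <- which(truth$true_amplicons$chrom == call$chrom &
                     truth$true_amplicons$lo <= min(rep_ranks) &
                     truth$true_amplicons$hi >= max(rep_ranks))
    if (length(t_idx) != 1L) {
      stop(sprintf(
        "call %s does not match exactly one true amplicon (matched %d)",
        call$id, length(t_idx)), call. = FALSE)
    }
    extent <- call_extent_symbols(call)
    ext_ranks <- g$rank[match(extent, g$symbol)]
    tr <- truth$true_amplicons[t_idx, ]
    per <- rbind(per, data.frame(
      chrom = call$chrom, truth_lo = tr$lo, truth_hi = tr$hi,
      call_id = call$id,
      overshoot_left = tr$lo - min(ext_ranks),
      overshoot_right = max(ext_ranks) - tr$hi,
      stringsAsFactors = FALSE))
  }
  overs <- c(per$overshoot_left, per$overshoot_right)
  structure(list(per_amplicon = per,
                 mean_overshoot = if (length(overs)) mean(overs) else NA_real_,
                 max_overshoot = if (length(overs)) max(overs) else NA_integer_,
                 n_matched = nrow(per)),
            class = "boundary_error_summary")
}

#' @export
print.boundary_error_summary <- function(x, ...) {
  if (x$n_matched == 0L) {
    cat("<boundary_error_summary> empty (no matched amplicons)\n")
  } else {
    cat(sprintf("<boundary_error_summary> %d amplicon(s): mean overshoot %.2f genes/side, max %d\n",
                x$n_matched, x$mean_overshoot, x$max_overshoot))
  }
  invisible(x)
}

#' Run one simulation end to end
#'
#' Generates a toy genome and a truth profile, runs inference on the implied
#' query, and measures boundary recovery. Deterministic per seed.
#'
#' @param n_genes,n_chroms toy genome size (see [make_toy_genome()]).
#' @param density panel density in (0, 1].
#' @param n_amplicons number of true amplicons.
#' @param seed integer RNG seed (genome uses `seed`, profile `seed + 1`,
#'   both derived deterministically).
#' @param max_gap adjacency flag threshold, see [flag_adjacent()].
#' @return list with `truth`, `calls`, `summary` (a
#'   [boundary_error()] result, or an empty one when nothing was reported).
#' @export
run_simulation <- function(n_genes, n_chroms, density, n_amplicons, seed,
                           max_gap = 1L) {
  genome <- make_toy_genome(n_genes, n_chroms, seed)
  truth <- simulate_profile(genome, density, n_amplicons, seed + 1L)
  if (length(truth$reported) == 0L) {
    calls <- structure(list(), class = "amplicon_calls")
  } else {
    calls <- infer_amplicons(genome, truth$panel, truth$reported,
                             max_gap = max_gap)
  }
  list(truth = truth, calls = calls, summary = boundary_error(truth, calls),
       seed = as.integer(seed))
}

#' Boundary resolution as a function of panel density
#'
#' Quantifies how a denser panel tightens inferred amplicon boundaries: for
#' each density, toy genomes with one true amplicon are simulated over a
#' range of seeds, inference is run on the implied query, and per-side
#' boundary overshoot is averaged over all runs that produced a call (a
#' sparse panel may miss the amplicon entirely; those runs contribute no
#' overshoot measurement and are counted separately).
#'
#' @param densities panel densities to sweep, each in (0, 1].
#' @param n_seeds number of simulation replicates per density.
#' @param n_genes,n_chroms toy genome size.
#' @param n_amplicons true amplicons per genome (default 1 so that call and
#'   truth match one-to-one whenever the amplicon is detected at all).
#' @param base_seed first seed; replicate k uses `base_seed + k`. The same
#'   seeds (hence the same genomes and truths) are reused across densities,
#'   pairing the comparison.
#' @return data frame with columns `density`, `mean_overshoot` (genes per
#'   side), `max_overshoot`, `n_detected`, `n_runs`.
#' @export
resolution_experiment <- function(densities = c(0.1, 0.2, 0.5, 1.0),
                                  n_seeds = 100L, n_genes = 500L,
                                  n_chroms = 1L, n_amplicons = 1L,
                                  base_seed = 20260101L) {
  out <- lapply(densities, function(d) {
    overs <- numeric(0)
    n_detected <- 0L
    for (k in seq_len(n_seeds)) {
      sim <- run_simulation(n_genes, n_chroms, d, n_amplicons,
                            seed = base_seed + k)
      if (sim$summary$n_matched > 0L) {
        n_detected <- n_detected + 1L
        overs <- c(overs, sim$summary$per_amplicon$overshoot_left,
                   sim$summary$per_amplicon$overshoot_right)
      }
    }
    data.frame(density = d,
               mean_overshoot = if (length(overs)) mean(overs) else NA_real_,
               max_overshoot = if (length(overs)) max(overs) else NA_integer_,
               n_detected = n_detected,
               n_runs = n_seeds)
  })
  do.call(rbind, out)
}
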