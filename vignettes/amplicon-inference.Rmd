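---
title: "Inferring amplicons from gene-level amplification calls: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring amplicons from gene-level amplification calls: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelamp)
```

## The inference model

A targeted tumor sequencing panel observes a sparse, fixed subset of genes.
When its report lists some of those genes as amplified, the underlying
biology is usually a small number of contiguous amplicons, each covering
many genes the panel never measured. `panelamp` reconstructs the most
parsimonious contiguous-amplicon explanation of the report from three kinds
of evidence:

* a gene reported amplified is amplified;
* an assayed gene *not* reported amplified is not amplified — positive
  evidence of a copy-number break;
* an unassayed gene carries no evidence either way.

All reasoning happens in **rank space**. Genes on a chromosome are sorted by
`(start, end, symbol)` and numbered `0..n-1`; "between" and "nearest" are
defined over these ranks, never over base pairs. Sorting ties are broken by
end coordinate and then symbol, so nested and overlapping genes get a
deterministic, if arbitrary, order — which is exactly what a gene-order
model needs, since interval geometry carries no extra information for a
binary amplified/not-amplified signal.

The pipeline has four stages, each exported separately and composed by
`infer_amplicons()`:

1. `classify_genes()` assigns every gene one of three statuses:
   `reported_amplified`, `assayed_not_amplified`, `not_assayed`. The three
   statuses partition the genome.
2. `build_amplicons()` consolidates: two consecutive reported genes (in rank
   order) belong to the same amplicon **iff** no assayed non-amplified gene
   lies strictly between them. The **core** spans the outermost reported
   genes of each group; every gene inside the core is considered amplified.
   This merge rule is the contrapositive of the break-evidence assumption:
   with no observed break between two amplified genes, one amplicon is the
   parsimonious call.
3. `extend_boundaries()` finds, on each side of a core, the nearest assayed
   non-amplified gene (the *boundary gene*). Genes strictly between the core
   and the boundary gene — up to, but not including, it — are **possibly
   amplified**. The amplicon's full *extent* is boundary + core + boundary.
4. `flag_adjacent()` marks same-chromosome amplicon pairs whose cores are
   separated by at most `max_gap` assayed non-amplified genes. A single
   separating gene may simply be a missed call, so closely co-located
   amplicons deserve the reader's suspicion that one regional amplification
   spans both. Flags are symmetric.

```{r fig1}
fx <- figure1_fixture()   # 30 genes, 5 assayed, 3 reported amplified
calls <- infer_amplicons(fx$index, fx$panel, fx$query)
calls[[1]]$core_genes
calls[[1]]$left_boundary_gene; calls[[1]]$right_boundary_gene
```

## Parameters that matter

* `max_gap` (genes; default **1**). Flagging threshold for closely
  co-located amplicons. The default captures the shared-boundary-gene
  situation — two cores delimited by one and the same assayed gene — which
  is the canonical missed-call suspect. Values below 1 are rejected:
  distinct amplicons always have at least one separator, so `max_gap = 0`
  would contradict the merge rule. Larger values trade specificity for
  sensitivity to regional amplification.
* `skip_unknown` (default **FALSE**). Query symbols missing from the genome
  index are an error by default, because a typo silently dropped changes the
  inference. The escape hatch demotes the error to a warning for reports
  containing retired symbols.
* `link_template`. URL template for per-gene external links; purely string
  construction, nothing is fetched.
* Coordinate dialects: `tsv4`/`tsv5` are read as 1-based inclusive and
  converted on load; `bed4` is 0-based half-open. Internally everything is
  0-based half-open, one convention, so off-by-one drift cannot accumulate.

## Degenerate inputs and tie-breaks

* **Chromosome ends.** With no assayed non-amplified gene beyond a core, the
  possibly-amplified region runs to the last gene on the chromosome and the
  side is marked *unbounded* in the report — the data give no evidence to
  stop earlier.
* **Boundary adjacent to core.** If the boundary gene's rank differs from
  the core edge by 1, the possibly-amplified set on that side is empty (the
  interval is exclusive on both ends).
* **No panel.** A query without a panel (a pasted custom list) treats the
  query itself as the assay: every query gene is assayed and amplified, and
  no gene in the genome is an assayed non-amplified separator. Query genes
  in the genome but off the declared panel are accepted as assayed and
  amplified, with a warning — they were evidently measured.
* **Panel genes absent from the genome** can neither bound nor join an
  amplicon; they are dropped with a warning stating the count.
* **Multi-interval symbols.** A coordinate source listing two intervals for
  one symbol is rejected outright rather than collapsed; choosing a
  transcript union is a data-preparation decision the loader refuses to make
  silently.
* **Case.** Symbol matching is case-insensitive (clinical reports vary, e.g.
  `C15ORF65` vs `C15orf65`); output always uses the coordinate file's casing.
* **Centromeres.** No centromere awareness: an extent may span one (a
  single-gene core near 1q21 can legitimately report an extent from 1p12 to
  1q23.1). Extent size is surfaced in every report so readers can judge
  implausibly wide regions; no distance cap is imposed, because the evidence
  model has none to offer.

## What the reports compute

The *co-amplified count* is `|core ∪ boundary| − |reported genes|`. Core and
boundary are deliberately pooled: the report's purpose is to enumerate
everything that may ride along with the reported genes, and splitting
"likely" from "possibly" co-amplified would suggest a confidence
quantification the binary input cannot support. Census membership and
region labels are evaluated over the same pooled extent, which is why a
single-gene core can carry a multi-band region label. Reported genes that
are census members are listed in the census column alongside the unassayed
ones.

## The synthetic layer: what it emulates, what it does not

`figure1_fixture()` is an exact, deterministic 30-gene scenario whose
expected call is known by construction; it anchors the unit tests and the
acceptance script. The schematic leaves open which unassayed genes are
cancer-relevant, so the fixture designates the five panel genes as census
members plus two unassayed census genes (`g10`, `g23`) placed inside the
inferred extent, where the annotation step can find them.

`make_toy_genome()` and `simulate_profile()` generate toy genomes and
ground-truth profiles: a panel sampled uniformly at a chosen density,
disjoint true amplicons placed uniformly (separated by at least one gene),
and the implied report — exactly the assayed genes inside a truth. A gene is
*truly amplified* iff its rank lies in a true amplicon, matching the
inference's rank-space convention. Both generators take an explicit seed and
restore the caller's RNG state, so identical seeds give byte-identical
downstream reports.

The simulation emulates the *observation process* (sparse panel over
contiguous amplicons) and nothing else. It does **not** model false
amplification calls, copy-number magnitude, deletions, or non-uniform gene
density along real chromosomes. Passing tests therefore demonstrate that the
set logic is exact under its own assumptions — they say nothing about how
often a real vendor's calls violate those assumptions.

Under the coverage condition — every true amplicon contains at least one
assayed gene and every gap between truths contains at least one assayed
gene — inferred calls are in bijection with truths, cores nest inside their
truths, and every truly amplified gene lands in core ∪ boundary. The test
suite checks this property on simulated profiles, alongside an O(n²)
brute-force oracle for consolidation and flagging, and a monotonicity
property: enlarging the panel with non-amplified genes never widens an
extent.

`boundary_error()` quantifies resolution: per side, the number of genes by
which the extent overshoots the truth (non-negative under the coverage
condition). `resolution_experiment()` sweeps panel density; it defaults to
one true amplicon per genome so the call–truth match is total whenever the
amplicon is detected at all (with several truths, a low-density panel can
leave a gap unobserved and merge two truths into one call, which the error
metric correctly refuses to score).

```{r resolution, eval = FALSE}
# Denser panels tighten boundaries; at full density the truth is recovered
# within one gene per side. ~1 minute at these sizes.
resolution_experiment(densities = c(0.1, 0.2, 0.5, 1.0),
                      n_seeds = 100, n_genes = 500, n_chroms = 1)
```

The test suite runs this experiment at 100 replicates per density on a
500-gene single-chromosome genome — sizes chosen so the sweep exercises
sparse (50 assayed genes) through exhaustive panels while each replicate
stays a few milliseconds of set logic; the property tests use 100 random
genomes of up to 500 genes against the quadratic oracle.

## Packaged data

The files under `inst/extdata/` are a hand-built **synthetic** stand-in for
real reference tables: 69 real gene symbols on chromosomes 1, 4, 5, 7, 11,
12 and 15 in their true relative order with approximate coordinates and
cytobands, a 29-gene panel modeled on a targeted assay, and a 36-gene census
subset. They exist so the documentation's worked clinical queries and the
integration tests run without downloads; absolute co-amplified counts on
this mini genome are small by construction and depend on which filler genes
it includes, exactly as real counts depend on the annotation release used.
For real analyses, supply a current coordinate table, the assay's gene
list and a census export.

## Known limitations

* The input is binary per gene; there is no magnitude modeling, no deletion
  handling, and no statistical confidence on boundaries.
* Exact-symbol matching only (case-insensitive): no alias or HGNC-history
  resolution, and no liftover between genome builds — the coordinate table
  must match the symbol vocabulary and build of the report.
* Inference quality is bounded by the vendor's calling accuracy; a missed
  call on a separating gene merges two amplicons (the adjacency flag exists
  precisely to surface the suspect cases).
* Region labels inherit the resolution of the supplied cytobands; without
  them, labels fall back to coordinates.
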