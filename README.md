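# panelamp

Amplicon boundary inference from gene-level amplification calls in targeted
tumor sequencing panel reports.

## The problem

Clinical NGS panel reports present somatic copy-number amplification as a
flat list of gene symbols — "amplified: RICTOR, CDK6, MET" — with no genomic
context. A physician or molecular tumor board reading such a list cannot
tell which of the reported genes sit on the same amplicon, how large that
amplicon might be, or which cancer-relevant genes *not on the panel* may be
co-amplified with them. That context matters: a small focal amplicon around
one oncogene supports the driver hypothesis; a broad region carrying many
genes suggests the reported gene may be a passenger.

`panelamp` reconstructs that context from the report alone, plus three
reference tables: gene coordinates, the assay's gene list, and a cancer gene
census.

## The algorithm

All reasoning is in **rank space**: genes on each chromosome are ordered by
position and numbered 0..n−1; "between" and "nearest" are defined on gene
order, never base pairs. For a panel *P* and a reported amplified set
*A ⊆ P*:

1. **Classification.** Every gene is `reported_amplified` (in *A*),
   `assayed_not_amplified` (in *P \ A*), or `not_assayed`.
2. **Consolidation.** Scanning each chromosome in rank order, two
   consecutive reported genes join the same amplicon **iff** no assayed
   non-amplified gene lies strictly between them. An amplicon's **core**
   spans its outermost reported genes; every gene in the core is considered
   amplified.
3. **Boundary extension.** On each side, the nearest assayed non-amplified
   gene delimits the amplicon; genes up to, but not including, that boundary
   gene are **possibly amplified**. With no assayed gene beyond the core on
   a side, the possibly-amplified region runs to the chromosome end and the
   side is marked unbounded.
4. **Adjacency flagging.** Two same-chromosome amplicons separated by at
   most `max_gap` assayed non-amplified genes (default 1) are mutually
   flagged: the single separating gene may be erroneously uncalled and one
   regional amplification may span both.

Reports annotate each amplicon with its cytoband region label (over the full
possibly-amplified extent), the count of potentially co-amplified genes
(extent genes minus reported genes — core and boundary are deliberately
pooled), census genes within the extent, and a COSMIC link per listed gene.

## Worked example

The package ships a small synthetic stand-in for the reference tables
(`inst/extdata/`: real gene symbols on chromosomes 1, 4, 5, 7, 11, 12 and 15
in their true relative order, with approximate coordinates and cytobands, a
29-gene panel and a 36-gene census subset — synthetic data, not an
annotation release). A triple-negative-breast-cancer-style query:

```r
library(panelamp)
fx <- synthetic_clinical_fixture()
calls <- infer_amplicons(fx$index, fx$panel, "RICTOR, CDK6, MET")
reports <- annotate_amplicons(calls, fx$index, fx$census)
writeLines(render_reports(reports, "text"))
```

```
Amplicon  Genes reported amplified  Co-amplified (region)  Census genes              Flags    
----------------------------------------------------------------------------------------------
amp1      RICTOR (Chr5p13.1)        3 (Chr5p13.2–5p12)     LIFR                               
amp2      CDK6 (Chr7q21.2)          5 (Chr7q21.12–7q22.3)  AKAP9, CDK6, TRRAP, CUX1  near amp3
amp3      MET (Chr7q31.2)           3 (Chr7q22.3–7q32.1)   MET, POT1, SND1           near amp2
```

Reading the output: the three reported genes resolve to three amplicons —
one on chromosome 5 and two on chromosome 7. `RICTOR`'s region stops just
short of the assayed, non-amplified `FGF10`, and carries the unassayed
census gene `LIFR`, which may be co-amplified although the panel never
measured it. The two chromosome-7 amplicons share the assayed gene `SRPK2`
at 7q22.3 as their only separator, so both are flagged `near` the other: a
single regional 7q amplification spanning both is a real possibility. The
`Co-amplified` column counts non-reported genes in each amplicon's full
(core + boundary) extent.

For real use, supply your own reference files:

```sh
Rscript inst/cli/panelamp.R call \
  --genes "RICTOR,CDK6,MET" \
  --coordinates coordinates.tsv --dialect tsv5 \
  --panel my_assay.txt --census census.txt --format text
```

File formats: coordinates are `symbol⇥chrom⇥start⇥end[⇥cytoband]` (tsv4/tsv5,
1-based inclusive) or BED4 (`chrom⇥start⇥end⇥symbol`, 0-based half-open);
panels and census lists are one symbol per line, `#` comments allowed, with
an optional tab-separated census tier. A source listing several intervals
for one symbol is rejected — collapse multi-transcript genes to one interval
per symbol before loading. Output formats: `text`, `tsv` (fixed header, one
amplicon per row), `json` (full structured calls: id, chromosome, reported
genes, core span with ranks/coordinates/genes, per-side boundary gene +
unbounded flag + genes, region label, extent coordinates, co-amplified
count, census genes, links, adjacency), `bed` (a core track and a
possibly-amplified extension track). `--verbose` adds the full assayed gene
list, every gene in each inferred amplicon, and the boundary genes used.

The `simulate` subcommand generates a toy genome with a known true amplicon,
runs inference on the implied report, and measures how far the inferred
extent overshoots the truth — the same machinery the test suite uses to
quantify how panel density limits boundary resolution.

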