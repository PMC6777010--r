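Package: panelamp
Title: Amplicon Boundary Inference from Gene-Level Amplification Calls in Targeted Panel Reports
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Clinical tumor sequencing panels report somatic copy-number
    amplification as a flat list of gene symbols, with no genomic context.
    panelamp reconstructs the likely contiguous amplicons behind such a list:
    genes reported amplified are placed in gene-rank order along each
    chromosome, consecutive reported genes are consolidated into one amplicon
    whenever no assayed non-amplified gene separates them, and each amplicon
    is extended outward to the nearest assayed non-amplified gene to delimit
    the possibly-amplified boundary region. Amplicons are annotated with
    cancer gene census membership, cytoband region labels and co-amplified
    gene counts, and closely co-located amplicons are flagged. A synthetic
    fixture and simulation layer generates toy genomes, panels and
    ground-truth amplification profiles so the whole pipeline is testable
    without external downloads, and a command-line interface exposes
    inference and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
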