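# SYNTHETIC cancer gene census subset (symbol <TAB> tier), modeled on a
# Tier 1/2 census list. Pairs with genome_synthetic_hg38_mini.tsv; not a
# census release.
BCL9	1
PDE4DIP	1
ARNT	1
MLLT11	1
TPM3	1
MUC1	1
LMNA	1
PRCC	1
SLC34A2	1
RHOH	1
PHOX2B	1
FIP1L1	1
CHIC2	1
PDGFRA	1
KIT	1
LIFR	2
IL6ST	2
AKAP9	2
CDK6	1
TRRAP	2
CUX1	1
MET	1
POT1	1
SND1	2
CCND1	1
NUMA1	1
LRIG3	2
WIF1	2
HMGA2	1
MDM2	1
B2M	1
USP8	2
MYO5A	1
C15ORF65	2
TCF12	1
MAP2K1	1
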