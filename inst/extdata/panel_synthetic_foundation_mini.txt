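# SYNTHETIC 29-gene assay panel modeled on a targeted clinical NGS test.
# Subset chosen to pair with genome_synthetic_hg38_mini.tsv; not a vendor
# gene list.
NRAS
MCL1
DDR2
FGFR3
PDGFRA
KIT
KDR
TERT
RICTOR
FGF10
PIK3R1
EGFR
CDK6
SRPK2
MET
SMO
HRAS
CCND1
FGF19
FGF4
FGF3
ATM
KRAS
CDK4
MDM2
PTPN11
SPRED1
MAP2K1
IDH2
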