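# SYNTHETIC stand-in for a genome coordinate table (tsv5 dialect:
# symbol, chrom, start (1-based), end, cytoband). Real gene symbols on
# chromosomes 1, 4, 5, 7, 11, 12 and 15 in their true relative order, with
# approximate hg38-like coordinates and cytobands. Built by hand for the
# worked clinical examples in the package documentation; not an annotation
# release.
NRAS	chr1	114704469	114716894	1p13.2
TBX15	chr1	119326566	119428928	1p12
BCL9	chr1	147547376	147632152	1q21.2
PDE4DIP	chr1	148829517	149071302	1q21.2
MCL1	chr1	150574551	150579738	1q21.2
ARNT	chr1	150809716	150876700	1q21.3
MLLT11	chr1	151062892	151072534	1q21.3
TPM3	chr1	154161812	154192100	1q21.3
MUC1	chr1	155185824	155192916	1q22
LMNA	chr1	156082573	156140081	1q22
PRCC	chr1	156769924	156800811	1q23.1
DDR2	chr1	162633660	162787404	1q23.3
FGFR3	chr4	1793293	1808872	4p16.3
KCNIP4	chr4	20730000	21950000	4p15.31
SLC34A2	chr4	25655644	25680370	4p15.2
RHOH	chr4	40192574	40246304	4p14
PHOX2B	chr4	41744082	41748970	4p13
FIP1L1	chr4	53377605	53458215	4q12
CHIC2	chr4	53787159	53812000	4q12
PDGFRA	chr4	54229097	54298245	4q12
KIT	chr4	54657957	54740715	4q12
KDR	chr4	55078481	55125595	4q12
TERT	chr5	1253287	1295162	5p15.33
SLC1A3	chr5	36606356	36688334	5p13.2
LIFR	chr5	38846059	38935002	5p13.1
RICTOR	chr5	38938021	39074510	5p13.1
PAIP1	chr5	43526066	43557327	5p12
FGF10	chr5	44300548	44389706	5p12
IL6ST	chr5	55935095	55994992	5q11.2
PIK3R1	chr5	68215756	68301821	5q13.1
EGFR	chr7	55019017	55211628	7p11.2
FZD1	chr7	91264000	91279000	7q21.12
AKAP9	chr7	91570180	91739987	7q21.2
CDK6	chr7	92604921	92836594	7q21.2
TRRAP	chr7	98878483	99062663	7q22.1
CUX1	chr7	101817097	102282656	7q22.1
LHFPL3	chr7	104161000	104743000	7q22.3
SRPK2	chr7	105122000	105415000	7q22.3
PUS7	chr7	105452000	105520000	7q22.3
MET	chr7	116672390	116798386	7q31.2
POT1	chr7	124822386	124929825	7q31.33
SND1	chr7	127652213	128092103	7q32.1
SMO	chr7	129188633	129213545	7q32.3
HRAS	chr11	532242	535550	11p15.5
BANF1	chr11	65971000	65980000	11q13.1
CCND1	chr11	69641156	69654474	11q13.3
FGF19	chr11	69699535	69705790	11q13.3
FGF4	chr11	69771000	69773000	11q13.3
FGF3	chr11	69809000	69818000	11q13.3
NUMA1	chr11	72002864	72080674	11q13.4
PAK1	chr11	77322000	77475000	11q13.5
ATM	chr11	108222484	108369102	11q22.3
KRAS	chr12	25205246	25250929	12p12.1
CDK4	chr12	57747727	57756013	12q14.1
LRIG3	chr12	58866700	59005000	12q14.1
WIF1	chr12	65055489	65128000	12q14.3
HMGA2	chr12	65824460	65966291	12q14.3
MDM2	chr12	68808172	68850686	12q15
CPM	chr12	69236000	69316000	12q15
PTPN11	chr12	112418915	112509918	12q24.13
SPRED1	chr15	38252086	38357249	15q14
B2M	chr15	44711477	44718877	15q15.1
USP8	chr15	50424655	50511113	15q21.2
MYO5A	chr15	52307283	52529050	15q21.2
TCF12	chr15	56918092	57290824	15q21.3
C15orf65	chr15	58000000	58010000	15q21.3
MAP2K1	chr15	66386837	66491656	15q22.31
IDH2	chr15	90083045	90102504	15q26.1
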