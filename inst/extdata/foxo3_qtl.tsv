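# QTL confidence intervals co-localizing with the FOXO3 candidate gene,
# as curated from the pig QTL database (48 records, 1-based inclusive
# coordinates). The source table carries no chromosome column; every
# record lies on pig chromosome 1 (the FOXO3 chromosome), so chrom is
# fixed to "1" here.
QTL_ID	QTL_symbol	Trait_name	chrom	QTL_start	QTL_end
3793	BFT	Average backfat thickness	1	52423837	166525431
5670	BFT	Average backfat thickness	1	3320998	144078329
5680	ADG	Average daily gain (10 weeks-slaughter)	1	3320998	193909568
329	ADG	Average daily gain (25-90 kg)	1	32980500	109360545
5928	ADG	Average daily gain (on weaning)	1	52423837	86769928
45	LUMBF	Backfat at last lumbar	1	73990528	154961837
3794	LRIBF	backfat at last rib	1	52423837	166525431
5674	LRIBF	backfat at last rib	1	7302766	163511869
651	BFTR	Backfat at rump	1	43291013	144078329
3795	10RIBBFT	Backfat at tenth rib	1	52423837	158592899
5672	10RIBBFT	Backfat at tenth rib	1	26500027	86769928
5679	BYLEAN	Belly meat content	1	7302766	163511869
2845	BELLYWT	Belly weight	1	51386391	139615854
5931	WWT	Body weight (weaning)	1	52423837	86769928
4260	CD2L	CD2-positive leukocyte number	1	24598042	144803085
4261	CD4L	CD4-positive leukocyte number	1	24598042	144803085
5669	cond	Conductivity 24 hours postmortem (ham)	1	52423837	166525431
5668	cond	Conductivity 24 hours postmortem (loin)	1	52423837	118433791
6366	CREAT	Creatinine level	1	33269805	126505160
8885	EAREA	Ear area	1	43291013	109360545
8886	EAREA	Ear area	1	43291013	109360545
8853	EARWT	Ear weight	1	43291013	109360545
8854	EARWT	Ear weight	1	43291013	109360545
5678	ECLC	Estimated carcass lean content	1	7302766	163511869
5676	FATAREA	Fat area	1	11402561	144078329
5677	FP	Fat ratio (percentage)	1	7302766	163511869
871	FEEDIN	Feed Intake	1	26957266	91781628
8908	FSCOREF	feet score (front)	1	32980500	108464751
860	HEADWT	Head weight	1	26957266	91781628
5420	HCT	hematocrit	1	33269805	126505160
8910	LSCOREH	leg score (hind)	1	32980500	108464751
872	LIVWT	Liver weight	1	26957266	91781628
3796	LMA	Loin muscle area	1	52423837	158592899
5468	LYMPH	Lymphocyte number	1	33269805	126505160
2930	MARB	Marbling	1	52423837	91781628
4019	MARB	Marbling	1	27710381	179573387
78	MARB	Marbling	1	73990528	86769928
5667	COLORO	Meat color OPTO QTL	1	52423837	163511869
5664	pH	pH for Longissmus Dorsi	1	52423837	118433791
5666	pH	pH for Longissmus Dorsi	1	52423837	118433791
5665	pH	pH for Semimembranosus	1	52423837	118433791
6380	BPOTASS	Potassium level	1	33269805	126505160
9658	PRRSVAB	PRRSV antibody titer	1	26500027	144251236
5675	SIDEF	Side fat	1	26500027	86769928
5671	SHOUFATD	Subcutaneous fat depth at shoulder	1	3320998	163511869
6481	TNUM	Teat number	1	43291013	109360545
79	TOTLIP	Total lipid	1	24598042	129115585
611	WBC	White blood cell counts	1	32980500	108464751
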