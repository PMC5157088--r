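##fileformat=VCFv4.1
##source=regionops synthetic fixture (COSMIC-like layout; not real data)
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene name">
##INFO=<ID=STRAND,Number=1,Type=String,Description="Coding strand">
##INFO=<ID=CDS,Number=1,Type=String,Description="CDS annotation">
##INFO=<ID=AA,Number=1,Type=String,Description="Peptide annotation">
##INFO=<ID=CNT,Number=1,Type=Integer,Description="Sample count">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
1	500	SYNDECOY001	A	C	.	.	GENE=SYNGENE1;STRAND=+;CDS=c.1A>C;AA=p.T1P;CNT=1
1	69345	COSM911918	C	A	.	.	GENE=OR4F5;STRAND=+;CDS=c.255C>A;AA=p.I85I;CNT=1
1	69523	COSM426644	G	T	.	.	GENE=OR4F5;STRAND=+;CDS=c.433G>T;AA=p.G145C;CNT=1
1	69538	COSM75742	G	A	.	.	GENE=OR4F5;STRAND=+;CDS=c.448G>A;AA=p.V150M;CNT=1
1	69539	COSM1343690	T	C	.	.	GENE=OR4F5;STRAND=+;CDS=c.449T>C;AA=p.V150A;CNT=1
1	69540	COSM1560546	G	T	.	.	GENE=OR4F5;STRAND=+;CDS=c.450G>T;AA=p.V150V;CNT=1
1	69569	COSM1599955	T	C	.	.	GENE=OR4F5;STRAND=+;CDS=c.479T>C;AA=p.L160P;CNT=2
1	150000	SYNDECOY002	G	A	.	.	GENE=SYNGENE2;STRAND=-;CDS=c.90G>A;AA=p.M30I;CNT=1
1	999999	SYNDECOY003	T	G	.	.	GENE=SYNGENE3;STRAND=+;CDS=c.12T>G;AA=p.S4A;CNT=3
1	1000500	SYNDECOY004	C	T	.	.	GENE=SYNGENE4;STRAND=+;CDS=c.33C>T;AA=p.D11D;CNT=1
1	1050000	SYNDECOY005	A	G	.	.	GENE=SYNGENE4;STRAND=+;CDS=c.101A>G;AA=p.K34R;CNT=2
1	1100000	SYNDECOY006	G	C	.	.	GENE=SYNGENE5;STRAND=-;CDS=c.7G>C;AA=p.A3P;CNT=1
1	1200000	SYNDECOY007	T	A	.	.	GENE=SYNGENE6;STRAND=+;CDS=c.55T>A;AA=p.F19I;CNT=1
2	5000	SYNDECOY008	C	G	.	.	GENE=SYNGENE7;STRAND=+;CDS=c.14C>G;AA=p.P5R;CNT=1
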