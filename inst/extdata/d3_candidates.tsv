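gene	protein_accession	sequence	charge	literature_flag	glyco_site	source_experiment
APMAP	Q9HDC9	AGPNGTLFVADAYK	2	TRUE	4	3D
AZU1	P20160	FVNVTVTPEDQCRPNNVCTGVLTR	3	TRUE	3	3D
CHL1	O00533	ISGVNLTQK	2	TRUE	5	3D
CHL1	O00533	IIPSNNSGTFR	2	TRUE	5	3D
CSPG4	Q6UVK1	LDPTVLDAGELANR	2	TRUE	13	3D
CTSD	P07339	GSLSYLNVTR	2	TRUE	7	3D
ELANE	P08246	VVLGAHNLSR	3	TRUE	7	3D
FCN3	O75636	VELEDFNGNR	2	TRUE	9	3D
IL6ST	P40189	LTVNLTNDR	2	TRUE	4	3D
LAMP2	P13473	VQPFNVTQGK	2	TRUE	5	3D
LTF	P02788	NGSDCPDKFCLFQSETK	3	TRUE	1	3D
MRC2	Q9UBG0	VTPACNTSLPAQR	2	TRUE	6	3D
POSTN	Q15063	EVNDTLLVNELK	2	TRUE	3	3D
RNASE1	P07998	SNSSMHITDCR	3	TRUE	2	3D
TIMP1	P01033	FVGTPEVNQTTLYQR	2	TRUE	8	3D
VNN1	O95497	MTGSGIYAPNSSR	2	TRUE	10	3D
VNN1	O95497	LTGVAGNYTVCQK	2	TRUE	7	3D
MASP1	P48740	NNLTTYK	2	TRUE	2	3D
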