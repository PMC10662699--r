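gene	protein_accession	sequence	charge	quant_mode	glyco_site
RNASE1	P07998	SNSSMHITDCR	3	is	2
MRC2	Q9UBG0	VTPACNTSLPAQR	2	is	6
ELANE	P08246	VVLGAHNLSR	3	is	7
VNN1	O95497	MTGSGIYAPNSSR	2	is	10
CHL1	O00533	ISGVNLTQK	2	is	5
CHL1	O00533	IIPSNNSGTFR	2	is	5
VNN1	O95497	LTGVAGNYTVCQK	2	is	7
IL6ST	P40189	LTVNLTNDR	2	is	4
LAMP2	P13473	VQPFNVTQGK	2	is	5
FCN3	O75636	VELEDFNGNR	2	is	9
CTSD	P07339	GSLSYLNVTR	2	is	7
TIMP1	P01033	FVGTPEVNQTTLYQR	2	is	8
AZU1	P20160	FVNVTVTPEDQCRPNNVCTGVLTR	3	label_free	3
LTF	P02788	NGSDCPDKFCLFQSETK	3	is	1
APMAP	Q9HDC9	AGPNGTLFVADAYK	2	is	4
POSTN	Q15063	EVNDTLLVNELK	2	is	3
CSPG4	Q6UVK1	LDPTVLDAGELANR	2	is	13
MASP1	P48740	NNLTTYK	2	is	2
AFM	P43652	YAEDKFNETTEK	2	is	7
APOH	P02749	VYKPSAGNNSLYR	3	is	8
KLKB1	P03952	GVNFNVSK	2	is	5
LGALS3BP	Q08380	GLNLTEDTYKPR	3	is	3
LUM	P51884	LHINHNNLTESVGPLPK	2	label_free	7
PON1	P27169	HANWTLTPLK	2	is	3
C6	P13671	VLNFTTK	2	is	3
LAMB1	P07942	LSDTTSQSNSTAK	2	is	9
PTPRJ	Q12913	SNDTAASEYK	2	is	2
NCAM1	P13591	DGQLLPSSNYSNIK	2	label_free	9
GPLD1	P80108	NINYTER	2	is	3
UMOD	P07911	QDFNITDISLLEHR	3	is	4
TFRC	G3V0E5	DFEDLYTPVNGSIVIVR	2	is	10
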