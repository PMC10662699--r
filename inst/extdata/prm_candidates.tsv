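gene	protein_accession	sequence	charge	source_experiment	blood_ng_ml	glyco_site
RNASE1	P07998	SNSSMHITDCR	3	3D	1100	2
MRC2	Q9UBG0	VTPACNTSLPAQR	2	3D	36	6
ELANE	P08246	VVLGAHNLSR	3	3D	0.37	7
VNN1	O95497	MTGSGIYAPNSSR	2	3D	980	10
CHL1	O00533	ISGVNLTQK	2	3D	5800	5
CHL1	O00533	IIPSNNSGTFR	2	3D	5800	5
VNN1	O95497	LTGVAGNYTVCQK	2	3D	980	7
IL6ST	P40189	LTVNLTNDR	2	3D	160	4
LAMP2	P13473	VQPFNVTQGK	2	3D	520	5
FCN3	O75636	VELEDFNGNR	2	3D	18000	9
CTSD	P07339	GSLSYLNVTR	2	3D	370	7
TIMP1	P01033	FVGTPEVNQTTLYQR	2	3D	110	8
AZU1	P20160	FVNVTVTPEDQCRPNNVCTGVLTR	3	3D	0.32	3
LTF	P02788	NGSDCPDKFCLFQSETK	3	3D	350	1
APMAP	Q9HDC9	AGPNGTLFVADAYK	2	3D	130	4
POSTN	Q15063	EVNDTLLVNELK	2	3D	660	3
CSPG4	Q6UVK1	LDPTVLDAGELANR	2	3D	48	13
MASP1	P48740	NNLTTYK	2	3D	9400	2
AFM	P43652	YAEDKFNETTEK	2	TMT-A	47000	7
APOH	P02749	VYKPSAGNNSLYR	3	TMT-A	280000	8
KLKB1	P03952	GVNFNVSK	2	TMT-A	29000	5
LGALS3BP	Q08380	GLNLTEDTYKPR	3	TMT-A	7100	3
LUM	P51884	LHINHNNLTESVGPLPK	2	TMT-A	29000	7
PON1	P27169	HANWTLTPLK	2	TMT-A;TMT-B	79000	3
C6	P13671	VLNFTTK	2	TMT-A	45000	3
LAMB1	P07942	LSDTTSQSNSTAK	2	TMT-B	250	9
PTPRJ	Q12913	SNDTAASEYK	2	TMT-B	670	2
PZP	P20742	QEVCEEFSQQLNSNGCITQQVHTK	4	TMT-B	15000	14
PZP	P20742	TFSSMTCASGANVSEQLSLK	3	TMT-B	15000	12
ENG	P17813	QNGTWPR	2	TMT-B	280	2
NCAM1	H7BYX6	NISSEEK	2	TMT-B	2300	1
GPLD1	P80108	NINYTER	2	TMT-B	110000	3
UMOD	P07911	QDFNITDISLLEHR	3	TMT-B	66	4
TFRC	G3V0E5	DFEDLYTPVNGSIVIVR	2	TMT-B	1300	10
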