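gene	protein_accession	sequence	fold_change	charge	p_value	literature_flag	glyco_site	source_experiment
PZP	P20742	QEVCEEFSQQLNSNGCITQQVHTK	1.53	4	0.052	FALSE	14	TMT-B
PZP	P20742	TFSSMTCASGANVSEQLSLK	1.41	3	0.077	FALSE	12	TMT-B
ENG	P17813	QNGTWPR	1.22	2	0.014	FALSE	2	TMT-B
UMOD	P07911	QDFNITDISLLEHR	1.21	3	0.085	FALSE	4	TMT-B
PON1	P27169	HANWTLTPLK	1.20	2	0.096	FALSE	3	TMT-B
TFRC	G3V0E5	DFEDLYTPVNGSIVIVR	1.20	2	0.095	FALSE	10	TMT-B
LAMB1	P07942	LSDTTSQSNSTAK	1.15	2	0.090	TRUE	9	TMT-B
NCAM1	H7BYX6	NISSEEK	1.11	2	0.082	TRUE	1	TMT-B
GPLD1	P80108	NINYTER	1.11	2	0.098	TRUE	3	TMT-B
PTPRJ	Q12913	SNDTAASEYK	1.09	2	0.031	TRUE	2	TMT-B
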