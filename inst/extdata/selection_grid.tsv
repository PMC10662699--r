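variable	pearson	chi2	rfe	logistic_l1	random_forest
ftPSA	TRUE	TRUE	TRUE	TRUE	TRUE
prostate_dimension	TRUE	TRUE	TRUE	TRUE	TRUE
proPSA	TRUE	TRUE	TRUE	TRUE	TRUE
tPSA	TRUE	TRUE	TRUE	FALSE	TRUE
fPSA	TRUE	TRUE	TRUE	FALSE	TRUE
VQPFNVTQGK	TRUE	TRUE	TRUE	TRUE	FALSE
SNSSMHITDCR	TRUE	TRUE	TRUE	FALSE	TRUE
NNLTTYK	TRUE	TRUE	TRUE	TRUE	FALSE
NINYTER	TRUE	TRUE	TRUE	TRUE	FALSE
LHINHNNLTESVGPLPK	TRUE	TRUE	TRUE	TRUE	FALSE
DGQLLPSSNYSNIK	TRUE	TRUE	TRUE	TRUE	FALSE
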