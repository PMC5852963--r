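# Pan-cancer cohort labels (colon and rectal merged as COADREAD) with the
# published RNA-seq sample counts, used as default per-cohort case numbers.
cohort	n_cases
BLCA	129
BRCA	817
COADREAD	382
GBM	166
HNSC	279
KIRC	469
LAML	173
LUAD	230
LUSC	501
OV	307
UCEC	333
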