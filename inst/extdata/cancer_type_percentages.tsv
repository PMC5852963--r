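# Top-10 cancer types associated with dual-role genes: percentage of
# dual-role gene associations vs the 2012 global cancer statistics share.
cancer_type	potsf_pct	global_pct
leukemia	13	2.5
breast	10.6	11.9
lung	6.2	12.9
prostate	5.1	7.9
sarcoma	4.7	1
hodgkin_lymphoma	4.7	0.5
colorectal	4.5	9.7
ovarian	4	1.3
bladder	3.6	3.1
stomach	3.6	6.8
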