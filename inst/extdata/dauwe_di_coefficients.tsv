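# Amino-acid degradation index (DI) reference statistics and first
# principal-component loadings, after Dauwe et al. (1999) Limnol. Oceanogr.
# 44:1809-1814. DI = sum_i [(mole%_i - mean_i) / sd_i] * loading_i over the
# protein amino acids below; positive scores indicate fresh, plankton-like
# material, negative scores degraded material.
#
# NOTE: values transcribed to the precision available here; verify against
# the original publication before quantitative cross-study comparison, or
# supply your own table via di_model().
aa_code	mean_molpct	sd_molpct	loading
Asp	13.4	2.2	-0.044
Glu	10.4	1.2	0.160
Ser	7.4	1.3	-0.187
His	1.2	0.6	0.041
Gly	16.6	3.9	-0.252
Thr	6.0	0.9	-0.180
Arg	4.5	1.0	0.181
Ala	11.1	1.3	-0.033
Tyr	2.4	0.8	0.284
Met	1.0	0.6	0.139
Val	6.4	0.7	0.106
Phe	3.8	0.6	0.272
Ile	4.3	0.6	0.289
Leu	6.8	0.9	0.288
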