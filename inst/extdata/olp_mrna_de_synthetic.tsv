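feature_id	fold_change_signed	p_value	distinct
COL21A1	-2.8	0.004	TRUE
CYP46A1	-1.9	0.012	TRUE
KCNJ1	-2.2	0.009	TRUE
MADCAM1	-3.1	0.002	TRUE
MRPS26	-1.6	0.026	TRUE
OR2T29	-2.4	0.007	TRUE
RPS9	-1.8	0.015	TRUE
SLC10A1	-2.9	0.003	TRUE
SLC16A8	-2.1	0.011	TRUE
SNTG1	-2.6	0.005	TRUE
TRPC5	-3.3	0.001	TRUE
GENE_UP1	2.4	0.008	FALSE
GENE_NS	-1.7	0.21	FALSE
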