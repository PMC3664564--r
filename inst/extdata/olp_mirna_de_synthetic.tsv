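feature_id	fold_change_signed	p_value
hsa-miR-155	3.1	0.003
hsa-miR-342-3p	1.9	0.021
hsa-let-7i	2.2	0.012
hsa-miR-15a	1.7	0.034
hsa-miR-143	2.5	0.008
hsa-miR-132	2.0	0.016
hsa-miR-31	2.8	0.005
hsa-miR-21	3.4	0.002
hsa-miR-335	1.8	0.028
hsa-miR-999-dn	-2.1	0.014
hsa-miR-888-ns	1.6	0.37
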