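mirna_id	transcript_id	score
hsa-miR-155	COL21A1	4
hsa-miR-342-3p	CYP46A1	3
hsa-miR-155	KCNJ1	4
hsa-let-7i	MADCAM1	3
hsa-miR-15a	MRPS26	2
hsa-miR-143	OR2T29	3
hsa-miR-132	RPS9	4
hsa-miR-31	SLC10A1	3
hsa-miR-31	SLC16A8	2
hsa-miR-21	SNTG1	4
hsa-miR-335	TRPC5	3
hsa-miR-155	GENE_UP1	3
hsa-miR-999-dn	COL21A1	2
hsa-miR-888-ns	MADCAM1	3
hsa-miR-335	GENE_NS	2
hsa-miR-21	GENE_ABSENT	4
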