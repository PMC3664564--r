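# Bundled example tables

`olp_mrna_de_synthetic.tsv`, `olp_mirna_de_synthetic.tsv`,
`olp_predictions_synthetic.tsv`

A synthetic reconstruction of the published oral-lichen-planus screening
summary used by the worked pairing example: the gene/miRNA identities, the
miRNA-to-target assignments and the regulation directions (all eleven
candidate miRNAs up-regulated, all eleven candidate target transcripts
down-regulated) follow the published results; the fold-change magnitudes
and p-values are invented placeholders (the underlying per-sample data are
not bundled), and a few distractor rows (a concordantly regulated target, a
non-significant transcript and miRNA, an unknown transcript id) are added
to exercise the pairing filters. Running `assemble_pairs()` on these tables
yields exactly the eleven opposite-direction candidate pairs.
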