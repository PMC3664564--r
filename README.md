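# mirlink

Integrated miRNA-mRNA differential expression and target pairing for
small two-group, two-platform expression studies.

`mirlink` is aimed at analysts of case-control transcriptomics studies in
which mRNA and miRNA profiles were measured on the same small cohort (the
motivating design is 7 diseased vs 7 healthy tissue samples) and the goal
is a set of candidate regulatory miRNA-mRNA pairs: a differentially
expressed miRNA linked to a predicted target transcript that is regulated
in the *opposite* direction.

## The statistics at its core

For each feature, case values $x_1,\dots,x_{n_1}$ and control values
$y_1,\dots,y_{n_2}$ are pooled and midranked. The package computes:

- the **rank-sum difference** $D = R_{\text{case}} - R_{\text{control}}$
  and its theoretical maximum for the group sizes (49 for 7 vs 7); a
  feature attaining the maximum shows **complete separation** between the
  groups ("distinctly expressed");
- the **Mann-Whitney U test**, exact by enumeration of the permutation
  distribution of $U$ for small samples (at 7 vs 7 the minimal two-sided
  p is $2/\binom{14}{7} \approx 5.8\times10^{-4}$), or a tie-corrected
  normal approximation;
- **signed fold changes** $+r$ / $-1/r$ from ratios of group means on the
  linear scale;
- canonical **seed-match target prediction** (6mer / 7mer-A1 / 7mer-m8 /
  8mer sites on the 3'UTR, strict Watson-Crick, with a 3'-supplementary
  bonus), or an external prediction table;
- the **opposite-direction pairing rule**, GO-process counting with exact
  hypergeometric enrichment tails, UPGMA clustering on $1-r$ correlation
  dissimilarity, PCA on z-scored values, a genomic hotspot scan, and a
  qPCR standard-curve validation stage whose screening-vs-validation
  Spearman correlation gets an empirical probability from $k$ random
  re-pairings (default $k = 10{,}000$, floor $1/(k+1) < 0.01\%$).

A synthetic-study generator plants DE features, complete-separation
features, seed sites and true miRNA-target pairs with known ground truth,
so the entire pipeline is testable without any downloads.

## Worked example

```r
library(mirlink)

cfg <- synthetic_config(seed = 1)       # 7v7, 2000 mRNAs, 150 miRNAs
ds  <- generate_dataset(cfg)
de  <- run_de(ds$mrna)
attr(de, "summary")
#> present regulated        up      down  distinct
#>    1485       151        86        65        85

sq    <- generate_sequences(cfg, ds$truth)
pred  <- predict_table(sq$mirna_seqs[ds$truth$de_mirna_ids], sq$utr_seqs,
                       min_site_type = "8mer")
pairs <- assemble_pairs(de, run_de(ds$mirna), pred)
nrow(pairs)
#> [1] 19
head(pairs[, 1:6], 4)
#>   mirna_id  mrna_id mirna_fc_signed mrna_fc_signed  mirna_p   mrna_p
#> 1  MIR0073 MRNA0050            6.25          -4.64 0.000583 0.000583
#> 2  MIR0110 MRNA0167           -4.16           4.09 0.000583 0.000583
#> 3  MIR0060 MRNA0170           -5.77           4.38 0.000583 0.000583
#> 4  MIR0059 MRNA0179            3.02          -3.32 0.000583 0.000583
```

Of the 2,000 simulated transcripts, 1,485 pass the present call and 151
are regulated at raw p ≤ 0.05 (the ~50 beyond the 100 planted effects are
the expected small-sample false positives); 19 opposite-direction pairs
carry an 8mer site, including all 11 planted true pairs, each with an
up-regulated member facing a down-regulated partner at Mann-Whitney
p-values down to the 7v7 floor of 0.000583. The remaining 8 pairs arise
from chance 8mer matches among regulated features — exactly the behavior
seed-only prediction is expected to show.

The full pipeline (simulation → DE → prediction → pairing → genomic map →
GO → clustering/PCA → qPCR validation and permutation concordance) runs in
one call and writes every table plus a digest manifest:

```r
out <- run_all(demo_pipeline_config("demo_run", seed = 1))
out$summary$concordance
#> $n_same      [1] 16        # all validated features keep their sign
#> $rho_observed [1] 0.985    # screening vs validation Spearman rho
#> $p_empirical  [1] 5e-04    # floor of the k = 2000 permutation test
```

A thin shell wrapper is included:
`Rscript inst/scripts/run_pipeline.R --out demo_run --seed 1`.

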