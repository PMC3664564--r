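---
title: "Methods: rank-based differential expression and miRNA-mRNA pairing"
author: "mirlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-based differential expression and miRNA-mRNA pairing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirlink)
```

## The analysis problem

`mirlink` implements an integrated two-platform analysis for small
case-control expression studies, of the kind used to look for regulatory
miRNA-mRNA networks in diseased versus healthy tissue (the motivating
setting is oral lichen planus, a chronic T-cell-mediated mucosal disease,
profiled in 7 patients against 7 controls on separate mRNA and miRNA
arrays). The pipeline takes normalized, positive relative-expression
matrices for both platforms, and produces:

1. per-feature rank-based differential-expression calls with a
   complete-separation ("distinctly expressed") flag,
2. seed-match target predictions linking miRNAs to 3'UTRs,
3. candidate miRNA-mRNA pairs in which the two members are regulated in
   opposite directions,
4. descriptive GO-process counts with enrichment/depletion tests, a genomic
   map with a windowed hotspot scan, clustering/PCA structure checks, and
5. a qPCR validation stage with a permutation-based concordance test.

## Differential expression

With case values $x_1,\dots,x_{n_1}$ and control values
$y_1,\dots,y_{n_2}$ for one feature, all values are pooled and midranked.
The statistic is the rank-sum difference
$D = R_{\text{case}} - R_{\text{control}}$. Its extreme value in the
upward direction, attained when every case value exceeds every control
value, is

$$D_{\max} = \left(n_1 n_2 + \tfrac{n_1(n_1+1)}{2}\right) -
\tfrac{n_2(n_2+1)}{2},$$

(for 7 vs 7, $D_{\max} = 77 - 28 = 49$), with the mirrored expression in
the downward direction; for unequal group sizes the two magnitudes differ,
and the reported maximum is the one for the observed direction. A feature
with $|D| = D_{\max}$ is *distinctly expressed*: the two groups' value
ranges do not overlap. Because midranks are used, a tie across the group
boundary always pulls $|D|$ below $D_{\max}$, so tied features can never be
distinct — this matches the set definition (all values of one group
strictly above all of the other). The equivalence of the rank criterion
and the range-overlap criterion is property-tested on random data.

Two-sided p-values come from the Mann-Whitney $U$ statistic,
$U = R_{\text{case}} - n_1(n_1+1)/2$. In `exact` mode the permutation
distribution of $U$ is enumerated: a dynamic program counts the
$k$-subsets of ranks $1..N$ by rank sum (tie-free data), or the subsets of
the observed midranks are enumerated outright (within-group ties). Exact
mode refuses cross-group ties, because the observed midrank $U$ is not a
point of the tie-free lattice; `normal` mode then applies the
tie-corrected normal approximation with a continuity correction. The
`auto` default uses the exact test for $n_1+n_2 \le 16$ without
cross-group ties. At 7 vs 7, complete separation gives the smallest
attainable two-sided p, $2/\binom{14}{7} = 2/3432 \approx 5.8\times
10^{-4}$.

Signed fold changes are ratios of group aggregates on the linear scale,
$r = \bar{x}/\bar{y}$, reported as $+r$ for $r \ge 1$ and $-1/r$
otherwise. The aggregate is the arithmetic mean by default, with the
median available (`agg = "median"`); the source analysis states only that
ratios of relative expression were used, so the choice is exposed rather
than hard-coded.

**Present-calling.** Array vendors' present/absent calls are
platform-specific, and the analysis this package generalizes reports only
the outcome of present-calling, not its rule. The package's own rule is: a
feature is present when its log2 expression exceeds a floor (default 4.0)
in at least half the samples of at least one group. Both knobs are
configurable; analyses of externally present-called matrices can pass
`floor = -Inf`.

**Multiple testing.** Regulation is called at raw $p \le 0.05$ by default,
matching the non-parametric screening convention the pipeline reproduces;
Benjamini-Hochberg adjustment is available behind `adjust = "BH"`.

### Calibration note: discreteness at 7 vs 7

The exact two-sided test at $n_1=n_2=7$ has attainable levels only at
multiples of $2/3432$. The largest attainable level not exceeding 0.05 is
$130/3432 \approx 0.0379$, and the tie-corrected normal approximation with
continuity correction selects the same rejection region. Consequently the
observed fraction of null features with $p \le 0.05$ concentrates near
0.038, not 0.05: the test is valid (never anti-conservative) but
discrete. This is a property of the design, not of the implementation, and
it is what the package's null-calibration check measures.

## Target prediction

The published analysis used a structure-aware predictor (PITA); the
package's built-in scanner deliberately implements only canonical seed
matching with a transparent score, because the object of interest
downstream is the pairing logic, and an external prediction table (e.g.
from PITA itself) can be supplied with `read_predictions()` to reproduce
any external tool's pairing inputs exactly.

Site types follow the field-standard definitions on the UTR sense strand:
6mer (match to miRNA positions 2-7), 7mer-A1 (6mer plus an adenosine
opposite position 1), 7mer-m8 (match to 2-8), 8mer (both). Matching is
strict Watson-Crick; G:U wobble is not honored — the conservative and most
common convention for seed sites. Scores rank the types 8mer=4 > 7mer-m8=3
> 7mer-A1=2 > 6mer=1, with a +1 bonus when the four UTR bases opposite
miRNA positions 13-16 all pair (a crude 3'-supplementary term).
Overlapping classifications at one locus collapse to the strongest type.
Offsets are 0-based on the UTR sense strand, pointing at the site's
5'-most matched base; this convention is used everywhere coordinates
appear. The scanner is verified against a naive per-offset oracle on
random sequences.

## Pairing rule

A candidate pair is a predicted (miRNA, transcript) interaction where both
members are regulated at the chosen threshold and their signed fold
changes have opposite signs. Direction comes from the fold change, not
from the rank statistic, matching how up-miRNA/down-mRNA pairing is
described in the source setting. Pairs are unique at the (miRNA,
transcript) level (multiple sites collapse into one pair carrying the best
score), ordered canonically, and `restrict_to_distinct = TRUE` narrows the
mRNA side to distinctly expressed transcripts — both readings of which DE
set feeds the pairing are supported because the source analysis does not
state it unambiguously.

The genomic map places regulated features at their coordinates with
$-\log_{10} p$ and fold change; the hotspot scan counts regulated features
per fixed 10 Mb window (configurable) and attaches a binomial tail
probability against the genome-wide regulated fraction. The scan is
reported descriptively and never thresholded into a headline, since its
role is to notice — or rule out — positional clustering.

## GO counting and enrichment

Annotations are consumed as a flat gene-to-term table (no ontology-graph
propagation; a documented limitation). Counting is by occurrences of terms
over a selection, with terms below a minimum level optionally omitted
(broad level-1 terms add little). Enrichment and depletion are exact
hypergeometric tails,
$p_{\text{enrich}} = P(X \ge k)$ and $p_{\text{deplete}} = P(X \le k)$,
against a background that defaults to the present features of the tissue
rather than the whole annotation universe. A permutation alternative
(resampling equal-size selections) is available for cross-checking. Raw
p-values are reported by default, with BH optional.

## Structure checks

Sample clustering is unweighted average linkage (UPGMA) on the
dissimilarity $1 - r$, where $r$ is the Pearson correlation of log2
profiles; samples are sorted by id first so ties break deterministically.
PCA z-scores each feature row across samples — population (divide-by-$n$)
standard deviation, a deterministic function of the data; the source
analysis does not specify — and decomposes the standardized matrix by SVD.
Components are oriented so the largest-magnitude loading is positive. The
separation score reports the minimal misassignment count over cluster-cut
labelings or over all thresholds of a 1-d score such as PC1. Whether the
original heat maps clustered raw, log or z-scored values is not stated in
the source; log2 is this package's choice, exposed as a flag.

## Validation stage

qPCR quantification uses the standard-curve method: a least-squares line
of Ct on $\log_{10}(\text{quantity})$, efficiency $10^{-1/\text{slope}} -
1$, technical triplicates averaged on the Ct scale before inversion
(optionally dropping replicate sets with range above 1 Ct), and
normalization to a constant reference assay per sample.

Concordance between screening and validation is Spearman's rank
correlation over matched per-feature signed fold changes (the
per-feature-value reading; the alternative per-sample reading is not
identifiable from the source description). Its significance is assessed by
permuting the association between the two vectors $k$ times (default
10,000) and recomputing rho — a single-statistic permutation scheme in the
Westfall-Young spirit; the full step-down maxT machinery is unnecessary
for one statistic and is out of scope. The empirical probability uses the
add-one correction $(\#\{|\rho^*| \ge |\rho|\}+1)/(k+1)$, two-sided on
$|\rho|$ by default with the signed one-sided version always reported,
since the source does not state sidedness. With $k = 10{,}000$ the
smallest attainable probability is $1/10{,}001 < 0.01\%$.

## The synthetic-data generator

Every stage is exercised end to end on generated data with known ground
truth. The generator emulates the study conditions: 7 cases vs 7 controls;
log2 baselines $\mathcal{N}(7, 2)$ floored at 0 (a plausible array scale —
the source gives no distribution); ~20% of features generated below the
present-call floor in every sample ("absent"); planted DE features shifted
in cases by a signed effect of magnitude $|\mathcal{N}(2, 0.25)|$ log2
units against within-group noise sd 0.5 (the source states no effect sizes
or variances; these are calibration choices made once, matching the
recovery conditions the test-suite states); a subset of DE mRNAs rebuilt
with a guaranteed log2 gap of 1 so complete separation holds by
construction; and 11 planted miRNA-target pairs (the published pair count)
whose members always move in opposite directions. Feature scale is reduced
(defaults 2,000 mRNAs / 150 miRNAs; tests use 120-1,000) relative to the
~33,000/~7,656 probes of a real array study purely for runtime; the
statistics under test are per-feature, so feature count affects only
Monte-Carlo resolution.

Sequences are random-composition (UTRs 500 nt, miRNAs 22 nt) with one
seed site of the configured type (8mer by default — the unambiguous
recovery target) written into each true pair's UTR at a recorded offset;
flanking bases are adjusted so the scanner reports exactly the planted
type, and accidental seed matches elsewhere are detected and recorded
rather than prevented. The qPCR generator derives triplicate Ct values
from the expression matrix through a standard curve (slope
$-1/\log_{10} 2$, one Ct per 2-fold) plus Gaussian noise, with a constant
reference feature; at noise 0 the validation stage reproduces screening
fold changes exactly, pinning the whole quantification chain.

All randomness flows from the single configuration seed through scoped RNG
(the session's `.Random.seed` is saved and restored), so identical
configurations give byte-identical artifacts and the generator never
perturbs user code.

What the generator does *not* emulate: probe-level array artifacts, batch
effects, normalization residue, correlated features, cell-composition
heterogeneity, or miRNA-induced repression as a causal process (planted
pairs are marginal opposite shifts, not a mechanistic model). Passing
recovery tests therefore demonstrates the correctness of the statistics
and the plumbing, not robustness to the confounders of real tissue data.

## Numerical and design choices

- Expression is stored on the linear scale; every log2 transform is
  explicit at its computation site, avoiding double-log bugs.
- Text tables are TSV with header, UTF-8, LF; floats are written with
  `%.17g`, which round-trips IEEE doubles, so write-read-write is
  byte-stable and reruns can be compared by digest.
- Exact-test enumeration is memoized per group-size pair; with
  $n_1+n_2 > 16$, `auto` switches to the normal approximation.
- Degenerate inputs fail loudly and name the offender: zero-variance
  sample profiles in clustering, zero rank variance in Spearman,
  non-positive group means in fold changes, infeasible synthetic
  configurations, cross-group ties in exact mode.
- The end-to-end demonstration (`demo_pipeline_config()`) uses 400 mRNAs,
  60 miRNAs, 8 planted pairs and 2,000 permutations so a full run
  completes in seconds; these sizes are the package's demonstration
  choices and can be raised freely.

## Worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 1)
ds  <- generate_dataset(cfg)
de  <- run_de(ds$mrna)
attr(de, "summary")

sq    <- generate_sequences(cfg, ds$truth)
pred  <- predict_table(sq$mirna_seqs[ds$truth$de_mirna_ids], sq$utr_seqs)
pairs <- assemble_pairs(de, run_de(ds$mirna), pred)
head(pairs)

out <- run_all(demo_pipeline_config(tempfile(), seed = 1))
out$summary$concordance
```

## Known limitations

- The built-in predictor is canonical seed matching only; no
  thermodynamic accessibility, conservation, or non-canonical sites.
  Supply an external table for structure-aware predictions.
- Flat GO annotations without is-a closure.
- The exact test's discreteness at very small $n$ (above) bounds
  achievable type-I rates below nominal.
- The pipeline consumes normalized matrices; normalization itself (e.g.
  RMA of raw arrays) is out of scope.
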