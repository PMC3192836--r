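---
title: "Methods: comparative miRNA expression and regulatory divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative miRNA expression and regulatory divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdiv)
```

# Scope and model

`mirdiv` implements a comparative small-RNA analysis for closely related
primate species (human, chimpanzee, rhesus macaque as outgroup) from the
point where reads have already been mapped: the inputs are per-sample
stacks of distinct small-RNA sequences with genomic 5' positions and copy
numbers, miRNA precursor annotations, ortholog hit tables produced by
external mappers, expression matrices, transfection matrices, and a
derived-SNP track. Every one of those inputs can also be produced by the
seeded synthetic generator with known ground truth, which is how the
package tests itself end to end.

The pipeline stages and their core assumptions:

* **5'-anchored quantification.** Mature miRNA have well-defined 5' ends
  (the seed sequence starts there), so reads are keyed to the annotated
  mature 5' genomic position. Reads within ±3 nt of it are retained; the
  retained sequence with the maximal copy number is the reference, and the
  miRNA's count is the summed copies of all retained sequences sharing the
  reference's 5' position. Novel star-arm candidates on the opposite
  precursor arm are accepted when at least 14 nt separate them from the
  annotated mature on the precursor. A miRNA counts as detected at 10 or
  more reads.
* **Ortholog assignment.** The three external mappers are not executed;
  the module consumes their hit tables. Hits are filtered to strictly
  70%–130% of the query length, grouped into loci by 50% reciprocal
  overlap, and a locus supported by at least two of the three methods is
  called; two such loci make the query ambiguous and no call is made.
  Mature sequences are projected through a global precursor alignment
  (match +1, mismatch −1, gap open −5, gap extend −1). Array probes are
  masked whenever the mature sequences differ at all between species.
* **Differential expression.** For sequencing counts, the two species'
  libraries are normalized and each miRNA is tested with Fisher's exact
  test on the 2×2 table contrasting its count with the remainder of each
  library; a call requires p < 0.01, linear fold-change > 2 and detection
  (≥ 10 reads in at least one species), in both technical replicates with
  the same direction. For arrays, a two-sample Student t-test with the
  same thresholds, after probe masking. An externally computed
  negative-binomial exact-test table can be filtered at p < 0.001 and
  FDR < 0.01 through a hook; that test is itself out of scope here.
* **Lineage assignment.** The macaque level proxies the ancestral state: a
  human–chimpanzee difference is assigned to the lineage whose level is
  farther from the macaque level, provided the other species lies on the
  macaque side of it. With real-valued data the side condition follows
  from the distance condition; it matters only at boundary equalities,
  which are left unassigned.
* **Target effects.** mRNA divergence is the log2 human/chimpanzee
  fold-change (genes with |divergence| < 0.5 excluded); protein divergence
  is the pooled-SD standardized mean difference (|d| ≤ 1 excluded). The
  divergence-shift comparison between targets of human-high and
  chimpanzee-high miRNA uses the unpaired rank-sum test; genes targeted by
  both groups are excluded first. Significance of per-gene divergence is
  thresholded with a whole-column label-permutation FDR (1000 permutations
  at production scale). The headline statistic is
  `percent_explained = 100 * (n_negative − n_positive) / n_total`, with a
  gene counted negative as soon as any miRNA–gene pair changes in opposite
  directions (opposite-direction evidence is decisive).
* **Verified targets.** Per prediction algorithm, transfection inhibition
  cutoffs are scanned from 0 to −2 in steps of 0.05, and the loosest
  cutoff whose proportion-based FDR (non-target passing fraction over
  target passing fraction, both requiring the cutoff in both cell lines)
  falls under 10% is selected; the verified set is the union over
  algorithms, with per-miRNA threshold overrides (e.g. 15% for a weakly
  inhibiting miRNA). The denominator reading "fraction of predicted
  targets passing" makes the FDR a proper ratio and is the default; the
  alternative "fraction of targets expressed" reading is switchable.
* **Selection scan.** A SNP is human-derived when at least 4 of 6 modern
  genomes are derived and all observed Neanderthal alleles are ancestral.
  The 150 kb upstream of each candidate precursor is tiled into 50 kb
  windows at a 10 kb step, each window tested one-sided against the genome
  totals with Fisher's exact test, Bonferroni-corrected across all windows
  of the scanned set (5 × 11 = 55 by default). Global significance comes
  from a feature-anchored permutation null: the same statistic on 1000
  random k-subsets of all annotated precursors, with empirical
  p = exceedances / permutations (so 44/1000 prints as 0.044).

# The synthetic-data generator

The generator is first-class, tested code; its defaults define the
simulated study conditions.

* **Counts** come from a gamma–Poisson (negative-binomial) model on
  per-miRNA relative abundances drawn log-normally (sdlog 1). The default
  dispersion of 1e-4 models technical replication of pooled libraries —
  replicate correlations in this design are near-perfect — and keeps the
  exact hypergeometric null of Fisher's test honest. Biological
  between-individual variability can be dialed in via `nbDispersion`, but
  then a count model that estimates dispersion (the externally computed
  exact-test hook) is the appropriate caller.
* **Read layout.** All in-window reads of a miRNA share the annotated
  mature 5' position and differ in 3' length only, mirroring the dominant
  isomiR mode (5' ends are constrained by seed function, 3' ends are
  ragged). About 5% of each miRNA's reads are diverted to a decoy beyond
  the ±3 window to exercise the window filter; stack copies therefore sum
  exactly to the drawn totals, and the quantified count equals the
  implanted in-window total.
* **Differential expression** is implanted by multiplying a fraction
  `deFraction` (default 0.1) of miRNA by `deFold` (default 4) in one
  random up-species. An optional phylogenetic drift term (`phyloSd`,
  default 0 so the null generator is truly null) makes human and
  chimpanzee expression covary relative to the macaque, for clustering
  studies: human and chimpanzee share an ancestor component of s.d.
  `phyloSd` with tip deviations of `phyloSd/3`, while the macaque drifts
  independently at `2 * phyloSd`.
* **Expression matrices** (5 individuals per species mRNA, 4 protein,
  matching a typical exon-array / proteomics design) shift the true
  targets of each implanted miRNA down by `targetEffect` log2 units in
  that miRNA's up-species, over a shared gene baseline, with Gaussian
  noise (`noiseSd`, default 0.2 log2 units).
* **Transfection matrices** give true targets a mean effect of
  `-targetEffect`; each gene also has a per-cell-line off-target response
  (s.d. `noiseSd`) shared between the two mock comparisons plus per-mock
  measurement noise (`mockNoiseSd`, default 0.05), so mock-replicate
  effects correlate above 0.9 as in real negative-control replicates.
* **SNP tracks** place SNPs uniformly (density 0.005/bp, giving ~250 SNPs
  per 50 kb window) with a 5% background derived fraction, raised by
  `excess` inside implanted sweep windows.

What the generator does **not** emulate: sequencing error and adapter
artifacts, hairpin thermodynamics, mappability structure, linkage
disequilibrium between SNPs, correlated target sets between miRNA
families, and compositional competition beyond the shared multinomial
normalization. Passing recovery tests therefore demonstrates that the
statistics find what they are defined to find under their own model — not
that the model captures every property of real libraries.

# Numerical choices

* "Within three nucleotides" is inclusive (|offset| ≤ 3); ties for the
  reference sequence break to the lexicographically smallest sequence.
* Separation between mature and star candidate is linear gap length on the
  precursor; hairpin base-pairing is out of scope.
* Fold changes add a 0.5 pseudocount to both species. Quantile-normalized
  counts are rounded to integers before the exact test.
* Quantile normalization rank-matches two libraries, which erases fold
  changes of miRNA whose rank is preserved (notably at the extreme top of
  the distribution) and makes the exact test conservative. The TPM path
  is therefore used wherever calibration matters; because Fisher's test
  depends only on proportions, it tests raw counts against raw library
  totals (an identical comparison of TPM values) rather than rescaling
  counts to a fictitious library size of 10^6, and uses TPM only for the
  fold-change scale.
* The two-sided Fisher p-value follows the "probability at most observed"
  rule; the window test is one-sided for derived excess (two-sided by
  flag). Genome totals include the window's own SNPs by default (the
  comparison is against the genome average; at genome scale the
  difference is negligible), with exclusion available by flag.
* Empirical permutation p-values use exceedances/n rather than
  (k+1)/(n+1): the printed convention of the reproduced statistics. The
  cost is that a p of exactly 0 is possible at finite n.
* The rank test is run unpaired: the named signed-rank variant presumes a
  pairing that the two target groups do not have; the discrepancy is
  recorded rather than resolved by guessing a pairing.
* UPGMA heights are half the merge distances (ultrametric node depths);
  agglomeration is `hclust(method = "average")` on 1 − Pearson
  correlation, and constant columns are an error naming the sample.

# Problem sizes in the test suite

The suite runs the full pipeline at reduced scale: 200 miRNA at depth
1e5 with 2 technical replicates for differential-expression calibration
(2000 null miRNA pooled over ten seeds) and recovery; 2000 genes for
target-effect and transfection recovery; 5 scanned upstream regions of
150 kb at SNP density 0.005 over 10–20 seeds for the sweep scan. These
sizes were chosen so that the binomial uncertainty of every estimated
rate stays well inside the asserted bounds. Exhaustive oracle sweeps for
the exact tests cover all 2×2 tables with small margins plus a seeded
random sweep up to N1 + N2 = 200; the rank-test oracle enumerates all
assignments up to 8 per group.

An overlapping-window caveat for the sweep recovery check: sliding 50 kb
windows at a 10 kb step necessarily share an implanted 50 kb sweep, so
"other windows stay silent" is asserted for windows disjoint from the
implanted interval.

# Limitations

* The Fisher exact test on counts assumes at most Poisson-level technical
  noise; with biological replicates and real dispersion it is
  anti-conservative, which is exactly why the external
  negative-binomial hook exists.
* The ortholog module trusts the hit tables it is given; reciprocal-best
  verification against whole genomes is out of scope, and the 50%
  reciprocal-overlap locus grouping is a convention, not an inference.
* The lineage rule is a minimal reading of outgroup-based assignment and
  does not model within-species polymorphism of expression.
* `percent_explained` inherits the assumption that negative
  miRNA–target association indicates regulation while positive
  association is background; both can fail in either direction.

# Worked example

```{r example, eval = FALSE}
cfg <- simConfig(seed = 1, nMirna = 200, depth = 1e5,
                 deFraction = 0.1, deFold = 4)
sim <- simulateReadStacks(cfg)
counts <- quantifyAll(sim$stacks, sim$loci)
calls <- callDeSeq(counts, normalize = "tpm")
expr <- simulateExpression(cfg, sim$truth)
m <- SummarizedExperiment::assay(expr$mrna, "log2")
species <- SummarizedExperiment::colData(expr$mrna)$species
divergence <- rowMeans(m[, species == "human"]) -
    rowMeans(m[, species == "chimpanzee"])
sig <- permutationFdr(m[, species != "macaque"],
                      species[species != "macaque"],
                      alpha = 0.001, nPerm = 1000, seed = 1)
countAssociations(calls, targetMap(sim$truth), divergence, sig$sig_genes)
```
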