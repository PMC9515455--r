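---
title: "Methods: MAG refinement, dereplication, profiling and cohort statistics"
author: "magprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MAG refinement, dereplication, profiling and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `magprof`, in the spirit of how distance-based ecology and
differential-abundance packages document theirs. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The chain and its assumptions

The package implements the analysis chain of a two-group (case `PE` vs
control `HC`) shotgun-metagenomics cohort built on metagenome-assembled
genomes (MAGs). Upstream stages that operate on raw reads — quality
control, assembly, initial binning, marker-gene quality estimation,
taxonomy inference, gene calling and KEGG search — are *consumed as
tables* (bin FASTA + quality + taxonomy, mapped-read counts, gene/KO hit
tables); the package neither reimplements nor wraps those external
tools. A synthetic-community generator emulates all of their outputs
with known ground truth, which is what the tests exercise.

## Bin refinement

**Depth** is `total_mapped_reads × average_read_length /
total_bin_length`, the mean number of read bases per position.

**Merging.** Within one sample, two bins are merge-compatible iff

* `|d1 − d2| / mean(d1, d2) ≤ 0.10` — the "±10% between each other"
  rule is operationalized as the relative gap to the pair mean, which is
  symmetric and avoids choosing a reference bin;
* `|gc1 − gc2| ≤ 0.02`;
* their species-rank lineage entries are identical and non-empty.

Compatibility is closed transitively (single linkage). This is the only
order-independent closure: bin groups, not just pairs, are merged, and
the test suite verifies that permuting the input order yields the
identical partition. A merged bin unions the contigs, recomputes GC from
sequence, and takes length-weighted means of depth, completeness and
contamination, flagged `merged`. Length-weighted quality recombination
is an approximation — a marker-gene re-estimate of the merged bin is the
external tool's job — and is the package's documented stand-in. Depth
tolerance is evaluated on the raw per-bin depths, not re-normalized
ones.

**Quality.** `QS = completeness − 5 × contamination`. Tiers: *high*
(completeness ≥ 90, contamination < 5), *medium* (≥ 70, < 5, and
QS ≥ 60), *low* (≥ 50), *fail* otherwise. The QS threshold for
dereplication eligibility defaults to **≥ 60** (inclusive) and is a
configuration parameter; the inclusive reading matches how realized
catalogs are reported. Bins must exceed 200 kbp to stay in the catalog;
low-tier bins stay in the catalog but are never species
representatives.

## Dereplication at 95% ANI

No MinHash/Mash engine exists in the R dependency stack used here, so
the sketch engine is implemented in the package:

* canonical k-mers (k = 21 by default, k ≤ 26) are 2-bit packed into
  doubles — at k ≤ 26 every value stays below 2^52 and is exact in IEEE
  double arithmetic;
* the hash splits the packed value into three 21-bit limbs and mixes
  them with a two-round modular linear map whose intermediate products
  stay below 2^53, so sketches are bit-reproducible across platforms;
* the sketch keeps the `sketch_size` (default 5,000) smallest distinct
  hashes; the Jaccard index is estimated on the bottom-s sketch of the
  union, and ANI follows the Mash formula
  `ANI = 100·(1 + ln(2j/(1+j))/k)`, clamped to [0, 100].

Clustering is greedy in decreasing-QS order (ties: longer genome, then
lexicographic id): each MAG joins the first cluster whose founder
exceeds the ANI threshold, else founds a cluster. The founder is the
representative by construction; `select_representative()` re-derives it
with the same tie-breaks. Greedy representative-first clustering is
deterministic and mirrors common dereplication practice; average-linkage
alternatives would require the full pairwise matrix.

Accuracy expectations, verified in the tests: for substitution-only
pairs at divergence d ≤ 5%, the Mash estimate deviates from true
identity by about `100·(d²/2)` (from `ln(1−d) ≈ −d − d²/2`), well
under half an ANI point, plus sketch sampling noise of order
`100/(k·sqrt(s))`. The test suite checks agreement within ±1 ANI point
against exact alignment identity on 10 kb pairs, and exact recovery of 8
planted species from 30 genomes (within-species divergence ≤ 2%,
between-species far beyond 10%) across 5 seeds.

## Abundance profiles

Species abundance is **depth-normalized**, not raw counts: counts scale
with genome length, and dividing by genome length (via the depth
formula) removes that bias before row-normalizing to relative
abundance. Taxon roll-ups sum member species, so mass is conserved at
every rank; a feature is "present" iff abundance exceeds a configurable
floor (default 0). Shannon (`−Σ p ln p`) and Simpson (`1 − Σ p²`)
indices are computed via vegan. Sample-based rarefaction draws, for each
subset size, 30 independent random sample subsets and reports the
median and quartiles of the union richness; the independent-draws
protocol is used rather than an accumulation-curve permutation so the
quartiles at each size are exchangeable across sizes.

## Function profiles

KO assignment is best-hit with *strict* thresholds: e-value < 1e-10 and
coverage > 0.5; ties by higher coverage, then lexicographic KO. Gene
abundance is the species' relative abundance times the gene's copy
number in the species representative — the simplest model consistent
with summing gene abundances into category abundances when genes are
single-copy; per-gene read mapping is deliberately not modeled.
Category (KO, module, pathway) abundances sum member genes
independently, so overlapping categories double-count shared KOs by
design, and the matrix is not renormalized. Species contributions to a
category divide each species' summed gene abundance by the category
total; over all species they sum to exactly 1 per sample, and reported
subsets may sum to less.

## Community statistics

Bray-Curtis, PERMANOVA (`adonis2`, one factor, p = (1 + #{F* ≥ F}) /
(1 + n_perm)) and the Mantel test are delegated to vegan; PCoA is
classical MDS (`cmdscale` on the double-centered Gower matrix), with
negative eigenvalues reported and excluded from the percent-variance
denominator by default (a documented option includes their absolute
values). Covariate-adjusted multi-factor PERMANOVA is out of scope; one
factor at a time.

Differential abundance per feature: two-sided Wilcoxon rank-sum — exact
when both groups have ≤ 25 samples and no ties, normal approximation
with continuity and tie correction otherwise — with Benjamini-Hochberg
q-values over the tested set (plain BH via `p.adjust`; a brute-force
implementation from the definition serves as the oracle in the tests).
Log2 fold changes of group means use a pseudocount of half the smallest
positive value in the matrix, so zero means are defined without
distorting the scale. Species-level calls conventionally use raw
p < 0.05 and family/KO/module-level calls q < 0.05; both are exposed as
configuration (`use_q`). Constant features get p = 1 and a flag.

## Classifier

A 1,000-tree random forest produces out-of-bag vote scores: each
sample's score is the fraction of case votes among trees where it was
out-of-bag, so the ROC is honest without a separate validation split.
Trees are grown on **balanced per-class subsamples** (0.632 × the
smaller class, without replacement). With plain bootstrap bags, the
trees for which a sample is out-of-bag have bags slightly depleted of
that sample's class; their votes lean toward the other class, and the
null out-of-bag AUC is biased below 0.5. Balanced subsampling removes
the skew — the test suite verifies a mean null AUC within [0.45, 0.55]
over 100 permuted-label simulations, and strong AUC on a cohort-scale
planted design (40 vs 37 samples, 400 features, 40 planted ±1.5 log2
effects). AUC is the trapezoidal ROC area (equal to the normalized
Mann-Whitney U with half-credit ties) with a DeLong 95% CI, via pROC.

## Synthetic communities: what they emulate, and what not

* **Genomes** are i.i.d. base draws at a target GC; related genomes are
  derived by i.i.d. substitutions at a per-site rate, so parent-child
  ANI is analytically `≈ 100·(1 − divergence)`. Substitutions only, no
  indels: dereplication needs controlled similarity around the 95%
  threshold, and the substitution-only model keeps the ground truth
  exact and alignment-free to verify.
* **Bins** are random contig tilings (contigs ≥ 2 kbp) with a retained
  subset hitting a target completeness and contaminant contigs drawn
  from *other* species of the same community — mirroring real
  cross-binning contamination. Targets are met within ~2 percentage
  points when the genome is much longer than one contig.
* **Counts** are multinomial with probability ∝ abundance × genome
  length, emulating fixed-depth mapping; per-sample noise is log-normal
  (`2^N(0, σ)` per species) with group effects applied on the log2
  scale, so planted fold changes are directly interpretable.
* **Gene catalogs** attach one true KO per gene, hits on both sides of
  the e-value/coverage filter (a configurable fraction fails it), and
  overlapping module/pathway maps; planted KOs can be made exclusive to
  chosen species to propagate group effects into function space.

Not emulated: read-level errors and FASTQ simulation, multi-mapping
reads, indels and rearrangements, strain mixtures within a species, and
real marker-gene quality estimation. Passing tests therefore demonstrate
the correctness and calibration of the chain's logic under its own
generative assumptions — not performance on real sequencing data.

## Study conditions and problem sizes

Defaults encode a two-group cohort of 40 cases and 37 controls with
log2-scale noise σ = 1 — a spread typical of log-normal microbiome
abundance models — and planted effects of ±1.5 log2 where a planted
design is requested. Sequence-level stages run on genomes of tens to
hundreds of kilobases (the pipeline default is 300 kb so the >200 kbp
size filter stays meaningful), while count simulation uses Mb-scale
genome lengths as metadata; these sizes were chosen once as desk-scale
stand-ins for Mb-scale genomes — the chain's logic is length-invariant,
which the ANI and completeness oracles verify at the smaller sizes.
Statistical checks use 500 null simulations (PERMANOVA type-I), 100
simulations (power, classifier null) and 20 replicates (planted-design
AUC).

## Numerical choices and degenerate inputs

* GC computation excludes ambiguous bases from the denominator; k-mers
  touching an ambiguous base are dropped from sketches.
* `estimate_ani` returns 0 when the sketch Jaccard is 0 (the Mash
  formula diverges to −∞) and exactly 100 for identical sketches.
* All-zero samples are an error in `relative_abundance` (named in the
  message); samples with zero category abundance get contribution 0
  and are flagged rather than divided by.
* Tie-breaks are total and documented everywhere a ranking matters
  (representative selection, KO best hit, feature importance), so
  results are permutation-invariant.
* Every stochastic function takes an explicit seed, and the pipeline
  derives per-stage seeds from one master seed; equal seeds give
  byte-identical outputs (verified by md5 in the tests).
* Pipeline outputs carry a `# stage=… params=…` header; stages are
  cached on output existence and input mtimes/hashes, with `--force`
  overriding.

## Known limitations

* Length-weighted merged-bin quality can misestimate the union of
  disjoint genome halves; real pipelines re-run marker-gene estimation.
* The Mash-formula ANI saturates for highly incomplete bins (sketch
  overlap shrinks with completeness), which is why only high/medium-tier
  bins enter dereplication.
* Gene abundance by MAG-abundance propagation ignores per-gene coverage
  variation within a genome.
* The classifier reports discrimination (AUC), not calibration, and no
  hyperparameter search is attempted.
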