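---
title: "spliceDyn: models and methods"
author: "spliceDyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spliceDyn: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`spliceDyn` analyses exon-level RNA-seq counts over a cellular
differentiation time course observed in several donor cohorts. This
vignette is the package's own account of the statistics it implements, the
choices made where the design was genuinely open, and what the simulation
framework does and does not establish.

## The study design

The default design (`studyDesign()`) is three cohorts (lean, obese,
obese with type-2 diabetes) observed at three differentiation time points
(confluence, day 3, day 15), with three subjects per cohort and two
technical sequencing runs per subject-by-time-point library. Runs are
repeated sequencing of one library: they share all biology and differ only
in library size and sampling noise, so they are kept as separate columns
and the run enters all models as a fixed-effect covariate rather than
being summed away. Analyses compare consecutive time points (confluence
vs day 3; day 3 vs day 15) within each cohort.

## Differential exon usage

Usage of exon $i$ in a gene is its share of the gene's transcripts,
irrespective of the gene's overall expression. We reduce each exon to a
two-bin count pair per sample — the exon's count and the summed count of
the gene's other exons — and fit a negative-binomial GLM with log link:

$$
\log \mu = \text{sample} + \beta_{\text{bin}}
  + \beta_{\text{bin:run}} + \beta_{\text{bin:condition}}
$$

where `bin` indicates this-exon (vs rest-of-gene). The per-sample factor
absorbs library size, the gene's expression level and any subject effect,
so $\beta_{\text{bin:condition}}$ is exactly the change in the exon's log
usage odds $\log(\mu_{\text{exon}}/\mu_{\text{rest}})$ between the two
time points, adjusted for a run-specific usage term. The interaction is
tested by likelihood ratio (1 df); usage coefficients per time point come
from the same two-bin model fitted jointly over all three time points.
This captures the estimand of exon-level tools built on generalized
linear models of exon bins at a fraction of their complexity; the full
per-gene joint model and empirical-Bayes dispersion machinery of those
tools are deliberately not replicated.

**Dispersion.** With three subjects per group, per-exon maximum-likelihood
dispersions are unusable. We use a method-of-moments estimate pooled over
both bins and all condition-by-run replicate groups, shrink it 50/50
toward the mean of its mean-count bin (up to 10 equal-count bins), and
floor it at $10^{-4}$. The 50/50 weight is a pragmatic stabilizer for
$n = 3$ designs; the package's calibration tests (fraction of null
p-values below 0.05, uniformity of the null p-value distribution) are the
evidence that the plug-in likelihood-ratio test is close to nominal under
the simulator's conditions.

**Multiplicity.** Benjamini–Hochberg step-up correction is applied across
all testable exons of one comparison; q < 0.05 calls an exon
differentially spliced. Testability (`filterTestable()`) requires a
summed count of at least 10 (a standard low-count prefilter; the value is
a declared default, not an inference) and at least two such exons in the
gene — a single-exon gene has no "rest" to compare against.

**The estimand couples exons within a gene.** Because usage is measured
against the rest of the gene, a genuine shift in one exon necessarily
shifts the usage odds of its sibling exons (their denominator contains
the shifted exon). This is a property of the this-vs-rest formulation,
not of the implementation. The simulator therefore records, alongside
the planted effects, the exact induced log2 odds change of every exon in
an affected gene (`truth$inducedUsage`). Recovery is scored accordingly:
sensitivity on the planted exons, precision against the full set of truly
shifted exons — i.e. precision measures contamination of the call set by
truly null exons, which is what FDR control promises. Scoring precision
against planted exons alone would penalise the test for correctly
detecting real (induced) usage changes.

## Differential gene expression

Exon counts are summed to genes and each gene is fitted with a
negative-binomial GLM `count ~ condition + run` with a log
median-of-ratios size-factor offset, the same dispersion scheme, and a
Wald test on the condition coefficient. A gene is called differentially
expressed when q < 0.05 **and** its fold change is at least 1.25; the
dual rule means a precisely measured 10% change is deliberately not
reported as a discovery.

## Pairwise sharing

For two analyses, the denominator is the set of features significant
(q < 0.05) in at least one of them; a feature is shared when its two
effects have the same sign and are within a factor of 0.5 of each other,
boundary inclusive: $0.5\max(|a|,|b|) \le \min(|a|,|b|)$. An effect of
exactly zero shares sign with nothing. Splicing–splicing sharing is
computed at the exon level; expression–expression at the gene level; and
splicing–expression after aggregating splicing to the gene level by each
gene's most significant exon (minimum p, ties broken by the
lexicographically smallest exon id).

Sharing is computed on the *estimated* effects. The empirical-Bayes
multivariate shrinkage model sometimes used to compute such sharing
(learning effect covariance across analyses and shrinking estimates
toward it before applying the same criterion) is intentionally not
reproduced; posterior-based sharing values would differ, generally
upward. The "significant in at least one" denominator follows the
convention of that method's sharing utility; this choice, and the
inclusive boundary, are declared here because reasonable alternatives
exist.

## Trajectory clustering

For each cohort, all exons differentially spliced in either consecutive
comparison are clustered on their usage-coefficient trajectories over the
three time points. Each trajectory is centered and scaled to sample
standard deviation 1 (n − 1 denominator) so that shapes, not magnitudes,
are compared; constant trajectories carry no shape and are dropped with a
warning. Fuzzy c-means then minimises
$\sum_{ij} u_{ij}^m \lVert x_i - c_j \rVert^2$ by alternating updates,
with k = 6 clusters and fuzzifier m = 2 (the conventional default of the
established R implementation; the near-crisp limit m → 1 recovers
k-means, which the tests verify at m = 1.05 against `stats::kmeans`).
Numerical choices: k-means++-style seeding from the data, 5 restarts
keeping the best final objective (c-means is sensitive to initialisation),
convergence when the objective changes by less than $10^{-9}$, at most
1000 iterations, squared Euclidean distance on the 3-dimensional
standardized trajectories, a point exactly coinciding with a centroid
gets membership 1 there, and argmax ties in hard assignment break to the
lowest cluster index. Cluster labels are arbitrary per cohort; shapes are
compared across cohorts by greedy minimal-Euclidean-distance centroid
matching, with pairs beyond a distance threshold reported as
cohort-specific.

## GWAS SNP enrichment in flanking introns

For each exon, the flanking introns are the gaps to its neighbouring
exons within the gene model (terminal exons have one flank; single-exon
genes none; coordinates are strandless). The statistic is the number of
distinct flanking introns of the differentially spliced exons containing
at least one SNP — an intron with five SNPs counts once, and introns are
deduplicated only when their coordinates are identical (an intron shared
by two adjacent differentially spliced exons counts once). The null is
built from 1000 control sets of the same number of exons sampled without
replacement from all tested exons (independently across sets; plain
uniform sampling — no length or expression matching, as declared). With
the empirical percentile defined as the fraction of null counts strictly
below the observed count, a set is called enriched when the observed
count exceeds more than 95% of the null and depleted when more than 95%
of the null exceeds it; ties count against both calls, so the degenerate
case where the test set equals the tested set (all null counts tie the
observed) is "ns", and both calls are conservative on discrete null
distributions. Coordinates of SNPs and models must share one assembly;
no coordinate conversion is performed.

One behaviour worth knowing: differentially spliced exons cluster within
genes (see the estimand coupling above), so a DS set covers fewer
*distinct* introns than a size-matched random set of exons. When SNP
density is so high that most introns contain a SNP regardless, this
clustering alone pushes the observed count below the null — a depletion
signal that reflects set geometry, not biology. At realistic SNP
densities (the demo uses one SNP per several kilobases) the effect is
negligible, but the test should not be run on near-saturating SNP sets.

## The synthetic-data generator

`simulateGeneModels()` lays out non-overlapping multi-exon genes
(defaults: 2–8 exons of 50–300 bp, introns 200–2000 bp, roughly 100
genes per synthetic chromosome so interval code is exercised across
chromosomes). `simulateCounts()` draws negative-binomial counts
(default dispersion 0.05, typical of well-controlled in vitro
differentiation series) around means that factor into a gene expression
level (log-normal across genes, sd 1; log-normal subject noise, sd 0.1)
and within-gene exon usage proportions (softmax over log-normal exon
weights, sd 0.75), so expression and usage are independently
controllable. Planted usage shifts move one exon's log weight by the
stated log2 effect from the later time point of a comparison onward
(cumulatively, as in a real time course), which changes that exon's
usage odds by exactly the planted amount; planted expression effects
scale the gene mean likewise. Defaults plant shifts on 10% of eligible
exons per cohort and comparison at |log2| = 1.5, half of them shared
identically across cohorts, and expression changes on 10% of genes at
|log2| = 1; sequencing depth defaults to 5e6 expected exonic counts per
run (a configuration parameter — the depth of the emulated experiments is
not publicly recorded), with run library factors (1, 0.8). Technical
runs are independent NB draws around the shared subject-by-time-point
mean times the run factor. `simulateSnps()` places background SNPs
uniformly over the simulated genome and spiked SNPs uniformly within
chosen introns, with exact counts and unique positions.

What the generator does **not** emulate: read-level artifacts (mapping
bias, positional coverage), isoform structure (effects are planted on
exon proportions directly, not through transcript abundances), correlated
usage changes along a gene, subject-level usage variability (biological
noise enters through the NB dispersion and a gene-level subject effect),
linkage disequilibrium among SNPs, and sequence content of any kind.
Passing tests therefore demonstrate that the statistics do what they
claim under a faithful NB model of the design — not that they are robust
to alignment artifacts or to biological structure the generator omits.

## Problem sizes used by the test-suite

The statistical properties are checked at sizes chosen to make the checks
sharp but routine to run: DEU calibration and recovery on 200 genes × 4
exons with 10 replicate simulations at depth 5e6; sharing against a
brute-force oracle on 100 instances of 1000 features; clustering recovery
on 600 trajectories from 6 template shapes at noise sd 0.3; enrichment
calibration on 200 simulated datasets (150 genes, 3000 SNPs, 1000
permutations) and power on 50 datasets with 10-fold spiked flank density;
the end-to-end demo on 50 genes. `scripts/acceptance.R` recomputes the
same kinds of quantities (at 5 replicates for the GLM-heavy steps) from a
single command-line seed.

## Known limitations

* The DEU model fits each exon separately; information is not pooled
  across a gene's exons beyond the rest-of-gene sum, and p-values for
  exons of the same gene are not independent (they share the rest
  counts). BH correction is applied marginally, as is standard.
* The plug-in dispersion makes the LRT approximate; calibration is
  verified empirically under the simulator, not guaranteed analytically.
* Sharing on estimated effects understates the sharing a shrinkage-based
  analysis would report, particularly for noisy effects.
* Control sets for enrichment are matched on count only; exon length or
  expression matching, LD pruning and colocalization are out of scope.
* All coordinates are assumed on one assembly throughout.
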