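---
title: "Reference-free copy-number scaling by normality search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free copy-number scaling by normality search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsa)
```

## The problem

SNP arrays report, for every SNP probe $j$ and sample $i$, two summarized
signals $\theta^A_{j,i}$ and $\theta^B_{j,i}$ that are approximately
proportional to the copy numbers of the two alleles — with a
proportionality constant that is unknown and different for every probe.
Turning signals into DNA copy numbers therefore requires a per-probe
reference. When an experiment contains control (normal) samples the
reference is easy: two copies divided by a robust average of the controls'
total signal. Many tumor studies have no usable controls, and the common
fallback — the median over all tumor samples — silently assumes that most
samples are copy-number neutral at every locus. That assumption breaks
exactly where it matters: at recurrent aberrations, where the biased
reference flattens real copy-number changes and can even fabricate
aberrations of the opposite sign in the unaffected samples.

This package implements a normality-search approach: it finds, within each
tumor sample separately, the genomic regions that look copy-number neutral
and free of loss of heterozygosity (LOH), and builds the references from
those regions only. No control samples, genotype calls, or batch
annotations are required.

## Detecting normal regions

The *level of heterozygosity* of a SNP,
$$ LH_{j,i} \;=\; \frac{2\,\min(\theta^A_{j,i},\,\theta^B_{j,i})}
                        {\theta^A_{j,i}+\theta^B_{j,i}}
   \;=\; 2\,\min(\beta_{j,i},\,1-\beta_{j,i}), $$
with $\beta$ the B-allele fraction, lies in $[0,1]$: it is 1 when both
allele signals are balanced and 0 when one of them vanishes. If the
signals were exactly proportional to allele copies, a genotype with $n_A$
and $n_B$ copies would give $LH = 2\min(n_A,n_B)/(n_A+n_B)$: 1 for a
normal heterozygote, $2/3$ for the heterozygote of a one-copy gain, $1/2$
at four copies, and 0 for every homozygote or LOH genotype. Balanced
two-copy gains (two extra copies, one per allele) also give 1, but they
are rare in tumors because simultaneous aberration of both homologous
chromosomes is unlikely — this is the method's load-bearing biological
assumption.

The hardest aberration to separate from normal is the one-copy gain
(expected $LH = 2/3$, pushed *upwards* by normal-cell contamination), so
the default call threshold is the midpoint between $1$ and $2/3$:
`default_lh_threshold()` returns $5/6$, derived from `expected_lh()`
rather than hard-coded. SNPs with $LH$ strictly above the threshold are
called HNCN (heterozygous, neutral copy number); everything else,
including probes with both signals zero, is not.

The binary HNCN track of each sample and chromosome is then segmented
with a circular binary segmentation (CBS) variant for binary data. In a
normal region the fraction of HNCN calls approaches the population
heterozygosity — about 27% of SNPs per sample in HapMap-like cohorts —
while any aberration (gain, deletion, or copy-neutral LOH) pushes it
toward 0. Segments with an HNCN proportion of at least
`default_proportion_threshold()` $= 0.27/2 = 0.135$ (ties count as
normal) are labeled normal. Non-polymorphic CN probes do not participate
in segmentation; they inherit the label of the SNP-defined segment
containing their position, or the nearest segment when they fall outside
SNP coverage.

### The segmentation test

For a stretch of $n$ informative markers with $s$ HNCN calls, every
circular arc — equivalently every breakpoint pair — is scored with the
standardized difference in proportions between the arc (length $l$, sum
$X$) and its complement:
$$ Z \;=\; \frac{|X - l s/n|}{\sqrt{\hat p(1-\hat p)\, l (n-l)/n}},
   \qquad \hat p = s/n. $$
The maximizing arc is accepted when its permutation p-value (over seeded
label permutations of the stretch) falls below `alpha`, and the procedure
recurses into the resulting pieces. Defaults are `alpha = 0.01`,
`n_perm = 1000`, `min_width = 5`, values in line with common CBS practice;
the permutation stream is deterministic given `seed`.

Numerical and design choices worth knowing:

* The maximal statistic (observed and under permutation) is taken over
  arcs of length $l \in [\mathrm{min\_width},\, n-\mathrm{min\_width}]$
  at *any* start, so the permutation null is exactly the distribution of
  the observed maximum. The *applied* split is the best arc whose
  resulting pieces are each empty or at least `min_width` markers wide;
  ties are broken by smallest arc start, then smallest length, making
  results reproducible bit for bit.
* Permutation scans exploit a property of binary data — the maximal and
  minimal window sums are nondecreasing in the window length, with
  increments of at most one — to jump over window lengths at which no
  exceedance is arithmetically possible. This prunes almost the entire
  scan when the observed statistic is large and makes permutation CBS
  practical at $10^3$–$10^4$ markers per chromosome. Permutations also
  stop early once the exceedance count proves the p-value is at least
  `alpha`.
* Markers with missing $LH$ (both signals zero) are excluded from the
  statistic but stay inside segments for coverage accounting.
* Segmentation is per chromosome, not per arm; no post-hoc merging is
  done, since the downstream 13.5% labeling rule is insensitive to
  oversegmentation.
* An exhaustive $O(n^2)$ single-split scan
  (`best_single_split_oracle()`) ships with the package purely as an
  independent reference: at `min_width = 1` the segmentation core must
  reproduce its chosen split exactly, and the test suite checks this on
  short random stretches.

## Scaling to copy numbers

With the probe-by-sample normal mask $I(\cdot)$ in hand, scaling proceeds
in two median steps applied to the total signal
$\theta^{(1)}_{j,i} = \theta^A_{j,i}+\theta^B_{j,i}$ (CN probes contribute
their single total signal):

1. per-SNP reference over the samples normal at $j$:
   $\mathrm{Ref}^{SNP}_j = \mathrm{median}_{i \in I(j)}\,\theta^{(1)}_{j,i}$;
2. $\theta^{(2)}_{j,i} = 2\,\theta^{(1)}_{j,i}/\mathrm{Ref}^{SNP}_j$;
3. per-sample reference over the probes normal in $i$:
   $\mathrm{Ref}^{sample}_i = \mathrm{median}_{j \in I(i)}\,\theta^{(2)}_{j,i}$;
4. $\theta^{(3)}_{j,i} = 2\,\theta^{(2)}_{j,i}/\mathrm{Ref}^{sample}_i$.

After step 4 the median of every sample's normal probes is exactly 2, and
the construction is invariant — to floating-point precision — to global
rescaling of all signals and to rescaling any single probe's signals,
which is precisely why the unknown per-probe proportionality constants
drop out. Medians use the standard convention (mean of the two central
order statistics for even counts).

Degenerate cases fall back rather than fail: a probe with no normal
sample uses the all-sample median (the very estimator whose bias the
method exists to avoid) and is flagged so such loci can be dropped; a
sample with no normal probe uses its all-probe median, also flagged.

The four steps can be iterated (`n_iter`), re-deriving both references
from the previous copy numbers with the mask held fixed; iterating only
the scaling (and not the mask) matches the reading that the four-step
scaling, not the region search, is what repeats. In practice the first
iteration is essentially the fixed point: on the convergence simulation
below the mean absolute change in the second iteration is far below 0.001
copies, so the default is `n_iter = 1`.

## Batch-effect removal

Samples hybridized together share multiplicative per-probe effects. The
batch-aware mode (`ber = TRUE`) replaces the plain median reference with a
per-sample weighted median. A set $S$ of SNPs (default size 10,000) is
chosen to be normal in as many samples as possible, ranked by the count
of normal samples with seeded random tie-breaking. Signals outside the
normal mask are filled with the plain reference, and for each sample $i$
nonnegative weights $\gamma_{i,k}$ ($\gamma_{i,i}=0$) minimize
$$ \bigl\lVert \log\hat\theta_{\cdot,i}
   - \textstyle\sum_{k\neq i}\gamma_{i,k}\log\hat\theta_{\cdot,k}
   \bigr\rVert_2 . $$
The solver iterates ordinary least squares, dropping every sample whose
coefficient is negative — the intuition being that a sample too unlike
sample $i$ should be excluded rather than given a counter-intuitive
negative weight. On its own, that drop-only scheme can stall at a
non-optimal fixed point, so after it converges the solver checks the
nonnegative-least-squares stationarity condition and re-admits any
dropped sample whose column still correlates positively with the
residual. The returned weights attain the exact constrained optimum: the
test suite verifies the objective against an independent
quadratic-programming solver (`pracma::lsqnonneg`) to $10^{-6}$ relative
on random instances.

The weighted reference is then
$\mathrm{Ref}^{SNP}_{j,i} =
 \mathrm{wmedian}_{k \in I(j)}(\theta^{(1)}_{j,k};\,\gamma_{i,k})$,
using the weighted median (the minimizer of
$\sum_k w_k\lvert x_k-m\rvert$) for robustness. Its tie rule — when the
half-weight point falls exactly between two order statistics, return
their midpoint — makes equal weights reproduce the ordinary median, so
the weighted reference is a strict generalization of the plain one, and
the overall scale of a weight row cancels identically. Constraints are
enforced as $\gamma \ge 0$: the removal step produces exact zeros, so a
strict inequality would be vacuous.

## The synthetic-data generator

Because real array experiments cannot ship with the package, every claim
is exercised on synthetic data with full ground truth
(`simulate_dataset()`). The generator emulates:

* **Genotypes.** Per-SNP minor-allele frequencies from a Beta(0.6, 1.6)
  prior and Hardy–Weinberg genotypes. The Beta parameters were chosen
  once so that the expected heterozygosity $2(E[p]-E[p^2]) = 0.2727$
  matches the ~27% heterozygous SNPs per sample of HapMap-like cohorts;
  they are a derived calibration, not an external measurement.
* **Aberrations.** Piecewise-constant allele-copy profiles: one-allele
  deletions, gains, copy-neutral LOH, homozygous deletions, and
  two-copy amplifications, each with a genome fraction, a recurrence
  fraction (exactly $\lfloor r \cdot I\rfloor$ samples affected), and
  either per-sample random or shared fixed locations. The default
  landscape — two deletions, a gain and an LOH event totalling ~20% of
  the genome per sample, randomly placed — represents a moderately
  rearranged tumor in which every locus keeps a majority of normal
  samples.
* **Signals.** $\theta = \varphi_j\, b_{batch(i),j}\, c\,
  e^{\varepsilon} + 0.05\,\varphi_j$, with log-normal per-probe constants
  (log-sd 0.3), optional log-normal per-batch-per-probe factors,
  effective copies mixed with the germline by tumor purity, multiplicative
  log-normal noise (default sd 0.05, a clean post-summarization array),
  and a small additive floor proportional to the probe constant. The
  floor stands in for cross-hybridization background: it keeps homozygous
  LH away from exactly zero and keeps logarithms finite for the weight
  estimation. It also means a one-copy deletion renders at about
  $1.05\times$ the ideal signal — visible as the slight upward bias of
  deleted-region copy numbers.

What the generator does **not** emulate: probe-level (pre-summarization)
effects, GC/wave artifacts along the genome, allele-specific
cross-hybridization, sex chromosomes, and polyploid genomes. Passing
tests therefore demonstrate correctness of the algorithm under its own
signal model, not robustness to every artifact of real arrays.

## Study conditions checked by the test suite

The acceptance-level tests run at the following problem sizes, chosen to
exercise each claim at realistic marker density (1,000–2,000 SNPs per
chromosome) while staying desk-scale:

* genotype calibration: 100,000 SNPs, one sample (heterozygosity
  $27\% \pm 1$ percentage point);
* normal-region recovery: 10 samples × 10,000 SNPs; marker-level
  sensitivity and specificity for normal status both $\ge 0.90$;
* scaling recovery: 20 samples × 20,000 SNPs (+1,000 CN probes); mean
  copy number $2 \pm 0.02$ in truly normal entries and $1 \pm 0.1$ in
  single-copy deletions; per-sample normal medians exactly 2; exact
  scale invariances;
* convergence: 50 samples × 50,000 SNPs, noise sd 0.05; mean absolute
  change between scaling iterations 1 and 2 below 0.001 copies;
* recurrent-aberration bias: a fixed-location gain in 70% of 20 samples;
  the all-tumor-median baseline (`scale_baseline(., "mts")`) depresses
  the unaffected samples' region mean below 1.9 copies while the
  normality-search estimate stays within $2 \pm 0.05$, and the
  region-ROC AUC for the jump is at least as high;
* batch weights: 25 random instances against the QP oracle, and 20
  replicates of a 3-batch × 8-sample simulation (batch log-sd 0.1) in
  which mean within-batch weights must exceed between-batch weights in
  at least 95% of replicates.

`scripts/acceptance.R` re-runs the headline quantities (balanced-allele
LH, generator heterozygosity, iteration-two convergence) from scratch
with a caller-supplied seed.

## Known limitations

* A locus aberrated in *every* sample has no normal reference; the
  fallback is the all-sample median, flagged per probe.
* Chromosome arms with no SNP probes (CN probes only) cannot be searched
  for normality; their probes inherit labels from SNP-bearing segments
  or are labeled aberrated with a warning.
* Low tumor purity shrinks all aberrations toward two copies and
  ultimately hides them from both the LH track and the ROC.
* Sex chromosomes in mixed-sex cohorts behave like recurrent deletions;
  the method has no special handling for them, and chromosome names are
  treated as opaque strings throughout.
* The weighted-median batch correction assumes batch effects are
  multiplicative and shared within a batch; it cannot correct effects
  confounded with true copy-number differences.
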