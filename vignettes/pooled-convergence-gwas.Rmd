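---
title: "Convergent clustering analysis of pooled genome-wide association data"
author: "poolConverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convergent clustering analysis of pooled genome-wide association data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(poolConverge))
```

## The problem and the design

Polygenic phenotypes rarely yield single-SNP associations at genome-wide
significance in samples of practical size. An alternative to that
"template" strategy is to look for *convergence*: small chromosomal
regions where several nearby SNPs are nominally significant, in each of
two independently collected case/control samples. Individually, each
nominal signal is unremarkable; jointly, clustered signals recurring
across independent samples are very unlikely under the null, and that
joint improbability is what this package quantifies — empirically,
by resampling, never by asymptotic theory.

The measurement design is DNA pooling: instead of genotyping
individuals, DNA from groups of 20 individuals of the same population
and phenotype is combined into a pool, and each pool is hybridized to
three replicate genotyping arrays. Pooling protects participant
confidentiality (a consideration when the phenotype is an illegal
behavior) and reduces cost, at the price of replacing individual
genotypes with noisy per-pool allele-frequency estimates.

## The allele-frequency proxy and the per-SNP test

Each SNP on each array is summarized by averaging its 3–4 perfect-match
probe intensities per allele and taking

$$ m = \arctan(\bar A / \bar B) \in [0, \pi/2], $$

a bounded, monotone proxy for the pool's A-allele frequency
(`arctanAB()`, `summarizeSnpArray()`). Averaging precedes the
arctangent. SNPs on sex chromosomes (which would otherwise confound
pooled male/female comparisons) and SNPs without reliable positions are
removed (`filterSnps()`).

The three replicate values per pool are averaged, and for every SNP a
two-sided two-sample *t* test compares case pools against control pools
(`snpTTest()`). The pool — not the array, not the individual — is the
experimental unit. We use the Welch (unequal-variance) form: the two
pool groups can be as unbalanced as 35 vs 12, where the equal-variance
pooling is fragile; no claim about which variance convention the
original analyses used is implied. SNPs with p < 0.05 (strict) are
"nominally positive" (`nominalPositives()`); zero-variance SNPs are
flagged degenerate rather than silently passed. The case/control ratio
of mean arctan values is carried as a descriptive column only.

## Clusters and genes

A *cluster* is a maximal chain of positive SNPs in which consecutive
members are at most `maxGap` apart, with at least `minSize` members
(`findClusters()`, `convergenceCriteria()`). We read "within 25 kb of
each other" as consecutive-gap chaining rather than a diameter bound:
chaining yields a unique, deterministic, order-independent partition,
whereas maximal diameter-bounded clusters are not unique. The canonical
criteria grid crosses sizes {3, 4} with gaps {25 kb, 10 kb}; gene sets
nest as criteria tighten, which the tests verify on random data.

A cluster supports a gene when at least `minSize` of its members lie
within the gene's span extended by 10 kb on each side
(`assignClustersToGenes()`). Two open choices are resolved as follows
and exposed as toggles. First, the full gene span is used rather than
exons only: intronic SNPs in linkage disequilibrium with functional
haplotypes would otherwise be discarded, and per-gene supporting-SNP
counts in large genes are only consistent with span-level counting.
Second, the stricter support rule (≥ `minSize` members inside the
flanked interval, not merely any overlap) is the default
(`rule = "anyOverlap"` relaxes it). A cluster straddling two genes'
flanked intervals supports both.

Two convergence strategies are implemented:

* **Converge then cluster** (`convergeThenCluster()`): intersect the
  two samples' nominal positive sets ("reproducibly positive" SNPs),
  cluster the shared SNPs, assign clusters to genes. No agreement in
  the direction of effect is required — with different linkage
  structure in the two populations, the same functional variant can
  show opposite phases at a marker.
* **Cluster then converge** (`clusterThenConverge()`): cluster each
  sample's own positives, and report genes tagged by at least one
  qualifying cluster from *each* sample. This tolerates allelic
  heterogeneity and population differences in tagging: the samples
  need not share a single positive SNP. Every approach-1 gene is an
  approach-2 gene at equal criteria.

```{r toy}
study <- simulateStudy(nSnps = 3000, nGenes = 30, nLoci = 2,
                       effectSize = 0.12, seed = 7)
assocA <- snpTTest(study$panels$A)
assocB <- snpTTest(study$panels$B)
r1 <- convergeThenCluster(assocA, assocB, study$map, study$genes,
                          convergenceCriteria(3, 25000))
r1$geneHits$gene_id
unique(study$truth@loci$gene_id)
```

## Empirical significance

All significance is resampling-based. The conventions:

* An exceedance is a null trial whose statistic **matched or exceeded**
  the observation (ties count).
* Sampled nulls report p = (exceedances + 1) / (trials + 1), so zero
  exceedances in 100,000 trials reports p ≈ 10⁻⁵ rather than 0 — an
  empirical p can bound, never certify, impossibility.
* Exhaustive enumeration (when the permutation space is small) reports
  the exact fraction instead.
* Pseudopositive SNPs are resampled **without replacement from the
  real map**, preserving its spacing structure; no homogeneous-Poisson
  position null is ever used.

Four nulls are provided. `mcOverlapP()` draws two random subsets of
the stated sizes and records their intersection (equivalently, a
hypergeometric draw — the default, with explicit set sampling as a
cross-check). `mcClusterP()` measures how many random pseudopositives
land in qualifying clusters. `mcGeneConvergenceP()` reruns the
cluster-then-converge analysis on independent pseudopositive sets of
the per-sample positive counts (raw counts by default; pass the
clustered counts to match on those instead) and counts convergent
genes; its null mean also gives the expected *true-gene fraction*
(observed − null mean)/observed (`truePositiveFraction()`).
`mcGeneLevelP()` assigns a per-gene p by placing random gene-resident
segments of the same length as the gene's flanked interval, uniformly
over all positions where the segment lies wholly within some flanked
gene. "Displays the same features" is not fully determined for that
last null; the default reads it, for approach 1, as the count of
clustered reproducible SNPs in the segment and, for approach 2, as the
presence of a qualifying cluster of each sample's positives — both
statistics are available via `approach =`.

`permutationP()` permutes case/control labels across pools — the pool
is the only permutable unit once DNA is pooled — independently within
each sample, preserving each sample's case/control pool counts, and
recomputes the full statistic (default: the approach-1
reproducible-SNP count) per trial. The default path is vectorized
(one matrix product per permutation block), so 10,000 permutations of
a 20,000-SNP two-sample study run in minutes.

## What the generator emulates

`simulateStudy()` reproduces the statistical structure the analysis
assumes, with every dimension config-driven and all randomness derived
from one master seed through named substreams:

* **Populations.** Base minor-allele frequencies uniform on
  [0.05, 0.28], assigned to either allele at random; a second
  population differs by a Gaussian shift (SD 0.05), clamped to
  [0.05, 0.95].
* **Pools.** Each pool's allele frequency is a binomial draw of
  2 × 20 chromosomes from its population frequency. Each of 3
  replicate arrays measures arctan(f/(1−f)) plus Gaussian noise with
  SD 0.03·√3, clipped to [0, π/2].
* **Effects.** A planted locus is a run of 6 consecutive SNPs within
  25 kb inside one gene — an idealized LD block whose members shift
  together by the effect size (0.05–0.10 on the frequency scale,
  toward 0.5 so frequencies stay in range). The same loci carry the
  effect in both populations; `tagging = "disjoint"` makes alternating
  members carry it in each population, the situation approach 2 is
  designed for.

The two noise scales are the calibration anchors: the replicate SD of
0.03·√3 makes the SEM of a 3-replicate pool mean 0.03, and the
frequency range [0.05, 0.28] was chosen once, by numerical integration
of the binomial-composition variance through the arctan transform, so
that the across-pool SEM of 20-pool groups is 0.02. `qcReport()`
recovers both from simulated panels to within 5% at 10,000 SNPs. QC
SEMs are root-mean-square over SNPs of the per-SNP variance (then
divided by √n): the RMS form is unbiased for σ/√n, whereas averaging
per-SNP standard deviations would be biased low by the small-sample
factor c₄(3) ≈ 0.89.

What the generator deliberately does **not** model: probe-level
hybridization physics (the measure is arctan(f/(1−f)) of the pool
frequency, a monotone stand-in for arctan(A/B) under proportional
hybridization), real linkage disequilibrium (blocks share effects
perfectly instead of decaying with distance), allele-frequency spectra
beyond a uniform band, and genotyping error. Passing tests therefore
certify the pipeline's statistical behavior under its own assumptions,
not performance on real hybridization data.

`simulateValidationDesign()` mirrors the pooled-vs-individual
validation: individuals with known simulated genotypes assigned to
pools of 2, 5 and 15 (81 individuals), with the correlation between
realized pooled frequencies and the noisy arctan measure summarized
over SNPs whose expected frequencies spread by ≥ 10% across pools
(`validationCorrelation()`, computed on the arctan scale so that a
noise-free design gives exactly 1).

## Numerical and scale choices

* Coordinates are 1-based inclusive; BED input is converted on read.
  Flanked intervals are clipped at position 1.
* Default simulated dimensions follow the study conditions where
  stated: pools of 20 individuals, 3 replicates, pool designs 20+14
  and 35+12. Desk-scale SNP counts (20,000–50,000 at ~3 kb spacing,
  the density of a ~1M-SNP array genome) stand in for the full 870,000;
  all counts scale linearly.
* Variances below 10⁻¹⁴ are treated as exactly zero when flagging
  degenerate SNPs, absorbing double-precision rounding.
* `tTestPower()` computes noncentral-t power with Welch–Satterthwaite
  degrees of freedom at equal group variances, so its predictions match
  the Welch test the pipeline runs (and coincide with the classical
  pooled-df calculation when groups are balanced). The σ behind the
  study's printed power values is not recoverable from its printed
  SEMs under any single convention we tried, so printed powers are
  context, not targets; the function is validated against simulation
  instead.
* Monte Carlo agreement checks use the binomial standard error
  √(p(1−p)/n); cross-checks are asserted within 3 such SEs.

## Limitations

Distance is the only proximity notion — no reference-panel LD, no
recombination map. The per-SNP test treats pools as exchangeable units
and ignores the binomial dependence of variance on allele frequency
(the t test absorbs it per SNP, but power varies across the frequency
band). Permutation is only possible at the pool level, which limits
the permutation space for small designs; the implementation enumerates
exactly when that space is smaller than the requested trials. Gene
assignment depends on the annotation supplied; unannotated regions are
invisible to the gene-level outputs even when clusters are found
there.
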