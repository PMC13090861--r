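---
title: "Quantifying subclonal heterogeneity and genomic burden in tumor exomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying subclonal heterogeneity and genomic burden in tumor exomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonith)
```

## Scope and model

clonith computes sample-level genomic statistics for whole-exome tumor
cohorts and compares them across groups. It deliberately starts *after*
the heavy upstream machinery: variant callers, CNV/purity callers and
Bayesian clonal-inference tools produce its inputs, and survival modeling,
recurrence analysis and signature extraction sit downstream and elsewhere.
What remains — retention filtering, burden metrics, the heterogeneity
score, and the group tests — is small enough to be fully specified and
property-tested, which is the point of this package.

### Cellular prevalence from allele frequency

For a mutation carried at multiplicity $m$ in tumor cells of local total
copy number $C$, in a sample of purity $\rho$, the expected variant allele
frequency is

$$\mathrm{VAF} = \frac{\rho \cdot \mathrm{CP} \cdot m}
                      {\rho C + 2(1-\rho)},$$

where CP is the fraction of tumor cells carrying the mutation.
`vaf_to_cp()` inverts this, clipping to $[0,1]$. The package defaults to
$C = 2$, $m = 1$ (a heterozygous mutation in a diploid region): in
exome-scale practice, per-site multiplicities are rarely known, and the
heterozygous-diploid assumption is the common operating point of
clonal-inference tools. Both parameters are arguments everywhere they
enter, so sensitivity analyses are one keyword away. The main consequence
of the assumption is that CP estimates in amplified or deleted regions are
biased; see Limitations.

### Subclone clusters

Cluster assignments can be **ingested** from a loci table written by an
external clonal-inference tool (the fidelity path: `cluster_id` column
present), or computed by the **built-in** stand-in, `builtin_cluster()`.
The stand-in is a one-dimensional binomial mixture: locus $i$ with depth
$d_i$ and alt count $a_i$ has $a_i \sim \mathrm{Binom}(d_i, \theta_j)$
under component $j$. It is fitted by EM for $k = 1..k_{\max}$ (default
6), and $k$ is chosen by BIC with $2k-1$ free parameters. This is a
deliberate simplification of Dirichlet-process clustering — no prior over
$k$, no MCMC — chosen because it is deterministic, fast at desk scale,
and correctly specified for the package's own generative model, which is
what the recovery tests exercise. It is *not* a reimplementation of any
external tool, and ingestion is preferred when such a tool has been run.

Numerical choices: responsibilities use log-sum-exp; $\theta$ is clamped
to $[10^{-6}, 1-10^{-6}]$; convergence is declared at a log-likelihood
change below $10^{-8}$ (cap 500 iterations). Each $k$ is fitted from a
quantile-spread initialization plus three seeded random restarts, keeping
the whole fit deterministic given `seed`. Components that end up with no
maximum-responsibility members are dropped, so the effective $k$ can be
below the BIC winner's nominal size.

### Two-stage cluster merging

Clonal-inference output tends to scatter singleton clusters around real
subclones. Stage 1 (`merge_stage1()`) therefore pools clusters whose
centroids are close: average-linkage hierarchical clustering of the
$(\overline{\mathrm{CP}}, \overline{\mathrm{VAF}})$ centroids under
Euclidean distance, dendrogram cut at height 0.05. Both coordinates live
on $[0,1]$, so the 0.05 cutoff is commensurate with CP/VAF units. Two
genuinely open choices are exposed as arguments rather than hidden:

* `features`: the centroid space is 2-D (CP and VAF) by default — "similar
  CP and VAF" reads most naturally as both — with a 1-D CP-only variant
  available (`features = "cp"`).
* `scope`: by default any clusters in a cut-group merge (`"all"`);
  `"singletons_only"` restricts merging so multi-member clusters are
  never merged with each other, reading the singleton-noise motivation as
  a restriction instead of an expected consequence.

Stage 2 (`merge_stage2()`) refines by evidence rather than distance: for
every cluster pair, two-sided rank-sum tests compare the member CP values
and, separately, the member VAF values; a pair is mergeable only when
*both* p-values exceed $\alpha = 0.05$ (strict inequality). Merging is
best-pair-first: among mergeable pairs, merge the one with the largest
minimum of its two p-values, recompute means, repeat until no pair
qualifies. Tie-breaks — larger p-value sum, then smaller centroid
distance, then lexicographic labels — make the procedure fully
deterministic. The prose criterion ("merge when neither differs
significantly") does not pin down an order; best-pair-first was fixed here
because it makes the procedure order-independent and idempotent, both of
which are tested (a second pass performs zero merges).

### The heterogeneity score

`shannon_ith()` normalizes mean cluster CPs into proportions
$p_i = \overline{\mathrm{CP}}_i / \sum_j \overline{\mathrm{CP}}_j$ and
scores

$$H' = -\sum_i p_i \ln p_i$$

in nats. $H' = 0$ for one cluster (returned exactly, not as a rounding
artifact) and $H' = \ln k$ for $k$ balanced clusters. Mean CPs are
per-mutation CP values averaged within the cluster. A cluster whose mean
CP is exactly 0 would make $p \ln p$ undefined; such clusters are dropped
with a warning (error if all are zero). Proportions are asserted to sum
to 1 within $10^{-9}$.

### Rank-sum tests

Both the stage-2 merges and the cohort comparisons use the same two-sided
rank-sum engine. When the smaller group has at most 10 observations the
null distribution of the rank sum is enumerated exactly over the observed
midranks by dynamic programming (doubling makes midranks integral), with

$$p = \min\!\big(1,\; 2\min(P(W \le w),\, P(W \ge w))\big).$$

This convention reproduces textbook exact values (e.g. $\{1,2,3\}$ vs
$\{4,5,6\}$ gives $2/\binom{6}{3} = 0.1$) and matches a full
combination-enumeration oracle to $10^{-12}$ in the test suite, ties
included. Above size 10 the continuity-corrected normal approximation
with midranks and tie-corrected variance is used (`stats::wilcox.test`);
the degenerate all-tied case returns $p = 1$ rather than NaN. Cohort
comparisons report raw p-values by default, matching the common practice
of reporting unadjusted pairwise Wilcoxon contrasts; Benjamini–Hochberg
adjustment is available behind `bh = TRUE` in `compare_pairs()`.

## Burden metrics

TMB counts effect classes `nonsilent` *and* `splicing` (variants within
2 bp of a splice site): the nonsilent definition is impact-based and
splice-proximal variants are protein-affecting. The denominator
`exome_size_mb` has **no default** — capture designs differ, and a wrong
silent denominator is worse than a required argument. The class
boundaries are closed on the pediatric-high side (2 and 10 muts/Mb are
both `pediatric_high`; hypermutator requires strictly more than 10),
reading "between 2 and 10" as inclusive, and are asserted at
$\pm 10^{-9}$ in the tests.

CNV burden treats "altered" as total copy number different from
`neutral_copy_number` (default 2; configurable, e.g. for male sex
chromosomes or ploidy-relative definitions). The default
`genome_size_bp`, $2{,}881{,}033{,}286$, is the GRCh37 autosomal total —
a configuration value, never hard-coded in a formula, since whether a
given study's denominator included sex chromosomes is a per-study
decision. Gene-level amp/del calls use fractional overlap of the gene
with the *union* of same-direction altered segments (the 80% rule
concerns how much of the gene is covered, not any single segment);
amplification/deletion copy-number thresholds default to $\ge 3$ /
$\le 1$ and are configurable, as CNV callers' state definitions differ.
Both metrics are verified exactly against a per-basepair brute-force
scan on hundreds of random small instances, along with invariance to
splitting a segment at constant copy number.

Coordinates are 1-based and inclusive throughout (MAF/SEG convention);
the BED reader converts half-open input at the boundary. Chromosome
comparisons strip an optional `chr` prefix, since cohorts routinely mix
`17` and `chr17` dialects.

## What the generator emulates — and what it does not

`simulate_subclonal_tumor()` draws depth from a truncated Poisson
(minimum 1; depth is not modeled upstream, and Poisson is the standard
exome depth stand-in), samples alt counts binomially at the expected VAF
from the CP→VAF mapping, and fills the `cellular_prevalence` column by
inverting that mapping per mutation — the same shape a clonal-inference
tool emits, without pretending to be one. Multiplicity is fixed at 1 and
tumor copy number defaults to 2. The truth object carries the generative
ITH from normalized true CPs, which is what recovery is measured against.

`simulate_segments()` composes altered and neutral spans so the altered
total is exactly `round(altered_fraction * genome_size_bp)` on a single
synthetic chromosome. `simulate_variant_table()` emits rows that pass the
retention filters by construction, plus optionally `spike_failures` rows
that each violate exactly one criterion (cycling depth, VAF, caller
count, flag) so filter behavior can be checked against exact counts.

`simulate_cohort()` draws group metric values i.i.d. from named
distributions. The default disease-status specification
(`ith_status_cohort_spec()`) uses 17 primary, 9 recurrent and 13
metastatic samples — group sizes typical of a fusion-driven sarcoma
cohort — with ITH drawn from Beta distributions rescaled to
$[0, \ln 6]$ (the attainable range for up to six subclones): primary
$\mathrm{Beta}(2, 6)$, metastasis $\mathrm{Beta}(4, 4.5)$, recurrent
$\mathrm{Beta}(5, 4)$. The implied location shifts of roughly 1.4–2
pooled standard deviations represent strongly significant contrasts at
these small group sizes. These defaults were fixed once, from the target
cohort structure, before any downstream measurement.

What the generator does **not** emulate: caller error profiles, FFPE
artifacts, mutational signatures, copy-number-driven VAF distortion,
overdispersed (beta-binomial) read counts, spatial or longitudinal
structure, and inter-metric correlation within a sample. Passing the
recovery tests therefore shows the pipeline is correct *under its own
generative assumptions* — it does not certify performance on real tumors,
where purity error and CNV overlap add bias the model does not see.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale by design:
subclone recovery uses 100 replicate tumors per $k \in \{1..4\}$ (40 in
the script) with 30–60 mutations per subclone at depth 500 and purity
0.6–1.0 and CP separation at least 0.15; calibration uses 1,000 null
cohorts of $n = 200$ per group (600 in the script) and the same count of
1-SD-shift cohorts at $n = 20$; the status-cohort contrast uses 200
replicate cohorts (150 in the script); the exact-test oracle covers
1,000 random pairs of up to 8 members per side. Every stochastic step is
seeded, and each generator reproduces byte-identical output for equal
seeds.

## Known limitations

* CP estimation assumes one multiplicity and one copy number for all
  loci; amplified regions bias CP upward, deletions downward.
* Clipping CP at 1 slightly deflates the mean CP of truly clonal
  clusters (binomial noise has nowhere to go above 1), a small downward
  bias that grows as depth falls.
* The Shannon score summarizes diversity only: it carries no phylogeny,
  under-weights rare subclones, and inherits purity-estimation error.
* The built-in clustering is a stand-in: for real cohorts, ingest the
  output of a dedicated clonal-inference tool and keep the built-in path
  for validation.
* Exact rank-sum enumeration is limited to the smaller group having at
  most 10 members; above that the normal approximation is standard but
  approximate.
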