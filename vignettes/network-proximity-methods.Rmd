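---
title: "Methods: drug-target network proximity for post-infarction remodeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug-target network proximity for post-infarction remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remodnet)
```

remodnet asks a network-medicine question: do the targets of the standard
post-myocardial-infarction drug classes — ACE inhibitors (ACE),
angiotensin-receptor blockers (AGTR1), beta-blockers (ADRB1), and
mineralocorticoid-receptor antagonists (NR3C2) — sit unusually close to a
protein signature of left-ventricular remodeling inside a
confidence-thresholded protein–protein interaction network? The package
implements the full chain from expression data to that answer, and a
synthetic-data generator that plants a known truth under every stage so the
chain is testable without any external download. This vignette records the
models, the tunable parameters, and the design decisions where the
methodology was genuinely open.

## Signature derivation

The disease signature starts from a two-group comparison of log2
intensities (post-MI vs control myocardium in the motivating application).
Samples are quantile-normalized — every column is forced onto the row-wise
mean of the sorted columns — which is the half of the Illumina "neqc"
recipe that is identifiable here; normexp background correction needs
control-probe intensities that the data model does not carry, so it is
deliberately not imitated.

Per gene, the group contrast is the difference of group means (second group
minus first, order taken from the sample sheet) with the pooled residual
variance $s^2_g$ on $d = n_A + n_B - 2$ degrees of freedom. Variances are
shrunk by the standard empirical-Bayes hierarchy

$$s^2_g \mid \sigma^2_g \sim \sigma^2_g \chi^2_d / d, \qquad
  \sigma^2_g \sim s_0^2 \, d_0 / \chi^2_{d_0},$$

whose hyperparameters $(d_0, s_0^2)$ are fit by the method of moments on
$\log s^2_g$ (digamma/trigamma matching, with a Newton inversion of the
trigamma function). When the spread of $\log s^2$ does not exceed what
$\chi^2_d$ sampling noise alone implies, $d_0$ is reported infinite and
every posterior variance collapses to $s_0^2$. The moderated statistic is

$$\tilde t_g = \frac{\hat\beta_g}{\sqrt{\tilde s_g^2 (1/n_A + 1/n_B)}},
  \qquad
  \tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},$$

referred to $t_{d_0 + d}$. At $d_0 = 0$ this is exactly the classical
pooled t-test (a tested identity); at $d_0 = \infty$ it is a z-test at
fixed variance $s_0^2$. P-values are Benjamini–Hochberg adjusted, and the
signature keeps genes with adjusted $p < 0.01$ and $|\log_2 \text{FC}| >
0.25$. Both inequalities are strict, as the thresholds are conventionally
printed; the fold-change scale is read as log2, the microarray convention.
Ties in the output ordering are broken by gene id so files are
reproducible.

Cross-species translation uses reciprocal best hits over scored hit
tables: a pair is accepted only when each member is the other's unique
top-scoring hit in both directions. A query whose top score is tied
between subjects is dropped entirely — determinism is preferred over
recall, since the tie has no principled winner. The subsequent
gene-to-protein step is strictly one-to-one: genes with zero or multiple
protein images, and proteins claimed by several genes, are dropped and
logged. No in-paralog clustering is attempted; the hit tables may come
from any aligner.

## The interaction network

Interaction tables are STRING-style triples (protein1, protein2, combined
score). Both score dialects in circulation are accepted — probabilities in
[0, 1], or 0–1000 integers, auto-detected by any score above 1 and divided
by 1000. The confidence threshold defaults to 0.9 and is inclusive
("minimum score" is read as attainable). Self-interactions are dropped;
symmetric duplicates collapse to the maximum score.

The disease network's node set is the signature plus all drug targets,
*including* members with no retained interaction, kept as degree-0 nodes —
so node counts follow set arithmetic (a 222-protein signature and four
disjoint targets give exactly 226 nodes). Edges are unweighted for all
distance computations; confidence gates edge existence only.

Edge enrichment is judged against a degree-product (Chung–Lu) null: for
the selected node set $S$, the expected edge count is
$\sum_{\{i,j\} \subset S} \min(1, k_i k_j / 2m)$ with degrees and $m$
taken from the full pre-subsetting graph, and the observed count is
referred to a Poisson upper tail $P(X \ge n_\text{obs} \mid \lambda =
E)$, evaluated in log space through the regularized incomplete gamma
function so tails far below $10^{-16}$ are still resolved. Tests validate
the expectation against degree-preserving edge rewiring (within 10%) —
the null is defined and reproducible, which a web platform's unpublished
null is not.

## Proximity and the degree-matched null

The proximity of a target set $T$ to the signature $S$ is the closest set
distance

$$d(T, S) = \frac{1}{|T|} \sum_{t \in T} \min_{s \in S} d(t, s),$$

with a mean-over-all-pairs variant available by option. Unreachable pairs
contribute a penalty of $n_\text{nodes}$ — finite, larger than any real
distance, and flagged — so scores stay ordered and finite.

Raw distances mean little without a reference: a hub is close to
everything. Each score is therefore calibrated against a degree-matched
permutation null: nodes are binned by $\lfloor \log_2 k \rfloor$ (degree-0
nodes in their own bin), bins with fewer than 10 candidates merge upward
(the top bin merges downward), and each permutation redraws a target-sized
set from the targets' bins without replacement. The z-score and an
empirical one-sided p-value with the $(r+1)/(n+1)$ correction follow; a
constant null is reported as degenerate (z undefined, p still defined)
rather than silently zero. Calibration is itself a tested property: under
uniform random placement the z distribution has mean within ±0.15 of 0 and
standard deviation in [0.8, 1.25].

Proximity and the full ranked association list are computed on the **full
interactome**, while the descriptive statistics, mechanism overlap and
modules use the induced signature+targets network. This split matters: a
null drawn inside the disease network would consist mostly of signature
members at distance zero and would invert every z-score. The ranked list
scores each non-signature protein as a singleton target set, orders by
ascending z, and breaks ties by id.

Mechanism overlap between two drug classes is the Jaccard index of the
unions of their targets' radius-$r$ neighborhoods in the disease network,
with $r = 1$ (direct interactors) by default — the claim it supports is
qualitative, so the radius is exposed and reported rather than hidden.

## Module detection

Modules come from K-means on a spectral embedding: the first 12 nontrivial
eigenvectors of the symmetric normalized Laplacian, rows normalized to
unit length, eigenvector signs fixed by making each vector's
largest-magnitude entry positive so the embedding is deterministic. The
clustered object is the network's nodes — what was clustered is not
otherwise derivable, and the spectral embedding is the standard graph
choice; it is isolated behind one function so an alternative feature space
can be swapped in. K-means uses k-means++ seeding with 20 restarts and
keeps the best inertia. The embedding dimension defaults to 12,
comfortably above the cluster counts of interest while keeping the
noise dimensions limited.

K is selected by the elbow rule, made precise as the interior K maximizing
the discrete second difference $I(K{-}1) - 2 I(K) + I(K{+}1)$ of the
inertia curve over K = 2..20, ties to the smallest K. This
parameter-free reading is affine-invariant and reproducible, which the
informal "elbow method" is not. On the reference synthetic interactome
(10 planted blocks of 25 nodes, within-block edge probability 0.25,
between-block 0.01) the rule selects K = 10 and the partition agrees with
the planted blocks at adjusted Rand index above 0.95.

## What the generator emulates — and what it does not

The synthetic generator is the package's study system, with defaults fixed
once:

* **Expression**: 500 genes (scaled to 20,000 in recovery tests), 4
  samples per group, baseline intensities N(7, 1), gene variances drawn
  exactly from the scaled inverse-chi-square prior with $d_0 = 4$,
  $s_0^2 = 0.05$ — so the empirical-Bayes estimator has recoverable ground
  truth (recovered within ±15% / ±10% at 20,000 genes) — and a planted
  log2 shift of 1.5 on signature genes.
* **Interactome**: a stochastic block model, 10 blocks of 25 nodes,
  within/between edge probabilities 0.25 / 0.01, confidence scores uniform
  on [0.9, 1] so the 0.9 cut is non-destructive; a noisy-score option
  draws from [0, 1] to exercise the threshold.
* **Signature and targets**: 20 proteins inside one block; four targets
  placed exactly one hop from the signature (placement is verified, and
  infeasible placements are an error, never silent).
* **Orthology**: a one-to-one planted layer plus decoys constructed so
  that reciprocal-best-hit inference provably returns exactly the planted
  pairs.

The generator does not emulate probe-level artifacts, dye or batch
effects, control probes, correlated gene expression, or the hub-dominated
degree distribution of real curated interactomes. Passing tests therefore
demonstrate that the machinery is correct under its stated model, not that
any biological conclusion transfers: with real data the signature depends
on preprocessing choices and database versions, which is precisely why
the headline counts of any one platform snapshot are treated as
descriptive rather than as reproduction targets.

On statistical power: under the $d_0 = 4$ prior the variance distribution
is heavy-tailed, and a one-log2-unit shift at 4 samples per group reaches
only ~55% sensitivity at the signature thresholds; 80% needs six samples
per group (or a 1.5-unit shift at four). The pipeline's demo regime uses
planted shifts of 1.5–2.5 accordingly.

## Numerical choices and degenerate inputs

* Zero within-group variance is retained (s² = 0, flagged); a zero
  posterior variance yields an infinite t and p = 0, flagged.
* BH adjustment is the step-up procedure; tests hold it equal to a
  from-definition oracle.
* The Poisson tail uses `pgamma(λ, shape = n, log.p = TRUE)`; an observed
  count of 0 returns p = 1.
* Shortest paths are breadth-first hop counts; unreachable is reported as
  such and penalized only at the proximity layer.
* One global seed per run is split deterministically into per-stage seeds
  and recorded in the run report; identical configuration and seed give
  byte-identical outputs (a tested contract).
* Cluster labels are 1..K in the R convention; all agreement statistics
  are label-permutation-invariant.

## Known limitations

The degree-matched null, the Chung–Lu/Poisson enrichment null, and the
second-difference elbow are this package's defined, reproducible choices
for steps whose original operationalizations (a proprietary
neural-network ranking layer, a web platform's internal null) are not
public. They are validated against independent oracles on synthetic
fixtures, not against those systems. Multi-timepoint contrasts, probe-level
preprocessing, in-paralog clustering and weighted shortest paths are out
of scope.
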