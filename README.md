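# remodnet

Network proximity analysis of drug targets in post-infarction cardiac
remodeling.

After a myocardial infarction the left ventricle remodels — a protein
program that the four standard drug classes (ACE inhibitors,
angiotensin-receptor blockers, beta-blockers, mineralocorticoid-receptor
antagonists) are meant to interrupt. remodnet implements, as a tested R
pipeline, the network-medicine chain used to ask whether a drug's targets
sit unusually close to a remodeling protein signature inside a
confidence-thresholded protein–protein interaction network:

1. **Signature** — two-group differential expression with quantile
   normalization, empirical-Bayes moderated t statistics
   ($\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$), Benjamini–Hochberg
   adjustment, and the filter adj. $p < 0.01$, $|\log_2\mathrm{FC}| > 0.25$;
2. **Orthology** — cross-species translation by reciprocal best hits with a
   strict one-to-one gene→protein map;
3. **Network** — STRING-style scored interactions cut at combined score
   ≥ 0.9, edge enrichment against the degree-product expectation
   $E = \sum_{\{i,j\}} \min(1, k_i k_j/2m)$ with a Poisson upper-tail
   p-value;
4. **Proximity** — closest set distance
   $d(T,S) = |T|^{-1}\sum_t \min_s d(t,s)$ from drug targets to the
   signature, z-scored against a degree-matched permutation null, plus a
   ranked association list over all proteins and pairwise drug
   mechanism-overlap (Jaccard of radius-1 neighborhoods);
5. **Modules** — K-means on a spectral embedding of the network with K
   chosen at the elbow (maximum second difference of the inertia curve).

A synthetic-data generator plants known truth under every stage (planted
differential genes, ortholog pairs, block-model communities, signature and
target placement), so the whole chain is testable offline. The analysis
itself lives in `analysis/01_simulate.R` … `05_modules.R`, thin drivers
over the package functions.

## Worked example

Running the five analysis stages on the default synthetic study
(`Rscript analysis/01_simulate.R` … `05_modules.R`) prints:

```
simulated study written to results/data/
  interactome: 250 proteins, 1056 interactions
  signature: 20 proteins in block B01; 4 drug targets at 1 hop
  expression: 500 genes x 8 samples, 20 planted differential

moderated-t prior: d0 = 5.26, s0sq = 0.0547
18 of 500 genes pass the signature filter; 250 ortholog pairs
derived signature: 18 proteins; recall vs planted 0.90, precision 1.00

disease network: 22 nodes, 38 connections
expected random connections: 6.6; enrichment p = 5.05e-17

drug-class proximity to the post-MI signature (closest metric):
  ACEi         d = 1.00, null 1.78 +- 0.68, z = -1.15, p = 0.262
  ARB          d = 2.00, null 1.92 +- 0.80, z = +0.11, p = 0.801
  beta_blocker d = 1.00, null 1.78 +- 0.68, z = -1.15, p = 0.262
  MRA          d = 1.00, null 1.78 +- 0.68, z = -1.15, p = 0.262

elbow selects K = 10 (planted modules: 10)
adjusted Rand agreement with planted blocks: 0.955
```

Reading the numbers: the differential-expression stage recovers 18 of the
20 planted signature genes with no false positives, and the estimated
variance-prior hyperparameters sit near their generating values (d0 = 4,
s0sq = 0.05). The derived 18-protein signature plus the four targets forms
a 22-node network with 38 connections where ~7 would be expected by
degree chance — the signature is a genuine module. Three of the four drug
targets sit one hop from the signature, closer than their degree-matched
null (negative z); ARB's planted neighbor was one of the two signature
proteins the filter missed, so its observed distance is 2 — proximity
conclusions inherit signature-derivation error, which is the point of
running the chain end to end. The elbow rule recovers the ten planted
interactome modules almost exactly.

A single call runs the same chain from one configuration:

```r
library(remodnet)
cfg <- pipeline_config(interactions = "interactions.tsv",
                       signature = "curated_signature.txt",  # skips stages 1-2
                       outdir = "out", seed = 1)
report <- run_pipeline(cfg)
```

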