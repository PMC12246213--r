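---
title: "Methods: exact Bayesian networks for genotype-aware surgical risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact Bayesian networks for genotype-aware surgical risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnrisk)
```

## The problem and the model

Children undergoing surgery for congenital heart disease (CHD) differ widely
in post-operative risk, and part of that variation tracks the genotype:
damaging variants in chromatin-modifying or cilia-related genes travel with
particular cardiac phenotypes, extracardiac anomalies and worse surgical
outcomes. bnrisk models a surgical cohort as a set of binary
presence/absence variables — damaging-genotype flags per gene pathway,
phenotype-class flags, an extracardiac-anomaly flag, a high-risk-surgery
flag, and post-operative outcome flags — and represents their joint
distribution with a discrete Bayesian network: a directed acyclic graph
(DAG) plus, for every variable, a conditional probability table (CPT)
giving $P(v = 1 \mid \text{parents})$.

Structure is learned by **exact** score maximisation, not heuristic search.
The score is BIC with natural logarithms: for a family $(v, S)$ on $N$
complete rows,

$$\mathrm{score}(v, S) \;=\; \max_\theta \log L \;-\; \frac{\ln N}{2}\, 2^{|S|}(r-1), \qquad r = 2,$$

with the convention $0 \log 0 = 0$ and with parent configurations that never
occur contributing zero likelihood but still counting in the penalty
dimension. BIC decomposes over families, which licenses the
Silander–Myllymäki dynamic program: (i) the best parent set of every node
within every candidate subset, (ii) a best-sink recursion over variable
subsets, (iii) reconstruction of an optimal ordering and its parent sets.
The search is globally optimal and deterministic; among equal-scoring
parent sets the smaller, then lexicographically earlier set wins, and sinks
are chosen in name order. Because the score is likelihood-based, Markov
equivalent DAGs tie exactly — learned edge directions within an equivalence
class are a tie-break, not a causal claim, which is why display output
moralizes the graph (co-parents married, directions dropped).

Queries are answered by **exact propagation**: the joint implied by the
CPTs is summed over hidden variables. The package enumerates the full
joint (networks here have $\le$ 20 nodes, usually $\le$ 10, so $2^n$
enumeration is cheap and transparent); an independent brute-force
implementation in the test suite checks every query path to $10^{-12}$
relative error.

Two risk summaries are computed from a fitted network:

* absolute risk ratio $\;P(T{=}1 \mid C{=}1)\,/\,P(T{=}1)$ — enrichment of a
  target state among carriers of a condition relative to the whole cohort;
* relative risk ratio $\;P(\mathbf{T} \mid F{=}1)\,/\,P(\mathbf{T} \mid F{=}0)$
  — contrast of a joint target assignment between carriers and
  non-carriers of a factor.

Uncertainty comes from a bootstrap that resamples patients with
replacement and **re-learns the structure in every replicate** before
refitting CPTs and re-evaluating the query, so intervals carry structural
as well as parametric uncertainty. Two summaries are offered: the
replicate median with empirical (5th, 95th) percentiles, and the replicate
mean ± $t_{0.975, B-1}$ times the replicate SD. The percentile pair is
deliberately literal — (5, 95) spans 90% of the resampling distribution
even when labelled a "95% CI" in clinical reporting conventions; the pair
is configurable and the interpretation is documented here once rather than
silently corrected. Replicates in which the conditioning event has zero
probability (e.g. a resample without a single genotype carrier) are
excluded and counted, never imputed.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `smoothing` | 0.01 | pseudocount per CPT cell | prevents zero-state probabilities inside bootstrap replicates; `"1/N"` selects the sample-size correction instead |
| `B` | 1000 | replicates | the reference bootstrap size; tests scale it down |
| `k` (imputation) | 10 | neighbours | KNN majority vote on binary data |
| `max_parents` | unlimited | — | the search is exact; networks are small enough not to need a cap (hard guard at 20 variables) |
| collinearity threshold | 0.7 | \|phi\| | flags near-duplicate variables, which distort both structure learning and risk propagation |
| missingness cap | 0.10 | fraction/variable | cohort-construction rule; loading refuses worse variables unless overridden |

Smoothing semantics: the pseudocount is added to both outcome counts of
every CPT cell, so an unseen parent configuration yields 0.5 rather than
an undefined estimate. Whether the original analysis smoothed always or
only during bootstrapping is ambiguous; both are supported — `bn_fit()`
applies the policy it is given, and the bootstrap applies it in every
replicate, which is the setting that matters for zero states.

KNN imputation details the cohort rule leaves open were fixed as follows:
distance is Hamming distance over mutually observed variables normalised
by the overlap size; distance ties break by patient row order; even votes
fall back to the variable's marginal mode. All three choices make the
procedure deterministic, and the mode fallback is unbiased toward
prevalence.

## What the synthetic generator emulates — and what it does not

`pcgc_scenario()` is a ten-variable ground-truth network whose CPTs were
solved once, by fixed-point iteration against exact enumeration, to
reproduce the statistical anchors of a 2,253-patient critical CHD surgical
cohort: overall damaging-genotype prevalence 10.56%, phenotype marginals
at cohort rates (LVO 647/2253, HTX 219/2253), deterministic phenotype
nesting (HLHS ⊆ LVO), and genotype–phenotype/outcome risk ratios in the
1.4–4.0 band (LVO enrichment 1.61 given a chromatin genotype, HTX
enrichment 2.63 given a cilia genotype, mortality/arrest/ventilation
relative risks 1.8/1.7/1.6 given a chromatin genotype and 1.4/1.5/1.4
given a cilia genotype). The solved CPTs and the anchors they attain ship
in a versioned preset (`inst/extdata/pcgc_like_scenario.json`); nothing is
re-solved at run time. Quantities the anchors do not pin down were set
once at clinically plausible values (extracardiac anomalies ~30%,
high-risk surgery ~22%, mortality 5%, arrest 6%, prolonged ventilation
15%) and are recorded in the preset. Missingness is injected MCAR,
cell-wise, capped at 10% per variable — the generator does not model
informative missingness because the cohort rule it emulates does not
characterise one.

Two honest limitations of the emulation. First, the real cohort's
damaging-genotype burden spans many gene pathways; the scenario's two
flags carry the whole 10.6% burden, so per-flag prevalences (~5.5%) are
higher than the real per-pathway counts (28 and 35 carriers). Second, the
synthetic phenotype-code scenario used for classifier tests is cleaner
than a real hierarchical coding vocabulary — codes are conditionally
independent given the category — so classifier accuracies on it
(approaching 100% at the default informativeness) overstate what the same
protocol attains on real codes (high-90s). Passing tests therefore
demonstrate correctness of the algorithms and protocols, not clinical
performance.

A consequence of honest BIC scoring worth knowing: at the study size of
n = 2253, weak genotype–outcome edges (marginal mortality signal from a
5–6% genotype in a 5% outcome) fall below the BIC penalty and are
correctly omitted; the corresponding propagated relative risks then sit
at 1.0. The planted outcome effects become recoverable at larger n (the
recovery tests use $10^5$), and phenotype-enrichment effects (stronger
signals) are recoverable at the study size itself. This mirrors the
general behaviour of penalised structure learning rather than a defect of
the search, and it is why interval calibration is assessed on a query
whose structure is identifiable at n = 2253.

## Numerical and design choices

* Counting for family scores builds one joint contingency table and
  marginalises recursively (total work $O(3^n)$ per node), implemented in
  C++; a plain-R family score is kept as the in-package reference and the
  two are cross-checked in tests.
* Enumeration is the reference inference path; any optimisation must agree
  with it to $10^{-12}$ relative (tested).
* All-constant data learn the empty DAG with a warning; zero-variance
  columns are reported and can be dropped before network stages, since
  their phi coefficients are undefined and their families vacuous.
* The t-interval interprets "fitted to a t-distribution" as mean ±
  $t_{0.975,B-1}\cdot$SD of the replicates, with df from the defined
  replicates actually used.
* Feature screening estimates each candidate–target conditional as the
  median over bootstrap networks learned on the pair and selects absolute
  risk ratios ≥ 1.0 — the permissive screen is intentional (it feeds a
  multivariate network stage, it is not an inference).
* The boosted-tree learner behind the phenotype classifier is a standard
  gradient-boosting library used single-threaded for bit-reproducibility;
  the package's contribution there is the protocol: binary code encoding,
  stratified 5-fold CV grid search minimising multiclass log loss (ties:
  lower error, then lower loss SD), argmax assignment, and the confidence
  margin (best minus second-best probability). The default grid (depth
  {3, 4, 6} × learning rate {0.1, 0.3} × rounds {50, 100, 200}) is a
  package choice; row subsampling is exposed as a hyperparameter because
  the protocol it mirrors does not fully specify it.

## Problem sizes used by the shipped checks

The test suite and the acceptance script choose sizes that make the
statistics sharp but the runs routine on a single CPU: 100 random datasets
for the exhaustive-search oracle (3–4 variables, where all 25/543 DAGs can
be enumerated), 100 random 5-node networks for the inference oracle,
$n = 10^5$ samples for point-estimate recovery, 200 synthetic cohorts of
n = 2253 with B = 200 for interval calibration (B scaled down from the
reference 1000), and 3,000-patient synthetic code cohorts for the
classifier. These are the package's chosen verification conditions and
are stated here so they can be scaled up by anyone wanting tighter Monte
Carlo error.

## Known limitations

* Binary variables only; no continuous or multi-level categorical support.
* Exact enumeration bounds practical network size (~20 nodes); that is the
  intended regime, not a scalability claim.
* The bootstrap's structural re-learning makes intervals honest about
  model selection but also means a weakly identified edge yields
  replicate distributions with point mass at ratio 1.
* No survival/time-to-event modelling; outcomes are presence/absence.
* The simulator draws i.i.d. patients; site effects, ascertainment and
  relatedness present in real multi-centre cohorts are out of scope.
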