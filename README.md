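# bnrisk

Exact Bayesian-network risk estimation for binary clinical cohorts.

bnrisk is for analysts of surgical cohorts — typically congenital heart
disease (CHD) cohorts — who want to quantify how damaging genotypes in
specific gene pathways shift the probability of phenotypes and
post-operative outcomes, with confidence intervals that are honest about
model selection. Everything is coded presence/absence: genotype flags per
gene pathway, CHD phenotype classes, extracardiac anomalies, high-risk
surgical categories (STAT 4–5), and outcomes such as mortality, cardiac
arrest, and prolonged ventilation.

## The model

A cohort's joint distribution is represented by a discrete Bayesian
network (DAG + conditional probability tables). The structure is learned
**exactly** — the Silander–Myllymäki dynamic program finds a globally
optimal DAG under BIC,

```
score(v, S) = max log-likelihood(v | S)  −  (ln N / 2) · 2^|S|
```

— and queries are answered by exact propagation (summation over hidden
variables). On top of the fitted network, two risk summaries are
computed:

* **absolute risk ratio**  `P(T=1 | C=1) / P(T=1)` — enrichment of a
  target among condition carriers relative to the whole population;
* **relative risk ratio**  `P(T | F=1) / P(T | F=0)` — contrast of a
  joint target assignment between carriers and non-carriers of a factor.

Confidence intervals come from bootstrap resampling in which **the
network structure is re-learned in every replicate** and the CPTs refit
with zero-state smoothing (pseudocount 0.01 or 1/N), summarised either as
the replicate median with (5th, 95th) percentiles or as mean ± t·SD.

Around this core the package provides binary-cohort I/O and validation,
phi-coefficient collinearity screening, KNN imputation (k = 10, Hamming
distance over mutually observed variables), a feature screen (absolute
RR ≥ 1 over bootstrap networks), pathway × phenotype enrichment tables, a
calibrated synthetic cohort generator with exact enumeration oracles, a
gradient-boosted five-class phenotype classifier over binary code
vocabularies, and a config-driven pipeline (`run_pipeline()`).

## Worked example

Simulate a 2,253-patient cohort from the calibrated ground-truth network,
degrade it with 5% missingness, impute, fit, and estimate a risk ratio:

```r
library(bnrisk)

gtn    <- pcgc_scenario()                       # ground-truth network
cohort <- sample_cohort(gtn, 2253, seed = 7)
cohort <- inject_missingness(cohort, 0.05, seed = 8)
cohort
#> cohort_matrix: 2253 patients x 10 variables
#>   missing cells: 1145 (5.08%)
#>   roles: cardiac_phenotype=3, extracardiac=1, genotype=2, outcome=3, surgical=1

imp <- knn_impute(cohort, k = 10)
fit <- bn_fit(subset_variables(imp, c("CHRMdGV", "LVO", "HLHS", "STAT45")))
summary(fit)
#> Exact Bayesian network over 4 binary variables (N = 2253)
#> network BIC score: -3294.5867
#> edges:
#>   CHRMdGV -> LVO
#>   STAT45 -> LVO
#>   LVO -> HLHS
#> propagated marginals P(v = 1):
#> CHRMdGV     LVO    HLHS  STAT45
#>  0.0519  0.2552  0.1062  0.2020

est <- bootstrap_risk(imp, c("CHRMdGV", "LVO", "HLHS", "STAT45"),
                      risk_query("absolute", target = "LVO", condition = "CHRMdGV"),
                      B = 1000, seed = 9, summary = "t_mean")
est
#> absolute LVO=1 | CHRMdGV=1: 1.539 (1.019, 2.060)  [t_mean, B = 1000, undefined = 0]

true_absolute_rr(gtn, "LVO", "CHRMdGV")   # exact generative truth
#> [1] 1.61
```

Reading the output: the exact search recovered the genotype→phenotype and
phenotype→surgery dependencies (HLHS attaches to LVO, of which it is a
deterministic subset); carriers of a damaging chromatin-pathway genotype
are about 1.5-fold enriched for left ventricular outflow obstruction in
this simulated draw, the t-based 95% interval excludes 1, and the interval
covers the generative truth (1.61) computed by exact enumeration of the
ground-truth CPTs. The `undefined = 0` counter reports bootstrap
replicates whose resample made the query unanswerable (none here).

See the methods vignette (`vignettes/bnrisk-methods.Rmd`) for the model,
calibration, and the design decisions behind imputation, smoothing, and
interval conventions.

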