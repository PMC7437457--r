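# csflink

Cerebrospinal fluid (CSF) biomarkers — amyloid-beta (Aβ), total tau (TAU)
and phosphorylated tau (PTAU) — track the brain pathology of late mild
cognitive impairment (LMCI), the prodromal stage with the highest risk of
conversion to Alzheimer's disease, but lumbar puncture is too invasive for
routine screening. `csflink` implements an association pipeline that asks
how much of the CSF signal can be read from peripheral blood instead: bulk
blood gene expression is converted into relative immune-cell abundances,
those abundances plus plasma Aβ measures are screened against the CSF
triplet, the joint relationship is quantified by canonical correlation
analysis, and the most promising peripheral markers are evaluated as
diagnostic classifiers. It is aimed at researchers analysing matched
blood-expression / plasma / CSF cohorts.

## The statistics at the core

**Immune-cell abundance by enrichment score.** For a cell-type signature
set *S* (|S| = N<sub>H</sub>) and a list of N genes ranked by statistic
r<sub>j</sub>, the running sum increases by |r<sub>j</sub>|<sup>α</sup> / N<sub>R</sub>
at each signature gene (N<sub>R</sub> = Σ<sub>g∈S</sub>|r|<sup>α</sup>) and
decreases by 1/(N − N<sub>H</sub>) otherwise; the enrichment score ES ∈
[−1, 1] is the maximal deviation from zero. Ranking genes by expression
within one sample (α = 0.25) makes the ES a relative abundance of that cell
type in that sample; a two-class signal-to-noise ranking (α = 1) is also
provided.

**Screening.** Every peripheral variable is correlated with every CSF
variable (Pearson r, exact two-sided p from t = r√((n−2)/(1−r²))); a
variable is carried forward if any pair is significant at α = 0.05.

**Canonical correlation analysis.** With CSF block X (p variables) and
selected peripheral block Y (q variables), CCA finds coefficient vectors
a<sub>i</sub>, b<sub>i</sub> maximising r<sub>i</sub> = corr(U<sub>i</sub>, V<sub>i</sub>)
for variates U<sub>i</sub> = a<sub>i</sub>ᵀX, V<sub>i</sub> = b<sub>i</sub>ᵀY.
`cca_fit()` reports the correlations, eigenvalues r²/(1−r²), the sequential
Wilks' Λ<sub>k</sub> = Π<sub>i≥k</sub>(1−r<sub>i</sub>²) with Rao's F
approximation, standardized coefficients, loadings, cross-loadings and
redundancy indices.

**Marker evaluation.** Single-marker AUC via the Mann–Whitney statistic
(ties half-credited) and a logistic-regression combination (coefficient
inclusion at Wald p < 0.1) whose fitted probabilities give the combined
ROC.

A synthetic cohort generator (`simulate_cohort()`) plants all of this
ground truth — latent cell abundances behind signature genes, a shared
latent factor giving a chosen first canonical correlation, and a group
mean-shift giving a chosen marker AUC — so the full pipeline runs and is
tested without restricted clinical data.

## Worked example

```r
library(csflink)

cohort <- simulate_cohort(seed = 42)   # 36 samples: 20 LMCI-like, 16 control
report <- run_pipeline(cohort, cohort$truth$signatures)
report
#> <csf_pipeline_report>
#>   abundance: 28 cell type(s) scored (ES weight = 0.25)
#>   screen: 10 variable(s) selected at alpha = 0.05: Activated CD4 T cell, Central memory CD4 T cell, Gamma delta T cell, Type 2 T helper cell, FP40, FP42, TP40, TP42, FP40/FP42, TP40/TP42
#>   cca: canonical correlations 0.865, 0.607, 0.370
#>   roc: Activated CD4 T cell = 0.431, Central memory CD4 T cell = 0.481, Gamma delta T cell = 0.419, Type 2 T helper cell = 0.456, FP40 = 0.537, FP42 = 0.472, TP40 = 0.428, TP42 = 0.541, FP40/FP42 = 0.734, TP40/TP42 = 0.569
#>   combined AUC = 0.938
```

Ten peripheral variables pass the Pearson screen (the six plasma measures,
which share a latent factor with the CSF block by construction, plus four
cell types that pass by chance at raw α = 0.05). The first canonical
function links the blocks at r₁ = 0.865 — the planted population value is
0.794, and estimates at n = 36 sit above it because the leading canonical
correlation is biased upward in small samples. Per-function inference:

```r
tidy(report$cca)
#> # A tibble: 3 × 10
#>   function_ correlation eigenvalue lambda statistic   df1   df2 p.value x_redundancy y_redundancy
#> 1         1       0.865      2.96   0.138     2.19     30  68.2 0.00385       0.533        0.186
#> 2         2       0.607      0.584  0.545     0.985    18  50   0.491         0.0620       0.0343
#> 3         3       0.370      0.158  0.863     0.535     8  27   0.820         0.0162       0.00877
```

Only the first function is significant: the CSF and peripheral blocks
share one latent axis, exactly as planted. Among the ROC markers (those
with |loading| ≥ 0.29 on V₁ or V₂), the designated shifted marker
FP40/FP42 scores AUC 0.734 (planted population value 0.709), and the
logistic combination of the high-loading markers reaches 0.938 on this
36-sample cohort — apparent (resubstitution) estimates, as reported by
`report$roc` and `report$combined`.

Real data enter through `read_expression()`, `read_gmt()`,
`read_biomarkers()` and `harmonize_cohort()`, which intersects the three
sources and applies listwise deletion before the same `run_pipeline()`
call.

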