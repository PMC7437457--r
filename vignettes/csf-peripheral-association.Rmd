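---
title: "Linking peripheral blood to CSF biomarkers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking peripheral blood to CSF biomarkers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csflink)
```

`csflink` chains four statistical steps to ask how much of the
cerebrospinal-fluid (CSF) biomarker signal of late mild cognitive
impairment (LMCI) is visible in peripheral blood: enrichment-score
estimation of immune-cell abundances from bulk expression, Pearson
screening of peripheral variables against the CSF triplet (Aβ, TAU,
PTAU), canonical correlation analysis (CCA) between the two variable
sets, and ROC evaluation of single and logistic-combined markers. This
vignette explains each model, the tunable parameters, the synthetic
cohort generator that closes the testing loop, and the numerical and
design choices that were genuinely open.

## Immune-cell abundance from the enrichment score

For a ranked list of $N$ genes with ranking statistics $r_j$ and a
signature set $S$ of size $N_H$, the running sum gains
$|r_j|^\alpha / N_R$ at each signature gene, where
$N_R=\sum_{g_j\in S}|r_j|^\alpha$, and loses $1/(N-N_H)$ at every other
gene. The enrichment score (ES) is the running-sum value at the index of
maximal absolute deviation from zero. It is bounded in $[-1,1]$, and
equals $1$ exactly when the signature occupies the top $N_H$ positions.
Two conventions needed fixing where the method description leaves play:

* **Tie-break.** If two indices attain the same absolute deviation the
  earliest index wins. This matters for short lists; it makes the score
  deterministic and is asserted in the exhaustive small-list tests (all
  subsets of all lists up to $N = 8$ against a step-by-step loop
  oracle).
* **Degenerate weights.** If every signature gene has a zero ranking
  statistic, $N_R = 0$; the score falls back to unweighted ($\alpha=0$)
  steps with a warning rather than failing.

Two ranking modes are exposed. The *per-sample* mode ranks genes by
their expression within one sample (ties broken by gene ID so results
are bit-reproducible) and uses $\alpha = 0.25$, the single-sample GSEA
convention; the ES of a cell-type signature is then interpreted as that
cell type's relative abundance in that sample. This is the default and
the reproduction path, since the motivating analysis reports per-sample
abundances. The *two-class* mode (`score_classes()`,
$\alpha = 1$) ranks genes by the case/control signal-to-noise ratio
$(\mu_1-\mu_0)/(\sigma_1+\sigma_0)$, with each class standard deviation
floored at $0.2\,|\mu|$ (at $0.2$ when $\mu = 0$), because the method's
textual description is phrased in terms of phenotype ranking; it is
provided for completeness, with an optional seeded gene-label
permutation null. No between-set normalisation (NES) is applied: the raw
ES is the abundance estimate. Signature genes absent from the expression
matrix are dropped silently from $S$ — the only workable choice when
signatures and platforms differ — with per-signature overlap counts kept
in the result.

## Pearson screening

Every peripheral variable (28 cell-type ES rows plus the plasma Aβ
measures) is correlated with every CSF variable; the two-sided p-value
uses the exact small-sample transform
$t = r\sqrt{(n-2)/(1-r^2)} \sim t_{n-2}$. A peripheral variable is
selected when at least one of its CSF correlations has $p < \alpha$
(default $\alpha = 0.05$). Two deliberate fidelity choices:

* **No multiple-testing correction by default.** The motivating analysis
  judges each of the $34\times3$ pairs at raw $\alpha = 0.05$;
  `screen_markers(..., adjust = "BH")` offers Benjamini–Hochberg
  selection for users who want it.
* **The selection rule** ("at least one significant CSF correlation") is
  stated explicitly here because the source analysis only implies it
  through its selected-variable count.

Constant variables, for which $r$ is undefined, are excluded from
selection with a warning rather than silently dropped.

## Canonical correlation analysis

With standardized blocks (mean 0, unit variance, $n-1$ denominator), the
canonical structure is taken from the SVD of the whitened
cross-correlation $R_{xx}^{-1/2} R_{xy} R_{yy}^{-1/2}$: the singular
values are the canonical correlations $r_1 \ge \dots \ge r_s$,
$s=\min(p,q)$, and back-transforming the singular vectors gives
coefficients scaled so each variate has unit variance. This is
algebraically equivalent to the classical generalized eigenproblem but
numerically stabler; equivalence with `stats::cancor` and with a dense
grid-search oracle over unit-norm coefficient directions is asserted in
the tests. Rank-deficient blocks are an error naming the collinear
columns; an explicit `ridge` (e.g. $10^{-8}$) can be requested and is
logged.

Derived quantities follow the standard identities, each verified against
a direct computation in the tests: loadings
$R_{xx} a_k = \mathrm{corr}(X_v, U_k)$; cross-loadings
$r_k \times$ loading $= \mathrm{corr}(X_v, V_k)$; redundancy
$RI_k = r_k^2 \cdot \overline{\text{loading}_k^2}$, the mean squared
cross-loading. Sequential inference uses Wilks'
$\Lambda_k = \prod_{i\ge k}(1-r_i^2)$ with Rao's F approximation at
effective dimensions $p_k = p-k+1$, $q_k = q-k+1$ and the *same* $n$ for
every $k$. Under this convention the function-1 statistics reproduce the
reference SPSS output exactly (to the rounding of the printed
correlations), while rows 2–3 agree only approximately — SPSS's
sequential-$n$ adjustment for later roots is not documented, so the
standard convention is kept and function 1 is treated as the reliable
comparison surface. A p-value displayed as 0.000 is asserted only as
$p < 0.0005$.

Two further conventions fix indeterminacies the source never mentions:

* **Sign.** Each canonical function's coefficient pair $(a_k, b_k)$ is
  flipped *together* (preserving $\mathrm{corr}(U_k,V_k) = +r_k$) so
  that the x-block variable with the largest-magnitude loading loads
  positively. Flipping only one block's vector, as a literal reading of
  a per-block rule would suggest, would break the positive-correlation
  invariant. Comparisons with published coefficient tables should be
  made up to a global sign per function.
* **Degenerate columns** are rejected, not dropped: a constant column in
  either block is an error.

## ROC analysis and marker combination

The AUC is computed by the Mann–Whitney pair statistic (rank-sum form,
ties credited one half); the ROC curve sweeps thresholds over the unique
score values, so tied scores produce a single diagonal segment and the
trapezoidal area equals the AUC to machine precision. Markers are scored
*as given*, and the result carries both the raw AUC and the
orientation-corrected $\max(a, 1-a)$, since the direction each marker
should point (which state is "positive") is a reporting convention the
source does not state. Logistic combination uses the binomial GLM (IRLS,
tolerance $10^{-8}$, 100 iterations max) with Wald z p-values — the SPSS
default — and the inclusion rule "every marker coefficient at
$p < 0.1$" enforced as a warning listing violators. Perfect separation
is detected (vanishing residual deviance or fully separated fitted
probabilities) and raised as an error; aliased collinear markers are
kept with a zero coefficient and a warning. No cross-validation is
applied by design: the reported AUCs are apparent (resubstitution)
estimates, matching the source analysis; users who need honest error
should resample externally.

The pipeline's default ROC marker set is every selected peripheral
variable with $|\text{loading}| \ge 0.29$ on $V_1$ or $V_2$. The
threshold encodes the source's unstated "highly contributing" rule — it
is the smallest loading magnitude that analysis highlighted — and is
fully overridable (`loading_threshold`, `roc_markers`).

## The synthetic cohort generator

`simulate_cohort()` emulates the study design so that every stage has a
closed testing loop. Its defaults *are* the study conditions and are not
tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `n_case`, `n_control` | 20, 16 | the 36-sample LMCI/control split |
| `cell_types` | 28 immune-cell names | latent abundances, one per type |
| `n_genes`, `genes_per_signature` | 2000, 30 | disjoint signatures carved from the gene list |
| `beta` | 1 | expression shift per unit abundance on signature genes |
| `baseline_mean`, `baseline_sd` | 7, 1 | log-scale Gaussian baseline (microarray-like) |
| `rho` | 0.794 | planted first canonical correlation (the reported value) |
| `delta` | $\sqrt{2}\,\Phi^{-1}(0.709)$ | group shift of the designated plasma marker, planting AUC 0.709 |
| `cell_delta` | $\sqrt{2}\,\Phi^{-1}(0.703)$ | downward case shift of the designated cell type's abundance |

Mechanics: abundances are standard Gaussians per cell type and sample
(the designated cell type, a type 1 T helper analogue, is mean-shifted
down in cases); expression is baseline noise plus
$\beta \times$ abundance on signature genes; the CSF triplet and plasma
block each load on a single shared latent factor $z$ (rank-1
cross-covariance) with unit-variance noise. Loading norms are calibrated
in closed form: a block with loading vector $w$, $\lVert w\rVert^2=h^2$,
and unit noise achieves best-combination correlation
$h^2/(h^2+1)$ with $z$, so setting $h^2 = \rho/(1-\rho)$ in both blocks
gives population first canonical correlation exactly $\rho$; the
calibration and the closed form agree to $10^{-10}$ in the tests. The
designated marker's group shift is scaled by its total standard
deviation, so its population AUC is $\Phi(\delta/\sqrt2)$ regardless of
its factor loading. Gaussian log-scale noise was chosen because the
source is silent on the noise model and it is the simplest model under
which ES recovery is analysable. All randomness flows from one explicit
seed, and the caller's RNG state is restored afterwards.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: microarray batch and saturation artifacts,
probe-level structure, heavy-tailed or correlated noise, overlapping
signatures, the marginal distributions of real ADNI measurements, and
any coupling between immune-cell abundances and CSF values (in the
generator only the plasma block shares the latent factor, so cell-type
ES rows are null with respect to CSF). A rank-1 shared factor is enough
to test the first canonical function, which carries the headline result,
but says nothing about the recovery of later functions.

## Numerical choices and problem sizes

* Ties: gene-ID order everywhere a ranking can tie; earliest index for
  the ES deviation; these make every result bit-reproducible (two runs
  of the pipeline write byte-identical artifacts, asserted in tests).
* Whitening uses the symmetric eigendecomposition inverse square root
  with a $10^{-10}$ eigenvalue floor as the rank-deficiency test.
* Duplicate gene probes are collapsed by mean at read time (logged);
  missing biomarker cells cause listwise sample deletion at
  harmonization, never imputation; the canonical sample order is the
  lexicographic sort of IDs.
* Expression is assumed already normalized on a log scale upstream; the
  readers do no transformation.

Test and acceptance problem sizes were chosen to make Monte-Carlo error
comfortably smaller than the asserted tolerances while keeping the whole
suite fast: exhaustive ES enumeration to $N = 8$; null calibration of
the function-1 Rao F test over 1000 replicates at $(p,q,n)=(3,8,36)$;
recovery of $\rho = 0.8$ over 100 replicates at $n = 500$ (where the
upward small-sample bias of $r_1$, clearly visible at $n = 36$, is
negligible); AUC closed-form checks at $n = 10^5$.

## Known limitations

* The sequential Wilks/Rao rows beyond the first are convention-
  dependent (see above); treat them as approximate when comparing with
  SPSS output.
* Screening at raw $\alpha = 0.05$ over $34\times3$ pairs has a
  family-wise error near certainty by construction; that is faithful to
  the source, not a recommendation — use the BH option for new analyses.
* Apparent AUCs on 36 samples are optimistic, especially the combined
  logistic AUC, which refits on the evaluation data.
* ES abundances are *relative* within a sample; they support
  correlation-style analyses but are not calibrated cell fractions, and
  per-sample mode makes scores across samples comparable only insofar as
  the expression columns are comparably normalized.
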