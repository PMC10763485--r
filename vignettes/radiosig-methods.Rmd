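---
title: "Methods: dose-response modelling, enrichment and signature validation in radiosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response modelling, enrichment and signature validation in radiosig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(radiosig)
```

This vignette documents the models, the tunable parameters and the design
choices behind `radiosig`, in the spirit of a methods supplement. It states
no empirical results beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

## The linear-quadratic model and the two radioresponse indicators

Clonogenic survival after an acute dose $D$ (Gy) is modelled as

$$S(D) = \exp(-\alpha D - \beta D^2),$$

with $\alpha$ (Gy$^{-1}$) the linear, single-hit killing coefficient and
$\beta$ (Gy$^{-2}$) the quadratic term attributed to interacting
double-strand breaks. The $\alpha/\beta$ ratio is tissue-dependent: large
for early-responding tissue (the linear term dominates), small for
late-responding tissue.

Two scalar indicators summarise a fitted curve:

* **SF2** $= S(2\,\mathrm{Gy}) = \exp(-2\alpha - 4\beta)$, the classical
  single-dose point estimate;
* **AUC** $= \int_0^{d_{\max}} S(D)\,dD$ (Gy), the integral of the fitted
  curve over the administered dose range, which aggregates response across
  all dose levels instead of one.

`radiosig` treats AUC as the primary indicator and SF2 as the comparator.
The integral is left unnormalized, in Gy, with $d_{\max}$ the maximum
administered dose of that cell line; on a 0–8 Gy grid AUC therefore lies in
(0, 8]. Cohorts are split into *resistant* (AUC strictly above the cohort
mean) and *sensitive* (at or below); ties go to sensitive since a line at
the threshold has not demonstrated above-average resistance.

### Fitting

`fit_lq()` minimises squared error on the log scale,
$\sum_i (y_i - \alpha D_i - \beta D_i^2)^2$ with $y = -\ln S$, with no
intercept so that $S(0) = 1$ is enforced rather than estimated. The
unconstrained minimiser is closed-form (2×2 normal equations);
non-negativity of $(\alpha, \beta)$ is enforced by an active set: if a
coefficient comes out negative, the two single-parameter fits (the other
coefficient pinned at 0, clamped at 0) are evaluated and the feasible
candidate with the lowest residual sum of squares wins. The procedure is
deterministic, ordering-invariant and needs no starting values. Survival
values are sanitized before the log transform by clipping to
$[10^{-6}, 1.5]$ with a warning — assay noise routinely produces survival
slightly above 1, and zeros would make the log undefined.

### Numerical evaluation of the AUC

For $\beta > 0$ the integral has a Gaussian closed form. Written naively it
contains $\exp(\alpha^2/4\beta)$, which overflows quickly; `compute_auc()`
instead combines the prefactor with upper-tail normal log-probabilities
(`pnorm(..., log.p = TRUE)`), mathematically equivalent to the scaled
complementary error function, so every intermediate stays in range. Two
guard rails remain: when $\alpha^2/4\beta > 10^4$ the addition
$c + \log Q(a)$ cancels catastrophically (the two terms agree to many
digits), so the nearly-exponential regime is integrated adaptively instead;
and any non-finite or out-of-range closed-form value falls back to
`stats::integrate()`. The tests hold the analytic path to relative
agreement of $10^{-8}$ with adaptive quadrature across the parameter grid.

## Enrichment analysis

Genes are ranked by Spearman correlation with the indicator (robust to the
heavy tails and nonlinear scales of expression data; Pearson is available
by argument). Constant genes get $\rho = 0$ with a warning, and equal
correlations are ordered lexicographically by gene id so rankings are
deterministic.

The per-pathway statistic is the classic weighted Kolmogorov–Smirnov
running sum: walking down the ranked list, set members add
$|\rho|^p / \sum_{hits} |\rho|^p$ and non-members subtract $1/(N - N_h)$;
the enrichment score (ES) is the signed maximum deviation from zero, in
$[-1, 1]$. Decisions where the methodology leaves room:

* **Weight exponent** $p = 1$ by default (the standard weighted form);
  $p = 0$ gives the unweighted form and is used against the enumeration
  oracle in tests.
* **Null scheme**: gene-label permutation — `n_perm` random same-size gene
  sets from the ranked universe — because the ranking statistic is
  per-gene; a sample-permutation scheme (permute the response, re-rank)
  is available via `permutation = "sample"`. Default `n_perm = 1000`.
* **Sidedness**: two-sided via $|ES|$, with add-one correction
  $p = (1 + \#\{|ES_{perm}| \ge |ES_{obs}|\})/(n_{perm}+1)$, so $p$ is
  never 0 and is reproducible bit-for-bit under a seed.
* **Set-size filters**: sets with fewer than 10 or more than 500 members
  after intersection with measured genes are excluded — tiny sets make the
  ES degenerate, huge ones are uninformative.
* **FDR**: Benjamini–Hochberg across each collection separately (per
  pathway database), significance at FDR < 10%.
* **Tie in |ES|** between the positive and negative extremum: resolved to
  the positive side, with a $10^{-12}$ cushion so algebraically equivalent
  evaluation orders cannot flip the sign.

Leading-edge genes are the set members at ranks up to the running-sum
maximum (positive ES) or after the minimum (negative ES). For pathways
enriched by both indicators, `leading_edge_overlap()` compares the unions
of leading-edge genes to ask whether the same genes drive the shared
signal.

## The predictive signature

The signature pipeline is: optional compendium prefilter (intersection with
a curated radioresponse gene list) → rank genes by $|\rho|$ with AUC on
training samples — absolute value, so both resistance- and
sensitivity-associated genes are admissible → fit a multivariate linear
model of AUC on per-gene z-scored expression. Rank-deficient designs take
the minimum-norm SVD solution, so duplicated features split coefficient
mass without changing predictions; features constant in training are
dropped with a warning.

Performance is the concordance index over pairs with distinct observed
AUC: concordant 1, prediction-tied 0.5, outcome-tied pairs excluded. It is
invariant under strictly increasing transforms of the score.

Cross-validation is 10 repetitions of 10-fold by default, with repetition
$r$ seeded as `seed + r`. Feature selection **and** fitting are re-run
inside every training fold — the held-out fold never influences selection,
and the report retains the per-fold selected features plus fold assignments
so the absence of leakage is directly auditable (the tests recompute the
selection from each fold's training samples and require identity). The
signature size $k$ is chosen from the grid
$\{2, 5, 10, 15, 20, 22, 25, 30, 40, 50\}$ by maximal mean concordance,
ties to the smallest $k$; the best $k$ is data-dependent, not a constant of
the method. A fixed-feature mode (`features =`) reproduces the alternative
protocol in which one feature set, chosen once on the full cohort, is
re-scored under CV; it is provided for comparison but the leakage-free
protocol is primary, since the fixed-feature variant lets test folds
influence selection. The reported 95% CI is mean ± 1.96·SD of the
repetition means.

The deliverable model is refit on the full discovery cohort at the best
$k$ and validated **once** externally. Because discovery and validation
cohorts typically come from different expression platforms, the validation
matrix is z-scored per gene within its own cohort before the linear form is
applied — a deliberately simple harmonization; no cross-cohort model of the
platform effect is attempted.

## The synthetic cohort generator

`generate_cohort()` emulates the geometry of a paired radiogenomics study:
a large discovery cohort (default 511 lines, doses 1, 2, 3, 4, 6, 8 Gy, 23
tissues collapsed here to 8 labels) and a small validation cohort (60
lines, doses 2, 4, 6 Gy) sharing a 2000-gene universe. Choices, fixed once:

* $\alpha \sim N(0.3, 0.1)$ Gy$^{-1}$ floored at 0.01, plus a tissue-level
  shift of SD 0.05 — the 0.1–0.6 Gy$^{-1}$ range typical of clonogenic
  assays, with tissue structure large enough to order tissue medians but
  small relative to line-to-line spread;
* $\alpha/\beta \sim U(5, 15)$ Gy, spanning common tumour values;
* multiplicative lognormal survival noise, $\sigma_S = 0.1$;
* 50 signal genes with effects $|b| \sim U(0.5, 1.5)$ and random sign:
  signal gene $j$ is $b_j\,z(\mathrm{AUC_{true}}) + N(0, 1)$, background
  genes iid $N(0,1)$, giving signal-gene correlations with AUC around
  0.4–0.8 — strong but noisy, as curated radioresponse genes are;
* the validation cohort reuses the discovery signal genes and effect signs
  (this shared biology is exactly what external validation tests) and adds
  a per-gene location ($N(0, 0.5)$) and scale ($U(0.8, 1.25)$) shift to
  mimic the platform gap the within-cohort z-scoring must absorb.

`generate_genesets()` plants pathways that draw ≥ 80% of their members
from signal genes **of one effect sign**, alternating directions across
sets: a pathway whose genes correlate with the response in both directions
would place hits at both ends of the ranked list and carry no running-sum
signal, so direction-coherent planted sets are the meaningful positive
control, mirroring how real pathways enrich positively or negatively. Null
sets are uniform draws from the universe; names (`PLANTED_*`, `NULL_*`)
encode the truth for assertions.

What the simulation does **not** emulate: count-level sequencing noise
(expression is drawn directly on the log scale), correlated gene modules
and co-expression structure, realistic marginal distributions of survival
or AUC beyond order-of-magnitude plausibility, batch effects beyond the
affine platform shift, and any nonlinear gene–response relationships.
Passing the planted-signal tests therefore shows the pipeline recovers a
linear, shared, moderately strong transcriptomic signal under assay-level
noise — not that it would achieve comparable concordance on real cohorts,
where signal is weaker and structured.

## Problem sizes and seeds in the shipped tests

The test suite exercises the full default cohort pair (511/60 lines, 2000
genes, 10×10-fold CV) once, with enrichment at 200 permutations across a
50-set collection; the remaining tests run on small fixtures (tens of
samples, hundreds of genes) chosen to keep the enumeration and grid-search
oracles exact. All stochastic steps are seeded explicitly; identical seeds
give bitwise-identical simulated cohorts and numerically identical pipeline
outputs.

## Known limitations

* The LQ fit weights all log-survival residuals equally; no per-dose
  replicate variance model is used.
* AUC and SF2 are derived from the same fitted curve, so errors in the fit
  propagate to both indicators jointly.
* The permutation null treats genes as exchangeable; correlated gene sets
  inflate the tail slightly relative to a sample-permutation null, which is
  available but slower.
* The signature model is deliberately plain least squares: no shrinkage,
  interactions or nonlinearity, matching the reference analysis rather than
  maximising predictive performance.
* External validation assumes all model features are measured in the
  validation cohort; missing features are an error, not imputed.
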