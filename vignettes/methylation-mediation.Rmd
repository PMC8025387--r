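---
title: "Treatment EWAS and methylation-mediated risk: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Treatment EWAS and methylation-mediated risk: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Survivors of childhood cancer carry persistent marks of their treatment in
blood DNA methylation, and some of those marks plausibly sit on the causal
path from treatment exposure to later cardiometabolic disease. `ewasmed`
implements the full analysis chain for that question:

1. **Quality control** of an array beta-value matrix (detection-p masking,
   missingness filters, quantile normalization, beta-to-M transformation),
   reference-based leukocyte deconvolution, and methylation principal
   components.
2. **Treatment-specific EWAS**: per-CpG linear regression of the M-value on
   each binary exposure, with the adjustment set chosen by a phi-coefficient
   rule, genomic-control correction of the p-values, a strict epigenome-wide
   threshold, dose-response trend tests, paired-exposure scans, and
   annotation-category enrichment.
3. **CHC association**: logistic regression of each chronic health condition
   (CHC) on residual methylation in the incident-only risk set, adjusted for
   age, sex and a polygenic risk score, under BH-FDR control.
4. **Causal mediation**: quasi-Bayesian ACME/ADE estimation per candidate
   CpG, FDR selection, correlation pruning, and a combined methylation score
   whose percent mediation is the headline quantity.

A synthetic-cohort generator with complete ground truth exercises the whole
chain; every stage is also checked against an independent oracle
(normal equations, hat matrix, Newton scoring, product of coefficients,
brute-force greedy scans).

## Models

### EWAS regression

For CpG $j$ and exposure $T$ the model is

$$M_{ij} = \alpha_j + \beta_j T_i + \gamma_j^\top Z_i + \varepsilon_{ij},$$

where $M = \log_2\!\big(\beta/(1-\beta)\big)$ is the M-value and $Z$ contains
sex, age at draw, the co-treatments retained by the phi rule, leukocyte
proportions (one cell type dropped because the six proportions sum to one;
we drop neutrophils, the largest fraction), genetic PCs and the top
methylation PCs. The test on $\beta_j$ is a two-sided t-test; complete cases
are used per CpG.

**Phi rule.** The correlation of two binary exposures is the phi
coefficient, $\phi = (ad-bc)/\sqrt{(a\!+\!b)(c\!+\!d)(a\!+\!c)(b\!+\!d)}$,
with significance from $\chi^2 = n\phi^2$. A co-treatment is *excluded* from
the adjustment set when $\phi > 0.4$ **and** $p < 0.05$: such protocol-linked
exposures are near-collinear with the exposure of interest and adjusting for
them would absorb the signal of interest. (A looser reading — adjust only
when $\phi < 0.4$ and $p > 0.05$ — would also exclude weak, non-significant
correlates; the rule implemented is the one that isolates only the strongly
confounded pairs.)

**Genomic control.** Raw p-values are converted to 1-df chi-square
statistics; the inflation factor is
$\lambda = \mathrm{median}(\chi^2)/0.45494$. When $\lambda > 1$ the
statistics are divided by $\lambda$ and p-values recomputed; deflated scans
are left alone, so the correction never manufactures significance and is
idempotent. The median-based estimator is used (rather than a
regression-based $\lambda$) because it is robust to the handful of true
signals in the tail. Significance is the strict bound
$p_{\mathrm{gc}} < 9\times10^{-8}$, the conventional epigenome-wide 5%
family-wise level for current arrays.

**Dose response.** Cumulative dose is coded ordinally — 0 for unexposed,
1–3 for tertiles of the exposed doses, computed with the $\le$-inclusive
upper boundary so ties go to the lower bin — and the trend p-value is the
t-test on the ordinal coefficient.

### CHC association and residual methylation

Residual M-values are the per-CpG OLS residuals on the non-treatment
covariates (sex, age, cell proportions, PCs). They are exactly orthogonal to
those covariates, so a later logistic model of incident CHC status on the
residual plus age, sex and PRS is not re-adjusting the same variance.
Prevalent cases — onset before the blood draw — are removed from each CHC's
risk set before modelling. Wald p-values are used (likelihood-ratio tests
are an easy substitute but Wald is the convention for per-CpG scans),
BH-FDR across CpGs.

### Polygenic risk scores

Panels of reported risk SNPs are pruned by a greedy scan in input order,
keeping a SNP only when its squared correlation with every kept SNP is
below 0.3, and the score is the unweighted risk-allele count. Input order is
part of the contract: permuting it can change the retained set, so the scan
order (typically the panel file's order) must be fixed upstream.

### Mediation

For treatment $T$, mediator $M^{\mathrm{res}}$ (a residual M-value or a
combined score) and binary outcome $Y$, two models are fitted on the
incident risk set:

- mediator: $M^{\mathrm{res}} = a_0 + a\,T + \text{(other significant
  treatments)} + \varepsilon$,
- outcome: $\operatorname{logit} P(Y=1) = b_0 + c\,T + b\,M^{\mathrm{res}} +
  \text{age} + \text{sex} + \text{PRS} + \text{(other significant
  treatments)}$.

"Other significant treatments" are those with $p<0.05$ in a one-shot
multivariable logistic model of the CHC on all treatments plus age and sex,
additionally filtered by the phi-exclusion rule so that a protocol-linked
co-treatment is never forced into the mediator model.

Effects come from the quasi-Bayesian algorithm: draw parameter vectors from
$\mathcal N(\hat\theta, \widehat{\mathrm{Var}}(\hat\theta))$ of each model;
per draw, simulate counterfactual mediators $M(0), M(1)$ (mean plus a fresh
Gaussian error at the residual SD) and push them through the outcome model
to get potential outcome probabilities $Y(t, M(t'))$. Then

$$\mathrm{ACME}(t) = \mathbb E\big[Y(t, M(1)) - Y(t, M(0))\big], \qquad
\mathrm{ADE}(t) = \mathbb E\big[Y(1, M(t)) - Y(0, M(t))\big],$$

averaged over $t \in \{0,1\}$; the total effect is their sum (this holds
per draw by construction, so the additivity invariant is exact), and the
proportion mediated is ACME/total **on the probability (risk-difference)
scale** — the scale is a genuine choice and is documented here because
ratios on the odds or logit scale differ; the probability scale is the one
under which the identity-link limit reduces to the familiar product of
coefficients $ab/(ab+c)$. For table-style reporting the total effect is also
expressed as the treatment odds ratio from the outcome model refitted
without the mediator. Confidence intervals are two-sided percentile
intervals over draws (not bias-corrected; with 1000 draws the difference is
well inside the Monte-Carlo error), and the ACME p-value is the two-sided
tail frequency, floored at $1/n_{\mathrm{draws}}$.

When ACME and the total effect have opposite signs the proportion mediated
is reported unclamped with a warning flag: clamping to $[0,1]$ would hide a
pathological decomposition.

Significant mediators (ACME FDR < 0.05) are pruned top-down by decreasing
|ACME| (ties broken by CpG id) at a squared-correlation threshold of 0.05 on
their residual M-values, and the survivors are summed into a combined score
that is re-run through the same engine; its percent mediation,
$100 \times \mathrm{ACME}/\mathrm{total}$, is the final summary.

## The synthetic cohort

The generator produces every input the analysis consumes, with ground truth:

- **Treatments.** Correlated binary exposures via a Gaussian copula: each
  target phi is converted to a latent correlation by numerically inverting
  the bivariate-normal orthant probability, so marginal prevalences are
  exact and phi is controlled. Infeasible targets (phi outside the
  Fréchet bounds for the margins) and non-PSD latent matrices are rejected
  with the offending pair named.
- **Methylation.** Per-sample Dirichlet cell proportions (the default
  concentration vector mimics whole blood: neutrophil-dominated) mix
  cell-type reference beta profiles linearly on the beta scale; treatment
  effects are injected **on the M scale** (the analysis scale, so the
  designed $\delta$ is directly comparable to EWAS coefficients) together
  with Gaussian M-scale noise; the result is mapped back to beta and clipped
  to $(0.001, 0.999)$ to keep M finite. Detection p-values are
  Uniform(0, 0.01) with an injectable failure rate.
- **Outcomes.** Logistic models on the treatments, the mediator CpGs'
  residual (baseline-free) M-values, and optional age/sex/PRS terms; a
  configurable fraction of cases is flagged prevalent. The designed
  proportion mediated recorded in the ground truth is the
  product-of-coefficients value $ab/(ab+c)$.
- **Genotypes.** Hardy-Weinberg dosages with optional LD blocks for pruning
  tests.

What the generator does **not** emulate: probe-type chemistry, batch and
chip effects, cell-type-specific treatment effects, age-dependent
methylation drift, and confounding of treatment by diagnosis. Passing
recovery tests on this cohort therefore demonstrates the statistical
machinery is correct under its own assumptions — not that those assumptions
hold in any particular survivor cohort.

### Effect-size defaults

No published effect sizes exist for treatment shifts on the M scale at
single CpGs, so the defaults ($\delta$ between 0.2 and 1.0 M-units,
noise SD 0.5) were chosen once for testability: $\delta = 0.8$ at $n = 500$
gives a per-CpG t-statistic near 18, comfortably past the epigenome-wide
threshold, while $\delta$ near 0.2 is marginal. Mediation designs use a
total treatment logit effect of 0.8 (odds ratio ≈ 2.2) split between the
mediated and direct paths.

## Numerical choices and degenerate inputs

- QC order is mask → drop samples with >5% missing → drop probes with >5%
  missing. Sample-first means one failed sample cannot take good probes down
  with it; the reverse order would. The filter is idempotent.
- Quantile normalization delegates to `limma::normalizeQuantiles`
  (ties get the mean of tied quantiles; missing entries are interpolated at
  the sample's own quantiles and stay masked).
- Beta values exactly 0 or 1 are rejected by the M transform with an error
  instructing upstream clipping, rather than silently producing infinities.
- Deconvolution is nonnegative least squares (`pracma::lsqnonneg`) plus
  renormalization to sum one. In the noise-free limit this equals the
  equality-constrained quadratic program; it avoids a QP dependency and is
  validated to 1e-6 on noise-free mixtures.
- The number of methylation PCs follows the largest relative drop between
  consecutive eigenvalues within the first `k_max`; when the drops are flat
  the fallback is 4, the conventional choice for this design.
- Rank-deficient per-CpG designs are flagged NA and the scan continues;
  complete/quasi-separated logistic fits (Wald SE > 100) are likewise NA.
- All randomness flows from one master seed through fixed per-stage
  substreams, so every generator and the mediation engine are
  bit-reproducible.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script study conditions are desk-scale
versions of a cohort analysis: null calibration uses 500 samples by 5,000
CpGs; power uses 20 injected CpGs at $\delta = 0.8$, $n = 500$, noise
SD 0.5; mediation recovery uses cohorts of 2,000 with designed proportions
{0.10, 0.35, 0.55, 0.70} and 1,000 quasi-Bayesian draws. These sizes give
sampling error small enough for the stated tolerances (e.g. mean absolute
recovery error below 0.08) while keeping a full run in the order of a
minute.

## Known limitations

- The combined score is an additive summary; joint multiple-mediator models
  are out of scope.
- No sensitivity analysis for sequential ignorability: the mediation
  estimates are causal only under no unmeasured mediator-outcome
  confounding.
- CHCs are binary incident indicators; no time-to-event modelling.
- Incidence confidence intervals default to the Wald approximation (Wilson
  available); only the point percentages should be compared across
  implementations, since published CI conventions vary.
- Probe exclusion lists (cross-reactive probes, SNP proximity, sex
  chromosomes) are the user's responsibility via an id list; the package
  ships none.
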