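---
title: "Variance components and genomic prediction in composite cattle: models, simulator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance components and genomic prediction in composite cattle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossvc)
```

## The problem

Composite beef cattle populations (here: a four-type composite built from
zebu **N**, tropically adapted taurine **A**, British taurine **B** and
Continental taurine **C** germplasm) carry systematic non-additive
signal — heterosis and recombination loss — on top of the usual additive
genetic and environmental variation.  Whether those effects belong in the
evaluation model, and whether variance components should be estimated with
the pedigree relationship matrix $\mathbf A$ (BLUP) or the combined
pedigree–genomic matrix $\mathbf H$ (ssGBLUP), changes both the estimated
heritability and the behaviour of predictions for young selection
candidates.  `crossvc` implements the full workflow needed to study that
question: relationship-matrix algebra, crossbreeding covariates, AI-REML
under five fixed-effect rosters, information-criterion comparison, and
LR-method forward validation — together with a population simulator, because
the motivating commercial data sets are proprietary.

## The model

All analyses are single-trait animal models
$$\mathbf y = \mathbf X\boldsymbol\beta + \mathbf Z\mathbf u + \mathbf e,
\qquad \mathbf u \sim N(\mathbf 0, \mathbf K\sigma_u^2),\quad
\mathbf e \sim N(\mathbf 0, \mathbf I\sigma_e^2),$$
with $\mathbf K = \mathbf A$ or $\mathbf H$.  Every roster contains
contemporary group (CG), embryo-transfer status, age at ultrasound and cow
age at calving (linear + quadratic).  The five parameterisations add, in
order: nothing (M1); breed-type fractions and combined heterosis (M2);
plus combined recombination (M3); breed fractions, combined recombination
and the six pair-specific heterosis covariates (M4); breed fractions and
both pair-specific sets (M5).

The crossbreeding covariates come from the sire-side and dam-side breed
fractions $\alpha^s_i, \alpha^d_i$:
$\mathrm{Het}_{ij} = \alpha^s_i\alpha^d_j + \alpha^s_j\alpha^d_i$ (Dickerson),
$\mathrm{Het} = 1 - \sum_i \alpha^s_i\alpha^d_i$,
$\mathrm{Rec} = 1 - \tfrac12\sum_i\big((\alpha^s_i)^2 + (\alpha^d_i)^2\big)$,
and the standard (Kinghorn) pair-specific recombination
$\mathrm{Rec}_{ij} = \alpha^s_i\alpha^s_j + \alpha^d_i\alpha^d_j$,
which satisfies $\sum_{i<j}\mathrm{Rec}_{ij} = \mathrm{Rec}$ exactly.  A
frequently reprinted alternative form of $\mathrm{Rec}_{ij}$,
$(\alpha^s_i+\alpha^d_j)(\alpha^s_j+\alpha^d_i) - \mathrm{Het}_{ij}$, gives
$-1$ for an F1 of two purebreds and cannot sum to the combined coefficient;
it is kept behind `form = "as_printed"` purely for audit and used nowhere.

Design choices in `build_design()` that the model statement leaves open:

* CG dummies absorb the intercept; groups with fewer than 10 records are
  excluded (records dropped), the standard CG filter.
* The four breed fractions sum to 1 and are collinear with the CG block, so
  three of four are fitted; type A (the largest mean fraction) is the
  dropped reference.  A fitted `frac_N` coefficient therefore estimates the
  N-vs-A contrast.
* Age at ultrasound enters as 30-day-bin classes by default (a covariate
  mode exists), cow age as centred linear + quadratic covariates.
* Columns with no variation are dropped with a message (they carry no
  information); genuinely aliased columns raise an error naming them, with
  `on_alias = "drop"` available for pipeline robustness — at small scale
  the twelve M5 pair-specific covariates are frequently near-collinear.

## Relationship matrices

$\mathbf A$ and $\mathbf A^{-1}$ use the tabular method and Henderson's
rules with inbreeding-adjusted Mendelian-sampling variances; inbreeding is
computed by the Meuwissen–Luo algorithm (exact, implemented in C++).  The
genomic matrix is VanRaden method I,
$\mathbf G = \mathbf Z\mathbf Z'/(2\sum_j p_j(1-p_j))$, with observed pooled
allele frequencies, mean-imputation of missing codes (they then contribute
zero after centering), and default blending
$0.95\,\mathbf G + 0.05\,\mathbf A_{22}$ for guaranteed invertibility.  The
single-step inverse is
$$\mathbf H^{-1} = \mathbf A^{-1} +
\begin{bmatrix}\mathbf 0 & \mathbf 0\\
\mathbf 0 & \tau\mathbf G^{-1} - \omega\mathbf A_{22}^{-1}\end{bmatrix},
\qquad \tau = \omega = 1.$$
SNP quality control removes, in order: call rate < 0.90, minor allele
frequency < 0.05, monomorphic markers, and markers whose observed
heterozygote frequency deviates from the Hardy–Weinberg expectation
$2p(1-p)$ by more than 0.15.

## REML and its numerics

The restricted log-likelihood is evaluated through the mixed-model-equation
factorisation,
$$-2\,\ell_R = n\log\sigma_e^2 + q\log\sigma_u^2 + \log|\mathbf K| +
\log|\mathbf C| - \log|\mathbf X'\mathbf X| + \mathbf y'\mathbf P\mathbf y,$$
where $\mathbf C$ is the MME coefficient matrix.  The
$+\log|\mathbf X'\mathbf X|$ term makes the *value* (not only the argmax)
invariant to invertible reparameterisation of the fixed effects; the test
suite checks this identity and the agreement with a dense error-contrast
evaluation to 1e-8.  $\log|\mathbf A|$ is free
($\sum_i \log d_i$ over Mendelian-sampling variances); $\log|\mathbf H|$
comes from a sparse Cholesky of $\mathbf H^{-1}$.

`ai_reml()` iterates average-information updates:

* the AI matrix is computed exactly from the standard quadratic forms
  $\mathrm{AI}_{ij} = \tfrac12 \mathbf f_i'\mathbf P\mathbf f_j$ with
  $\mathbf f_u = \mathbf Z\hat{\mathbf u}/\sigma_u^2$ and
  $\mathbf f_e = \hat{\mathbf e}/\sigma_e^2$ (two extra sparse solves);
* the score is a central finite difference of the likelihood (each
  evaluation is one sparse Cholesky); the EM fallback's trace term
  $\mathrm{tr}(\mathbf K^{-1}\mathbf C^{uu})$ uses the exact identity
  $\partial\log|\mathbf C|/\partial\gamma =
  \mathrm{tr}(\mathbf C^{uu}\mathbf K^{-1})$ with $\gamma = 1/\sigma_u^2$,
  again by central difference — no selected-inverse computation is needed;
* step-halving protects the AI update, an EM step replaces it when it
  leaves the parameter space, and convergence is declared at a relative
  parameter change below 1e-8 or a likelihood change below 1e-9
  (at most 200 iterations);
* standard errors are from the inverse AI matrix at the optimum, the
  heritability SE by the delta method;
* $\hat\sigma_u^2$ collapsing to the 1e-10 bound — or to a numerically
  negligible heritability below 1e-4 — is flagged `boundary`, not raised.

Starting values are $(0.3, 0.7)\,\mathrm{var}(\mathbf y)$.

Model comparison uses $\mathrm{AIC} = -2\ell + 2p$ and
$\mathrm{BIC} = -2\ell + p\log n$ with $p = 2$ estimated variance
components and $n$ the record count — the convention under which the
BIC−AIC gap is $(\log n - 2)\,p$, reproducing published gap values exactly.
REML likelihoods across different fixed-effect rosters are *not* strictly
comparable; the package reproduces that behaviour (including possible
negative likelihood-ratio statistics, reported with a warning) because it
is what the field's software does, and additionally exposes
`reml_loglik(..., restricted = FALSE)` so ML-based comparisons with
$p = p_\mathrm{fixed} + 2$ are available.  Burnham–Anderson support labels
use the quoted cutpoints (≤ 2 substantial, 4–7 considerably less, > 10
essentially none) and label the unnamed gaps (2, 4) and (7, 10]
`intermediate` rather than forcing them into a class.

## LR-method forward validation

`forward_split()` takes the last $k$ (default 2) birth-year cohorts of
phenotyped, progeny-free (and optionally genotyped) animals, removes their
phenotypes from the partial set, and `run_validation()` solves whole and
partial systems at fixed, externally supplied variance components.  The
statistics are
$$\hat\rho_{w,p} = \sqrt{\frac{\mathrm{cov}(\hat u_w, \hat u_p)}
{(1-\bar F)\hat\sigma_u^2}},\qquad
\hat b_{w,p} = \frac{\mathrm{cov}(\hat u_w, \hat u_p)}{\mathrm{var}(\hat u_p)},\qquad
\hat\mu_{w,p} = \frac{\overline{\hat u}_p - \overline{\hat u}_w}{\hat\sigma_u}.$$
Decisions where the published formulas are ambiguous: the accuracy carries
the square root (the LR literature's definition); the bias denominator is
the additive genetic *standard deviation* as the accompanying text states
(`standardise = "variance"` evaluates the literal variance form); $\bar F$
is the validation-cohort mean; $\hat\sigma_u^2$ is the estimate of the
same model/VC source being validated; a negative covariance in the
accuracy is mapped to 0 with a warning.  Self-comparison
($\hat u_p = \hat u_w$) gives $b = 1$, $\mu = 0$ exactly.

A subtlety surfaced by testing: the model-derived counterpart of
$\hat\rho$ is **not** the per-animal reliability
$\sqrt{1 - \mathrm{PEV}_i/((1-\bar F)\sigma_u^2)}$ averaged over animals.
The LR covariance is computed within the validation cohort (centred), so
the consistent oracle is
$\sqrt{\mathrm{tr}(\mathbf J(\mathbf A\sigma_u^2 - \mathbf D)\mathbf J)/
((n-1)(1-\bar F)\sigma_u^2)}$ with $\mathbf D$ the PEV matrix of the
partial fit and $\mathbf J$ the centering projector; the test suite
verifies agreement with both this and a simulation-truth oracle.

## The simulator: what it emulates and what it does not

`sim_config()` defaults describe a rump-fat-like trait in a four-type
composite herd.  Choices fixed once, with their sources:

* **Founder counts** `c(N = 36, A = 80, B = 38, C = 14)`: proportional to
  the reported mean breed fractions (≈ 0.22/0.50/0.24/0.09), so random
  inter-se mating settles near those means and the equilibrium combined
  heterosis $1 - \sum_i \bar\alpha_i^2 \approx 0.66$ — the reported
  population mean.  Realised runs give mean final-cohort heterosis ≈ 0.66
  and mean inbreeding ≈ 0.015–0.02 against the reported 0.015.
* **Variance components** (0.425, 1.937), trait mean 3.9: the published
  M1/BLUP rump-fat estimates and descriptive mean.
* **Mating structure**: each generation uses ~10% of available males as
  sires (bull usage drives relatedness and the mild inbreeding above),
  dams sampled from the previous cohort; 5 generations of ~650 offspring
  by default.
* **Fixed-effect sizes** the source data cannot provide (records are
  proprietary) are set once at plausible magnitudes for a trait with
  phenotypic SD ≈ 1.5: CG SD 0.5, embryo-transfer effect 0.3 (5% of
  calves), 0.004/day of ultrasound age, cow-age regressions (0.08, −0.005),
  breed-type contrasts (−0.5, 0.2, 0.6, 0.4), heterosis 0.4 and
  recombination −0.2 trait units per unit covariate.
* **Breeding values are exactly A-distributed**: founders
  $N(0, \sigma_u^2)$, descendants parent-average plus a Mendelian deviation
  with variance $\tfrac12\big(1 - (F_s + F_d)/2\big)\sigma_u^2$ — required
  for parameter-recovery tests to have the stated truth.
* **Gene dropping over independent loci** (default panel scaled down to
  2,000 SNPs): founder allele frequencies per type uniform on
  (0.05, 0.95), one Mendelian-sampled allele per parent per locus, 1%
  missingness, ~2% of animals genotyped — selectively, the best young
  animals by true breeding value, emulating selective genotyping of
  superior candidates.

Not emulated: linkage/LD (downstream analysis consumes only genotype
covariances, and independence keeps the heterozygosity oracle analytic),
maternal effects, genotype-by-environment, multi-trait correlations,
unknown-parent groups.  A green simulation test therefore establishes
correctness of the estimation machinery under the stated generative world,
not robustness to LD structure or model misspecification beyond what the
directional experiments probe.

## What the package's own experiments show

At desk scale (≈ 1,200–3,400 animals, 30 replicates) the test suite
reproduces the two directional findings: on heterosis-laden data the
fuller roster (M3) attains a lower REML-AIC than M1 in a majority of
replicates, while the LR accuracy of M1 fits is not inferior to M5 fits in
a majority — better fit does not buy better forward prediction.  Under a
correctly specified M1 world at $h^2 = 0.2$ with true variance components,
the 30-replicate mean dispersion $\bar b$ is statistically
indistinguishable from 1 and the mean bias $\bar\mu$ from 0 (these are the
quantities `scripts/acceptance.R` recomputes).  One published arithmetic
check is knowingly left failing: the back-fat ssGBLUP heritability row
rounds to 0.161 from its own printed variance components but is printed as
0.162; the package reports the arithmetic truthfully.

## Known limitations

Single trait, two variance components only; no maternal or permanent
environmental effects; no APY or iteration-on-data solvers (dense
$\mathbf G$/$\mathbf A_{22}$ limit the genotyped set to a few thousand);
REML-likelihood model comparison carries the comparability caveat above;
the simulator's independence assumptions as listed.
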