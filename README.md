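# crossvc

Variance components and genomic prediction for **composite (multi-breed)
beef cattle** populations.

Composite herds — built from zebu (N), tropically adapted taurine (A),
British (B) and Continental (C) biological types and then mated inter se —
carry heterosis and recombination-loss signal on top of additive genetic
variation. Two practical questions follow for anyone running such an
evaluation: *which fixed-effect parameterisation should the animal model
carry*, and *should variance components come from the pedigree relationship
matrix (BLUP) or the single-step pedigree–genomic matrix (ssGBLUP)*?
`crossvc` implements the complete workflow for studying both, plus a
population simulator so everything is testable without proprietary records.

## What it computes

For the single-trait animal model
**y = Xβ + Zu + e**, u ~ N(0, **K**σ²ᵤ), e ~ N(0, **I**σ²ₑ), **K** ∈ {**A**, **H**}:

* **Pedigree algebra** — tabular **A**, sparse Henderson **A⁻¹** with
  inbreeding-adjusted Mendelian-sampling variances, Meuwissen–Luo
  inbreeding (C++), breed-composition propagation, pedigree summaries.
* **Crossbreeding covariates** — Dickerson specific heterosis
  Het₍ᵢⱼ₎ = αˢᵢα<sup>d</sup>ⱼ + αˢⱼα<sup>d</sup>ᵢ, combined heterosis
  Het = 1 − Σᵢ αˢᵢα<sup>d</sup>ᵢ, combined recombination
  Rec = 1 − ½Σᵢ((αˢᵢ)² + (α<sup>d</sup>ᵢ)²) and the pair-specific
  (Kinghorn) recombination, with the exact identities Σ Het₍ᵢⱼ₎ = Het and
  Σ Rec₍ᵢⱼ₎ = Rec.
* **Genomics** — BLUPF90-dialect SNP files, QC (call rate < 0.90,
  MAF < 0.05, monomorphic, heterozygosity deviation > 0.15), VanRaden
  method-I **G**, blending, and the single-step inverse
  **H⁻¹ = A⁻¹ + [0 0; 0 τG⁻¹ − ωA₂₂⁻¹]** (τ = ω = 1).
* **AI-REML** — average-information updates with exact AI quadratic forms,
  EM fallback, step halving, SEs from the inverse AI matrix, delta-method
  heritability SE; five fixed-effect rosters M1–M5 (CG, embryo transfer,
  ultrasound-age classes, cow-age regressions, then breed fractions,
  combined/specific heterosis and recombination).
* **Model comparison** — AIC/BIC (p = 2 variance components, n = records),
  likelihood-ratio tests, Burnham–Anderson support labels.
* **LR-method forward validation** — progeny-free last cohorts, partial vs
  whole fits at fixed variance components, accuracy
  ρ = √(cov(û_w, û_p)/((1−F̄)σ²ᵤ)), dispersion b = cov/var(û_p), bias
  μ = (mean û_p − mean û_w)/σᵤ.
* **Simulator** — 4-type composite pedigrees, exact A-distributed breeding
  values, gene-dropped SNPs, phenotypes under the fullest generative model,
  selective genotyping of top young candidates.

## Worked example

```r
library(crossvc)
cfg <- sim_config(seed = 7, n_snps = 1200, genotyping_fraction = 0.05)
pop <- simulate_population(cfg)
pop
#> Simulated composite population: 3418 animals, 3250 phenotypes, 171 genotyped

hs <- h_structure(pop$ped, pop$geno)      # QC -> G -> blend -> H^-1
sys <- build_design(pop$phen, model_spec("M3", "H"),
                    pop$cov, pop$comp, pop$ped, relmat = hs)
fit <- ai_reml(sys)
fit
#> M3/H: sigma_u2 = 0.4312 (0.0813), sigma_e2 = 1.9920 (0.0725), h2 = 0.178 (0.031)
#>   lnL = -2944.1454 after 6 iterations (converged: TRUE)
```

The generative truth was (σ²ᵤ, σ²ₑ) = (0.425, 1.937) — a rump-fat-like
trait — so the estimates sit within one standard error of the simulated
world. Comparing rosters on the same data:

```r
compare_models(list(M1_H = fit_m1, M3_H = fit))
#>  model      lnL p    n sigma_u2 sigma_e2       h2     aic     bic delta_aic          support
#>   M1_H -2968.07 2 3250 0.487124  1.97993 0.197451 5940.13 5952.30   47.8396 essentially_none
#>   M3_H -2944.15 2 3250 0.431217  1.99195 0.177956 5892.29 5904.46    0.0000      substantial
```

The data carry real heterosis/recombination signal, so the fuller M3 fits
far better (ΔAIC ≈ 48; the M1-vs-M3 LRT is 47.8 on 5 df). Forward
validation of the youngest progeny-free cohort tells the prediction side of
the story:

```r
split <- forward_split(pop$phen, pop$ped, last_k_years = 1)
run_validation(split, model_spec("M1", "A"), pop$ped, pop$cov, pop$comp, fit_m1a)
#> LR validation (n = 650): rho = 0.454, b = 0.818, mu = 0.028
```

ρ is the LR accuracy, b the dispersion (1 = no inflation), μ the
standardised bias (0 = unbiased).

A command-line front end covers the same steps
(`inst/cli/crossvc simulate | covariates | qc | fit | compare | validate |
report`), reading/writing CSV, JSON and BLUPF90-style SNP files.

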