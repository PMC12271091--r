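---
title: "Methods: genetic covariance estimation and DWLS structural models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic covariance estimation and DWLS structural models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery of `gencovsem`: the
estimators, the numerical conventions that are frozen in the code, the
design choices that were genuinely open, and what the synthetic-data tests
do and do not establish.

## 1. From summary statistics to (S, V)

### Harmonization

All estimation runs on a `harmonized_panel`: the intersection of variant
IDs across traits, with every trait's Z-score aligned to the first table's
effect allele. Alleles reconcile by exact match, swap, strand complement,
or complement-swap; swaps negate Z. Strand-ambiguous variants (A/T, C/G)
are always dropped rather than frequency-resolved — the conservative
convention of standard munging tools — and irreconcilable pairs are dropped
and counted. QC removes variants outside [maf_min, 1 − maf_min] (default
0.01) and variants with z² above `chisq_max` (default
max(80, 0.001·median N)) in any trait. Published analyses of this kind typically delegate QC to the munging
tool without printing thresholds, so these defaults are package choices, surfaced in the
provenance sidecars; desk-scale simulations lift `chisq_max` because they
concentrate far more signal per variant than a real million-variant GWAS.

### LD scores

For a reference dosage panel, the LD score of variant *j* is
ℓⱼ = 1 + Σₖ≠ⱼ r̃²ⱼₖ over the window, with the small-sample correction
r̃² = r² − (1 − r²)/(n_ref − 2) applied to every partner term (the self
term is exactly 1). Negative totals are truncated at 0; monomorphic
variants get score 0 with a warning. Windows are variant counts by default
or base pairs with sorted positions. On panels of ≤ 100 variants the
implementation is tested for exact agreement with a brute-force double loop.

### LDSC regressions

Each moment of S comes from a two-parameter weighted regression. The
response is z²ₐⱼ (diagonal) or zₐⱼ·z_bⱼ (off-diagonal); the regressor is
xⱼ = √(Nₐ N_b)·ℓⱼ/M, so the slope *is* h² or ρ_g without rescaling and the
free intercept absorbs confounding (1 + N·c) or sample overlap
(ρ·N_s/√(Nₐ N_b)). Intercepts are free by default because several source
GWAS share a cohort; a config switch fixes them (1 for h², 0 for ρ_g).

Weights are the standard heteroskedasticity/overcounting form
1/(ℓⱼ·(1 + Nₐh²ₐℓⱼ/M)(1 + N_b h²_b ℓⱼ/M)), with provisional h² values from
an unweighted first pass; the h² case reduces to the familiar
1/(ℓ·(1 + Nh²ℓ/M)²). Weights are computed once from the full data and held
fixed across jackknife blocks, so delete-one-block estimates are cheap
block-sum arithmetic. A `weights = "unit"` mode exists for the
hand-computable closed-form examples in the tests.

### Block jackknife and V

`build_S_V` re-estimates every element of vech(S) — lower triangle,
column-major, a frozen and tested convention — in one shared
leave-one-block-out jackknife (default 200 contiguous equal-sized blocks,
reduced when variants are scarce, never below 2). V is the jackknife
covariance of the delete-block estimate vectors, so it captures
cross-element dependence from shared variants and overlapping samples; its
diagonal equals the squared pairwise jackknife SEs by construction (tested
to 1e−10). `to_correlation` rescales S to genetic correlations and
transforms V by the exact delta-method Jacobian; diagonal moments become
constants with zero sampling variance, which is why model fitting runs on
the covariance scale. Indefinite S or V are repaired by eigenvalue
truncation at 1e−8 × the largest eigenvalue — large enough for numerical
stability, small enough not to move estimates (the maximum element change
is logged).

## 2. DWLS model fitting

Models are declared in a lavaan-flavoured syntax (`F =~ a + b`, `x ~~ y`,
`y ~ x1 + x2`, `0*`-prefixed fixed constants) and assembled in RAM form:
directed paths (loadings, regressions) in A, variances/covariances in S*,
implied covariance Σ = F(I−A)⁻¹S*(I−A)⁻ᵀFᵀ. Single-indicator variables ride
along as observed rows of the RAM matrices, which makes the "factor
correlates with observed trait" structure of the shipped models a plain
S*-entry. Latents are identified by unit variance by default — matching how
standardized loadings and the fixed-zero factor covariance are reported —
with marker-loading identification available.

The fit function is F(θ) = Σᵢ (sᵢ − σᵢ(θ))²/Vᵢᵢ. Minimization is
quasi-Newton (`nlminb`) with an *analytic* moment Jacobian derived from the
RAM algebra (outer products of rows of (I−A)⁻¹), validated in the tests
against finite differences; on non-convergence, up to 10 jittered restarts
from scale-aware heuristic starts (loadings from mean absolute
within-factor covariances, residuals at half the observed variance). A
final BFGS polish verifies stationarity: nlminb's convergence code is
pessimistic on the flat objectives that df = 0 models produce, so a point
the second optimizer cannot improve is accepted as converged.

Standard errors are full-V sandwich estimates; p-values are two-sided
normal, unadjusted; raw p-values are the reporting convention for these
models.
`standardize_solution` rescales every estimate to the correlation metric
via the model-implied variances and transforms SEs by the delta method on
the sandwich covariance.

### The model χ²

The raw weighted residual sum F(θ̂) is not χ²-referenced under DWLS. The
package applies a trace-based mean correction: with
U = W − WΔ(ΔᵀWΔ)⁻¹ΔᵀW and W = diag(V)⁻¹, the statistic is
df · F(θ̂) / tr(UV), whose expectation under the model is df. This was the main
under-specified numerical choice — reference implementations are not
explicit about which variant they print — so the correction is validated by
simulation (mean χ² ≈ df under correctly specified models over replicate
fits) and `correction = "none"` exposes the uncorrected statistic.

### Fit indices

CFI = 1 − max(χ²_m − df_m, 0)/max(χ²_0 − df_0, χ²_m − df_m, 0) against an
independence baseline that frees only variances. SRMR is the root mean
square of correlation-scale residuals over all K(K+1)/2 unique moments,
*including* diagonal residuals, standardizing both S and Σ(θ̂) by the
observed standard deviations; implementations differ on whether the
diagonal enters, so this convention is frozen here and documented.
AIC = χ² + 2q, comparable across models fitted to the same S only.
Verdicts follow the stated thresholds: CFI > 0.95 good, ≥ 0.90 acceptable,
SRMR < 0.08.

## 3. The shipped models

The correlated-factor model: a common-impulsivity factor over six UPPS-P /
BIS subscales (negative urgency, positive urgency, premeditation,
attentional, motor, non-planning), an urgency-specific factor over the two
urgency scales with its covariance to common impulsivity fixed at zero, a
single factor over the four substance-use disorders, and delay
discounting, sensation seeking, lack of perseverance and anorexia nervosa
as single indicators; all other covariances free (q = 46, 105 moments,
df = 59). Published variants of this model family differ on whether the
BIS attentional and motor subscales enter the common factor; six
indicators is the default here, and the indicator lists are config
switches rather than silent choices. The regression model replaces the outcome's
covariances with six directed paths plus a free residual — an exact
re-parameterization, so both models share one χ² (asserted in tests). All
six predictors enter jointly: reported coefficient sets for this model
family include the single indicators alongside the factors. Delay discounting is
oriented so higher scores mean steeper discounting; the replication report
exposes the outcome–DD correlation so the expected negative sign is
checkable.

Case-control traits are represented by user-supplied effective sample
sizes with no liability-scale conversion: correlations, standardized
loadings and paths are invariant to trait-wise rescaling, which is all the
shipped models report.

## 4. The synthetic world

`make_architecture("an_impulsivity")` states the world the acceptance tests
live in: 14 traits, the three-factor structure above with a fixed-zero
urgency/common-impulsivity covariance, genetic correlations chosen to match
published estimates for these trait pairs (outcome–DD −0.19,
outcome–perseverance −0.15, outcome–SUD +0.07), SNP heritabilities of
0.06–0.12 (typical for questionnaire and case-control psychiatric traits),
N = 50,000 per trait and M = 10,000 causal variants (desk scale; the
source's cohorts are 72k–903k on ~1M variants), full sample overlap among
the nine questionnaire traits with phenotypic correlations at 0.3 × the
genetic ones, and LD scores 1 + Gamma(3, 10). These values were chosen once
and are not tuned against test outcomes.

Two generators emulate this world. The *direct* mode draws per-variant
z-vectors exactly from the bivariate LDSC model via the decomposition
Σⱼ = E + ℓⱼG (E the overlap-intercept matrix, G the scaled genetic
covariance), which is fast, exact, and PSD by construction. The *forward*
mode simulates block-autocorrelated haplotypes, Gaussian infinitesimal
effects with Cov = Σ_g/M, phenotypes, and per-variant regression Z-scores,
exercising the readers and LD-score stage end to end; it supports
zero-or-full pairwise overlap only, and case-control traits via a liability
threshold with point-biserial Z approximation. The two modes are checked
against each other in distribution.

What a green suite establishes: the estimators recover the parameters of
data generated under their own model assumptions, with calibrated
uncertainty (pooled 2-SE coverage ≥ 90% across 100 seeds; ~5% null
rejection rate), and the algebraic components match independent oracles
exactly. What it does not establish: behavior under real LD structure, MAF
and annotation heterogeneity, uncorrected population stratification,
liability-scale effects, or non-European panels — none of which the
generator emulates.

## 5. Known limitations

- No partitioned (annotation-stratified) LD-score regression; no
  cross-ancestry support.
- No ML/GLS estimation and no SNP-level multivariate GWAS; DWLS only.
- The χ² mean-correction variant and the SRMR diagonal convention are
  frozen package choices validated in simulation, not against an external
  reference fit; a config switch exposes the
  uncorrected χ².
- Recovery coverage criteria are evaluated pooled over (element, replicate)
  events — the "jointly calibrated" reading — because per-element joint
  coverage at 2 SE is not a statistically attainable bar with 46–105
  simultaneous elements.
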