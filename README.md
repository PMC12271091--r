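# gencovsem

Genomic structural equation modeling from GWAS summary statistics, in R.

`gencovsem` is for statistical geneticists who want to go from per-trait
GWAS summary statistics to fitted multivariate genetic models without
individual-level data. It implements the two-stage approach used throughout
the psychiatric-genetics literature:

1. **LD-score regression** estimates each trait's SNP heritability and every
   pairwise genetic covariance from summary statistics plus reference-panel
   LD scores, assembling a K×K genetic covariance matrix **S** together with
   the sampling covariance **V** of its unique elements from a single block
   jackknife (so V captures cross-element dependence, including the
   covariance induced by overlapping GWAS samples).
2. **Diagonally weighted least squares (DWLS)** fits latent-variable
   structural models to (S, V), with full-V sandwich standard errors, a
   mean-corrected model χ², and CFI / SRMR / AIC fit indices.

## The model

For trait *a* and variant *j* with LD score
ℓⱼ = Σₖ r²ⱼₖ, LD-score regression uses

    E[z²_aj]        = 1 + N_a·c + (N_a h²_a / M) ℓⱼ
    E[z_aj · z_bj]  = (√(N_a N_b) ρ_g,ab / M) ℓⱼ + ρ N_s / √(N_a N_b)

so the slope of the (weighted) regression on ℓⱼ recovers h² (diagonal of S)
or the genetic covariance ρ_g (off-diagonal), while the free intercept
absorbs confounding and sample overlap. A leave-one-block-out jackknife
over contiguous variant blocks gives V.

A structural model Σ(θ) — loadings Λ, latent covariances Ψ, regressions B,
residuals Θ in RAM form — is then fitted by minimizing

    F(θ) = Σᵢ (sᵢ − σᵢ(θ))² / Vᵢᵢ

over the half-vectorized moments, with sandwich covariance
(ΔᵀD⁻¹Δ)⁻¹ ΔᵀD⁻¹ V D⁻¹ Δ (ΔᵀD⁻¹Δ)⁻¹ for θ̂ (D = diag V, Δ = ∂σ/∂θ).

The package ships the two models from the anorexia-nervosa /
impulsivity / substance-use-disorder analysis it was built around: a
correlated-factor model (common impulsivity; an orthogonal urgency-specific
factor; a single SUD factor; delay discounting, sensation seeking, lack of
perseverance and AN as single indicators) and a multiple regression of AN
on all six predictors. A synthetic-data module simulates summary statistics
under a known factor-structured genetic architecture so the whole pipeline
is testable offline.

## Worked example

Simulate three genetically correlated traits, build (S, V), and fit a
one-factor model:

```r
library(gencovsem)
arch  <- make_architecture("small", M = 2000, N = 20000, seed = 7)
ld    <- make_ld_table(arch$M, 7)
panel <- harmonize(simulate_sumstats_direct(arch, ld))
sv    <- smooth_sv(build_S_V(panel, ld, n_blocks = 100))
print(sv)
#> sv_matrices: 3 traits, 100 jackknife blocks (smoothed)
#> S:
#>        X1     X2     X3
#> X1 0.2781 0.1117 0.1304
#> X2 0.1117 0.1945 0.0921
#> X3 0.1304 0.0921 0.2129
```

The diagonal of S holds the estimated SNP heritabilities (true values 0.30,
0.25, 0.20), the off-diagonals the genetic covariances. `to_correlation(sv)`
rescales to genetic correlations (here 0.48–0.54 against true 0.42–0.56).

```r
fit <- fit_dwls(sv, parse_model("F =~ X1 + X2 + X3"))
print(fit)
#> fit_result: chisq(0) = 0.000 (p = NA), converged = TRUE
#>        estimate     se      p
#> F=~X1    0.3978 0.0758 0.0000
#> F=~X2    0.2807 0.0612 0.0000
#> F=~X3    0.3279 0.0601 0.0000
#> ...
round(standardize_solution(fit)$estimates, 3)
#>  F=~X1  F=~X2  F=~X3 X1~~X1 X2~~X2 X3~~X3
#>  0.754  0.637  0.711  0.431  0.595  0.495
```

The standardized loadings are the correlations of each trait's genetic
component with the shared factor; the residual entries are the proportions
of genetic variance not explained by it. A three-indicator one-factor model
is just-identified, hence χ² = 0 on 0 df.

The full 14-trait analysis runs through `replicate_models(sv)` (or the CLI:
`Rscript inst/cli/gencovsem-cli.R replicate --out DIR ...`), which fits the
correlated-factor and AN-regression models, standardizes both solutions,
applies the CFI ≥ 0.90 / SRMR < 0.08 thresholds, and writes a JSON +
markdown report.

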