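# flockconnect

Genetic connectedness diagnostics for animal-model BLUP evaluations,
computed exactly from the variance–covariance matrix of estimated fixed
effects alone.

## The problem

In livestock genetic evaluation, breeding values of animals in different
contemporary groups (CGs — management units such as flock–sex–year classes)
are only comparable when the groups are genetically connected, typically
through shared link sires. The accepted way to quantify connectedness is
through the prediction error variance–covariance matrix of breeding values,
PEV = Var(û − u), averaged by contemporary group:

    PEVMean = (X₁′X₁)⁻¹ X₁′Z · PEV · Z′X₁ (X₁′X₁)⁻¹

from which pairwise statistics follow: PEVD (prediction error variance of a
CG mean difference), the flock correlation r, and the coefficient of
determination CD of CG contrasts. The obstacle is that PEV is the q × q
random-effect block of the mixed-model-equation inverse, with q the number
of animals — prohibitive at evaluation scale. The cheap alternatives, VED
and the connectedness rating CR, use Var(β̂₁), the p₁ × p₁ variance matrix
of estimated CG effects, but they are approximations that degrade when
other fixed effects are fitted.

## The method

This package implements the exact correction. With the intercept absorbed
into the CG effect, X = [X₁ X₂] (X₂ the other fixed effects) and
W = (X₁′X₁)⁻¹X₁′X₂:

* **CG-only models:** PEVMean = Var(β̂₁) − σ²ₑ (X₁′X₁)⁻¹ — subtract the
  record-count correction σ²ₑ/nᵢ from each diagonal.
* **Any fixed effects:** PEVMean = Var(β̂₁) + W Var(β̂₂) W′ +
  W Var(β̂₂, β̂₁) + Var(β̂₁, β̂₂) W′ − σ²ₑ (X₁′X₁)⁻¹.

Only the (p₁+p₂)-dimensional fixed-effect block of the mixed-model-equation
inverse is required — obtained by solving C B = [I_p; 0] — never the q × q
PEV block. The post-solve cost is 2p₁ + 6p₁² + p₁p₂(2p₁ + p₂) operations,
independent of the number of animals.

Around this core the package provides: pedigree numerator relationship
matrices and their sparse inverses (Meuwissen–Luo with exact inbreeding),
genomic relationships (VanRaden method 1) and single-step H⁻¹ (Aguilar),
Henderson MME assembly and block solving, the full family of pairwise
statistics (PEVD, flock r, VED, corrected VED, CR, CD), model diagnostics
(correction-factor trace, covariance ratio between nested models, marginal
r² and Wald r²), and a synthetic multi-flock simulator with gene-dropped
genotypes so everything is testable end to end.

## Worked example

```r
library(flockconnect)

sc <- sim_scenario(n_cgs = 5, offspring_per_cg = 20, link_sire_fraction = 0.4,
                   factor_levels = 3, covariate_means = 20, covariate_sds = 4,
                   covariate_slopes = 0.3, seed = 42)
herd <- simulate_herd(sc)
fit <- fit_connectedness(herd$records, herd$pedigree,
                         sigma_g2 = 1.81, sigma_e2 = 7.43,
                         factors = "factor1", covariates = "cov1")
fit
#> <conn_fit> relationship = A | p1 = 5 , p2 = 3 , q = 280 , n = 200
#>   lambda = 4.10497 | max |function3 - direct PEVMean| = 1.22e-15
#>   pairwise report: 10 contemporary-group pairs

tidy(fit)[1:5, c("cg_i", "cg_j", "pevd", "flock_r", "corrected_ved", "cr", "cd")]
#>   cg_i  cg_j   pevd flock_r corrected_ved    cr     cd
#> 1 CG01  CG02  0.259   0.163         0.263 0.798 0.127
#> 2 CG01  CG03  0.258   0.118         0.261 0.800 0.0977
#> 3 CG01  CG04  0.259   0.121         0.288 0.808 0.142
#> 4 CG01  CG05  0.248   0.155         0.254 0.804 0.146
#> 5 CG02  CG03  0.241   0.208         0.242 0.809 0.122

glance(fit)[, c("p1", "p2", "q", "correction_trace", "r2_marginal",
                "op_count", "max_dev_direct")]
#>   p1 p2   q correction_trace r2_marginal op_count max_dev_direct
#> 1  5  3 280           -6.559      0.3071      355      1.221e-15
```

Reading the output: `max_dev_direct` is the largest absolute deviation
between PEVMean computed through the fixed-effect block and PEVMean
averaged from the explicitly extracted PEV — at machine precision, as the
identity predicts. `pevd` is in trait units squared (small = the CG mean
difference is well predicted); `flock_r` and `cr` are correlations (the CR
approximation here sits far above the exact flock correlation, the
distortion the correction factor removes); `corrected_ved` approximates
`pevd` and matches it exactly when no other fixed effects are fitted;
`cd` ∈ [0, 1] rates each CG contrast against its prior variance. The
`correction_trace` of −6.56 says the extra fixed effects materially distort
Var(β̂₁) here, so the uncorrected approximations should not be trusted.

`autoplot(fit, statistic = "flock_r")` draws the pairwise heatmap. A thin
command-line wrapper is installed at `inst/cli/connect`
(`connect simulate | fit | diagnose`).

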