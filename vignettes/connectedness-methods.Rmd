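---
title: "Exact contemporary-group connectedness from the fixed-effect variance matrix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact contemporary-group connectedness from the fixed-effect variance matrix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flockconnect)
```

## The model

flockconnect works with the single-trait animal model

$$y = X_1\beta_1 + X_2\beta_2 + Zu + e, \qquad
u \sim N(0, \sigma^2_g K), \quad e \sim N(0, \sigma^2_e I),$$

where $\beta_1$ are contemporary-group (CG) fixed effects with the
intercept absorbed (so $X_1$ is a full 0/1 incidence matrix and $X_1'X_1$
is diagonal with the CG record counts $n_i$), $\beta_2$ are any other fixed
effects, $Z$ maps records to animals, and $K$ is either the pedigree
numerator relationship matrix $A$ or the single-step matrix $H$ combining
pedigree and genomic information. Variance components are taken as known
inputs; the package performs no REML estimation. The residual covariance is
$\sigma^2_e I$ throughout — a single trait, one record type, no
heterogeneous variances.

Connectedness between CGs is quantified through the prediction error
variance–covariance matrix $PEV = Var(\hat u - u)$ averaged by CG,

$$\overline{PEV} = (X_1'X_1)^{-1}X_1'Z \; PEV \; Z'X_1(X_1'X_1)^{-1},$$

and the derived pairwise statistics: $PEVD_{ij}$ (variance of the
prediction error of the CG mean difference), the flock correlation
$r_{ij}$, and the coefficient of determination $CD$ of a CG contrast. The
classical cheap surrogates VED and CR apply the same difference/correlation
forms to $Var(\hat\beta_1)$ instead.

## The exact identity

Taking variances through the fixed-effect equations of Henderson's mixed
model equations and absorbing the intercept gives, with
$W = (X_1'X_1)^{-1}X_1'X_2$,

$$\overline{PEV} = Var(\hat\beta_1)
 + W\,Var(\hat\beta_2)\,W'
 + W\,Var(\hat\beta_2,\hat\beta_1)
 + Var(\hat\beta_1,\hat\beta_2)\,W'
 - \sigma^2_e (X_1'X_1)^{-1}.$$

When CG is the only fixed effect the three $W$ terms vanish and the
identity reduces to subtracting $\sigma^2_e/n_i$ from each diagonal. The
package exposes three estimators named for what they use:
`pevmean_function1()` ($Var(\hat\beta_1)$ unchanged — an approximation),
`pevmean_function2()` (record-count correction — exact for CG-only models),
and `pevmean_function3()` (the full identity — exact always). The three
$W$ terms are available separately as `correction_factor()`.

The computational point is that the identity needs only the
$(p_1+p_2)$-dimensional fixed-effect block of the MME inverse, obtained by
solving $C\,B = [I_p; 0]$ against the sparse coefficient matrix, never the
$q \times q$ PEV block. The post-solve cost is
$2p_1 + 6p_1^2 + p_1p_2(2p_1+p_2)$ operations (`op_count()`), independent
of the number of animals. `extract_pev()` still materialises the dense PEV
block — deliberately, as the validation oracle — but refuses beyond a
configurable animal limit (default 5,000).

## Relationship matrices

* `build_A()` uses the tabular recursion (dense, intended for moderate
  pedigrees and as an in-package oracle).
* `build_A_inverse()` assembles the sparse inverse directly from per-animal
  Mendelian sampling variances, with exact inbreeding coefficients from the
  ancestor-tracing recursion (`inbreeding()`); the two routes are checked
  against each other in the test suite.
* `build_G()` is VanRaden's first method,
  $G = MM'/(2\sum_j p_j(1-p_j))$ with $M$ the dosage matrix centred by
  $2p_j$. Allele frequencies default to the observed sample frequencies; a
  base-population override is accepted. Monomorphic markers are dropped
  with a message.
* `blend_G()` returns $wG + (1-w)A_{22}$, default $w = 0.95$ — standard
  single-step practice guaranteeing invertibility; $w = 1$ is a no-op used
  by the null tests.
* `build_H_inverse()` adds $G^{-1} - A_{22}^{-1}$ into the genotyped block
  of $A^{-1}$, with the $\tau/\omega$ scalings fixed at 1. When
  $G = A_{22}$ exactly, $H^{-1} = A^{-1}$, which is the end-to-end null
  test that the genomic path changes nothing it should not.

Unknown parents are coded `"0"` and treated as unrelated, non-inbred base
animals — the standard animal-breeding convention. Pedigrees are ordered
internally (stable topological sort, input order preserved when already
valid); animals appearing only as parents are promoted to founders with a
message rather than corrupting indices silently.

## Parameters that matter

| Parameter | Units | Default | Role |
|---|---|---|---|
| `sigma_g2`, `sigma_e2` | trait² | 1.81, 7.43 | variance components; their ratio $\lambda = \sigma^2_e/\sigma^2_g$ (4.105 at the defaults, heritability 0.20) scales $K^{-1}$ in the MME |
| `blend_weight` | — | 0.95 | genomic blending fraction |
| `dense_limit` | animals | 5000 | upper bound for dense PEV extraction and dense A |
| `eps_var` | trait² | 1e-12 | guard on near-zero PEVMean diagonals; affected pairs are flagged, not silently computed |

The defaults for the variance components are the live-weight values used
throughout the simulator, so simulated traits are in kilogram-like units.

## Design choices in ambiguous territory

* **X₂ coding.** With the intercept absorbed into $X_1$, every categorical
  in $X_2$ uses drop-first (treatment) coding. Any full-rank coding leaves
  the exact identity intact; drop-first keeps $X_1$ a pure CG incidence
  matrix, which the derivation requires. Full column rank of $[X_1\,X_2]$
  is verified and a confounded column is a named error.
* **Covariate centring** is the global mean (and sd, if standardising),
  not per-CG: centring per CG would itself enforce orthogonality and hide
  the behaviour the correction factor exists to expose.
* **Averaging weights.** $(X_1'X_1)^{-1}X_1'Z$ averages over records, so an
  animal with several records would be weighted by its record count. The
  simulator emits one record per animal, so this distinction is untested
  by default.
* **Wald r².** `r2_beta()` forms $F = \hat\beta'Var(\hat\beta)^{-1}
  \hat\beta / p$ and returns $(q-1)F/(\nu + (q-1)F)$ with $q = p$ (the
  number of estimated fixed effects) and $\nu = n - p$. Whether $\nu$
  should also subtract random-effect degrees of freedom is genuinely open;
  the $q = p$ convention is used consistently and surfaced here rather
  than guessed per call. `r2_marginal()` uses the population
  (divide-by-$n$) variance of $X\hat\beta$.
* **Covariance ratio** (`covariance_ratio()`) is computed on the CG block
  $Var(\hat\beta_1)$ only, via log-determinant differences.
* **Genetic groups / phantom parents** are not modelled; unknown parents
  are plain base animals.

## Numerical choices

The MME are assembled on the $\lambda$ scale and variance blocks multiplied
back by $\sigma^2_e$; sign or scale errors here would silently corrupt the
correction terms, so the convention is fixed in one place
(`assemble_mme()`). Solves are exact (sparse Cholesky/LU through Matrix);
no iterative solvers, since approximation error would be indistinguishable
from a broken identity. Singularity is diagnosed by a sparse 1-norm
condition estimate with threshold $10^{12}$, which separates confounded
designs from merely ill-scaled covariates. The function-3 output is
symmetrised as $(M + M')/2$; asymmetry beyond $10^{-8}$ relative is an
error rather than silently absorbed. The flock correlation and CR return
`NA` (and a `flagged` row in the report) when a diagonal sits at or below
the $10^{-12}$ guard.

## The simulator, and what passing tests do not show

`simulate_herd()` emulates a multi-flock sheep evaluation: founders split
across flocks, discrete generations, flock dams, and sires drawn either
from the flock or from a shared link-ram team with probability
`link_sire_fraction` — 0 gives exactly disconnected flocks, which the
tests exploit (all cross-flock PEVMean entries are then structural zeros).
Breeding values use the pedigree recursion
$u_i = (u_s + u_d)/2 + m_i$ with Mendelian sampling variance
$\sigma^2_g(0.5 - 0.25(F_s + F_d))$ using exact parental inbreeding, so
the replicate covariance of $u$ is exactly $\sigma^2_g A$ — not the
non-inbred approximation. Genotypes are gene-dropped at independent
markers with founder frequencies from Uniform(0.1, 0.9). Scenario defaults
(8 flocks, 25 offspring per flock and generation, $\sigma^2_g = 1.81$,
$\sigma^2_e = 7.43$, CG effect sd 2 kg, covariates resembling a weaning
weight of 20 ± 4 kg with slope 0.3) are fixed once as a realistic
desk-scale herd; identical scenario and seed reproduce the data exactly.

What the simulator does not emulate: selection and non-random mating,
overlapping generation structure in the records, multiple records per
animal, linkage between markers, genotype–environment structure, and
genetic groups. The exactness results are algebraic identities and so
carry over to real data unchanged, but the *magnitudes* of CR/VED
distortion, correction traces and CD values observed on simulated herds
say nothing quantitative about any real evaluation.

One subtlety the tests make explicit: for disconnected flocks the flock
correlation is exactly zero, but CD of a cross-flock contrast is exactly
zero only when recorded animals are unrelated within flocks. With
within-flock pedigree structure, relatives let the flock-mean breeding
value be partially predicted even though no cross-flock comparison is
possible, so CD stays slightly positive — a reminder that CD mixes
within- and between-group information.

## Problem sizes used in validation

The acceptance suite runs five scenarios of roughly 340–1,400 animals with
5–40 contemporary groups and 1–3 extra fixed effects, under both $A$ and
$H$, asserting element-wise agreement of the fixed-effect-block PEVMean
with the directly averaged PEV at $10^{-8}$ relative; 50 random pedigrees
of 60–500 animals (with inbreeding loops) for the sparse-inverse check at
$10^{-8}$; dense GLS oracles at $10^{-7}$ on instances up to 300 animals;
and 500 Monte-Carlo replicates for the breeding-value covariance at
$0.1\,\sigma^2_g$. These sizes were chosen so the whole suite validates
every claim in well under a minute of linear algebra while still spanning
the regimes (many small CGs, few large CGs, genomic subset) where the
identities could plausibly break.

## Known limitations

Single trait, single random effect, homogeneous residual variance; no
REML; no APY or other approximate inverses; CD only for CG mean-difference
contrasts; dense $A$/PEV oracles capped at 5,000 animals. For national-
scale evaluations the fixed-effect-block route is the supported path, and
the dense validation machinery is intentionally out of reach.
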