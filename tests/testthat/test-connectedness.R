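vc <- list(g = 1.81, e = 7.43)

multi_effect_fit <- function(seed = 70, ...) {
  sc <- sim_scenario(n_cgs = 5, offspring_per_cg = 12,
                     factor_levels = 3, covariate_means = 20,
                     covariate_sds = 4, covariate_slopes = 0.3,
                     seed = seed, ...)
  quick_fit(sc, factors = "factor1", covariates = "cov1")
}

test_that("direct PEVMean equals the explicit row-averaging oracle", {
  qf <- multi_effect_fit()
  fit <- qf$fit
  pev <- extract_pev(fit$system)
  idx <- match(qf$herd$records$animal, qf$herd$pedigree$animal)
  oracle <- pevmean_avg_oracle(pev, qf$herd$records$cg, idx,
                               fit$design$cg_labels)
  expect_lt(max(abs(fit$pevmean_direct - oracle)), 1e-10)
})

test_that("one CG holding all records averages the whole PEV block", {
  sc <- sim_scenario(n_cgs = 1, offspring_per_cg = 10, seed = 71)
  herd <- simulate_herd(sc)
  fit <- fit_connectedness(herd$records, herd$pedigree, vc$g, vc$e)
  pev <- extract_pev(fit$system)
  idx <- match(herd$records$animal, herd$pedigree$animal)
  expect_equal(fit$pevmean_direct[1, 1], mean(pev[idx, idx]),
               tolerance = 1e-10)
})

test_that("CG-only models: function 2 is exact, function 1 exact off-diagonal", {
  sc <- sim_scenario(n_cgs = 6, offspring_per_cg = 10, seed = 72)
  qf <- quick_fit(sc)
  fit <- qf$fit
  direct <- fit$pevmean_direct
  fn1 <- pevmean_function1(fit$var_beta$vb1)
  fn2 <- pevmean_function2(fit$var_beta$vb1, fit$design$n_per_cg, vc$e)
  expect_lt(max(abs(fn2 - direct)), 1e-8)
  off <- upper.tri(direct)
  expect_lt(max(abs(fn1[off] - direct[off])), 1e-8)
  # function-1 diagonals exceed the exact ones by sigma_e2 / n_i
  expect_equal(unname(diag(fn1) - diag(direct)),
               unname(vc$e / fit$design$n_per_cg), tolerance = 1e-8)
})

test_that("function 3 reproduces the direct PEVMean with other fixed effects", {
  for (seed in c(73, 74)) {
    fit <- multi_effect_fit(seed)$fit
    expect_lt(max(abs(fit$pevmean - fit$pevmean_direct)),
              1e-8 * (1 + max(abs(fit$pevmean_direct))))
    expect_identical(attr(fit$pevmean, "source"), "function3")
  }
})

test_that("function 2 + correction factor = function 3, exactly", {
  fit <- multi_effect_fit(75)$fit
  fn2 <- pevmean_function2(fit$var_beta$vb1, fit$design$n_per_cg, vc$e)
  corr <- correction_factor(fit$var_beta, fit$design)
  expect_equal(unclass(fit$pevmean)[, ], unclass(fn2)[, ] + corr,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("orthogonal designs need no other-effects correction", {
  # covariate balanced to zero mean within every CG: X1'X2 = 0
  ped <- order_pedigree(data.frame(animal = as.character(1:12),
                                   sire = "0", dam = "0"), quiet = TRUE)
  set.seed(76)
  rec <- tibble::tibble(
    animal = as.character(1:12),
    cg = rep(c("A", "B", "C"), each = 4),
    bal = rep(c(-2, -1, 1, 2), 3),
    y = rnorm(12, 10, 3)
  )
  fit <- fit_connectedness(rec, ped, vc$g, vc$e, covariates = "bal")
  expect_true(check_orthogonality(fit$design))
  corr <- correction_factor(fit$var_beta, fit$design)
  expect_lt(max(abs(corr)), 1e-10)
  fn2 <- pevmean_function2(fit$var_beta$vb1, fit$design$n_per_cg, vc$e)
  expect_equal(unclass(fit$pevmean)[, ], unclass(fn2)[, ],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("PEVD matches the record-contrast quadratic form", {
  qf <- multi_effect_fit(77)
  fit <- qf$fit
  pev <- extract_pev(fit$system)
  dm <- fit$design
  Z <- as.matrix(dm$Z)
  X1 <- as.matrix(dm$X1)
  for (pair in list(c(1, 2), c(2, 4))) {
    x <- X1[, pair[1]] / dm$n_per_cg[pair[1]] -
      X1[, pair[2]] / dm$n_per_cg[pair[2]]
    oracle <- as.numeric(t(x) %*% Z %*% pev %*% t(Z) %*% x)
    expect_equal(pevd(fit$pevmean_direct, pair[1], pair[2]), oracle,
                 tolerance = 1e-8)
  }
  expect_error(pevd(fit$pevmean, 2, 2), "distinct")
})

test_that("disconnected unrelated singleton groups hit the closed forms", {
  fit <- unrelated_two_cg(1, 1)
  pm <- fit$pevmean_direct
  expect_equal(pevd(pm, 1, 2), 2 * vc$g, tolerance = 1e-9)       # 3.62
  expect_equal(ved(fit$var_beta$vb1, 1, 2), 2 * (vc$g + vc$e),
               tolerance = 1e-9)                                  # 18.48
  expect_equal(corrected_ved(fit$var_beta$vb1, fit$design$n_per_cg, vc$e,
                             1, 2),
               pevd(pm, 1, 2), tolerance = 1e-9)
  expect_equal(flock_correlation(pm, 1, 2), 0, tolerance = 1e-10)
  expect_equal(cr(fit$var_beta$vb1, 1, 2), 0, tolerance = 1e-10)
  expect_equal(cd_contrast(pm, fit$kbar, 1, 2), 0, tolerance = 1e-9)
})

test_that("flock correlation and CR behave as correlations", {
  fit <- multi_effect_fit(78)$fit
  pm <- fit$pevmean_direct
  expect_equal(flock_correlation(pm, 3, 3), 1)
  expect_equal(cr(fit$var_beta$vb1, 2, 2), 1)
  rep <- fit$report
  expect_true(all(abs(rep$flock_r[!rep$flagged]) <= 1 + 1e-10))
  expect_true(all(abs(rep$cr[!rep$flagged]) <= 1 + 1e-10))
  expect_true(all(rep$pevd >= -1e-10))
  expect_equal(nrow(rep), choose(fit$design$p1, 2))
})

test_that("CR never exceeds the flock correlation in CG-only models", {
  sc <- sim_scenario(n_cgs = 6, offspring_per_cg = 12, seed = 79)
  fit <- quick_fit(sc)$fit
  rep <- fit$report
  expect_true(all(rep$cr <= rep$flock_r + 1e-10))
})

test_that("corrected VED equals PEVD in CG-only models, pair by pair", {
  sc <- sim_scenario(n_cgs = 6, offspring_per_cg = 9, seed = 80)
  fit <- quick_fit(sc)$fit
  expect_lt(max(abs(fit$report$corrected_ved - fit$report$pevd)), 1e-8)
})

test_that("CD is bounded and reaches its endpoints", {
  qf <- multi_effect_fit(81)
  fit <- qf$fit
  rep <- fit$report
  expect_true(all(rep$cd >= -1e-8 & rep$cd <= 1 + 1e-8))
  # no information: PEV equals the prior
  kbar <- fit$kbar
  expect_equal(cd_contrast(kbar, kbar, 1, 2), 0, tolerance = 1e-12)
  # perfect information: PEV = 0
  zero <- kbar * 0
  expect_equal(cd_contrast(zero, kbar, 1, 2), 1, tolerance = 1e-12)
  # direct evaluation of the CD formula with an explicit contrast
  pev <- extract_pev(fit$system)
  dm <- fit$design
  Z <- as.matrix(dm$Z)
  X1 <- as.matrix(dm$X1)
  A <- build_A(qf$herd$pedigree)
  x <- X1[, 1] / dm$n_per_cg[1] - X1[, 3] / dm$n_per_cg[3]
  num <- as.numeric(t(x) %*% Z %*% (vc$g * A - pev) %*% t(Z) %*% x)
  den <- as.numeric(t(x) %*% Z %*% (vc$g * A) %*% t(Z) %*% x)
  expect_equal(cd_contrast(fit$pevmean_direct, fit$kbar, 1, 3), num / den,
               tolerance = 1e-8)
})

test_that("rescaling a covariate leaves function-3 PEVMean unchanged", {
  sc <- sim_scenario(n_cgs = 4, offspring_per_cg = 10,
                     covariate_means = 20, covariate_sds = 4,
                     covariate_slopes = 0.3, seed = 82)
  herd <- simulate_herd(sc)
  fit1 <- fit_connectedness(herd$records, herd$pedigree, vc$g, vc$e,
                            covariates = "cov1")
  rec2 <- herd$records
  rec2$cov1 <- rec2$cov1 * 10 + 100
  fit2 <- fit_connectedness(rec2, herd$pedigree, vc$g, vc$e,
                            covariates = "cov1")
  expect_gt(max(abs(fit1$var_beta$vb1 - fit2$var_beta$vb1)), 1e-6)
  expect_lt(max(abs(fit1$pevmean - fit2$pevmean)), 1e-8)
})

test_that("adding records to a CG never inflates its PEVMean diagonal", {
  set.seed(83)
  ped <- order_pedigree(data.frame(animal = as.character(1:30),
                                   sire = "0", dam = "0"), quiet = TRUE)
  base <- tibble::tibble(animal = as.character(1:20),
                         cg = rep(c("A", "B"), each = 10),
                         y = rnorm(20, 10, 3))
  extra <- tibble::tibble(animal = as.character(21:30), cg = "A",
                          y = rnorm(10, 10, 3))
  fit_small <- fit_connectedness(base, ped, vc$g, vc$e)
  fit_big <- fit_connectedness(dplyr::bind_rows(base, extra), ped, vc$g, vc$e)
  expect_lte(fit_big$pevmean_direct["A", "A"],
             fit_small$pevmean_direct["A", "A"] + 1e-10)
})
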