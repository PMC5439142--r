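vc <- list(g = 1.81, e = 7.43)

herd_fixture <- local({
  sc <- sim_scenario(n_cgs = 5, offspring_per_cg = 12,
                     factor_levels = 3, covariate_means = 20,
                     covariate_sds = 4, covariate_slopes = 0.3, seed = 90)
  simulate_herd(sc)
})

fit_full <- fit_connectedness(herd_fixture$records, herd_fixture$pedigree,
                              vc$g, vc$e, factors = "factor1",
                              covariates = "cov1")
fit_cg <- fit_connectedness(herd_fixture$records, herd_fixture$pedigree,
                            vc$g, vc$e)

test_that("rearranged correction trace equals the full-matrix trace", {
  tr_fast <- correction_trace(fit_full$var_beta, fit_full$design)
  tr_full <- sum(diag(correction_factor(fit_full$var_beta, fit_full$design)))
  expect_equal(tr_fast, tr_full, tolerance = 1e-8)
})

test_that("orthogonal designs have zero correction trace", {
  ped <- order_pedigree(data.frame(animal = as.character(1:12),
                                   sire = "0", dam = "0"), quiet = TRUE)
  set.seed(91)
  rec <- tibble::tibble(animal = as.character(1:12),
                        cg = rep(c("A", "B", "C"), each = 4),
                        bal = rep(c(-2, -1, 1, 2), 3),
                        y = rnorm(12, 10, 3))
  fit <- fit_connectedness(rec, ped, vc$g, vc$e, covariates = "bal")
  expect_lt(abs(correction_trace(fit$var_beta, fit$design)), 1e-10)
})

test_that("moving a covariate mean away from zero grows the correction trace", {
  rec0 <- herd_fixture$records
  fit_c <- fit_connectedness(rec0, herd_fixture$pedigree, vc$g, vc$e,
                             covariates = "cov1", centre = TRUE)
  tr_centred <- abs(correction_trace(fit_c$var_beta, fit_c$design))
  rec_shift <- rec0
  rec_shift$cov1 <- rec_shift$cov1 - mean(rec_shift$cov1) + 50
  fit_s <- fit_connectedness(rec_shift, herd_fixture$pedigree, vc$g, vc$e,
                             covariates = "cov1")
  tr_shifted <- abs(correction_trace(fit_s$var_beta, fit_s$design))
  expect_gt(tr_shifted, tr_centred)
  # PEVMean itself is indifferent to the shift
  expect_lt(max(abs(fit_c$pevmean - fit_s$pevmean)), 1e-8)
})

test_that("covariance ratio identities hold and match the determinant oracle", {
  vb_full <- fit_full$var_beta$vb1
  vb_red <- fit_cg$var_beta$vb1
  expect_equal(covariance_ratio(vb_full, vb_full), 1, tolerance = 1e-10)
  r_ab <- covariance_ratio(vb_full, vb_red)
  r_ba <- covariance_ratio(vb_red, vb_full)
  expect_equal(r_ab * r_ba, 1, tolerance = 1e-8)
  oracle <- det(vb_full %*% solve(vb_red))
  expect_equal(r_ab, oracle, tolerance = 1e-6)
})

test_that("orthogonal additions leave the covariance ratio at 1", {
  ped <- order_pedigree(data.frame(animal = as.character(1:12),
                                   sire = "0", dam = "0"), quiet = TRUE)
  set.seed(92)
  rec <- tibble::tibble(animal = as.character(1:12),
                        cg = rep(c("A", "B", "C"), each = 4),
                        bal = rep(c(-2, -1, 1, 2), 3),
                        y = rnorm(12, 10, 3))
  full <- fit_connectedness(rec, ped, vc$g, vc$e, covariates = "bal")
  red <- fit_connectedness(rec, ped, vc$g, vc$e)
  expect_equal(covariance_ratio(full$var_beta$vb1, red$var_beta$vb1), 1,
               tolerance = 1e-8)
})

test_that("marginal r-squared tracks the fitted-value variance", {
  expect_equal(r2_marginal(rep(3, 50), vc$g, vc$e), 0)
  # Var(yhat) = sigma_e2 + sigma_g2 gives exactly one half
  target <- vc$g + vc$e
  yhat <- c(-1, 1) * sqrt(target)        # population variance = target
  expect_equal(r2_marginal(yhat, vc$g, vc$e), 0.5, tolerance = 1e-12)
  r2 <- r2_marginal(fit_full$yhat_fixed, vc$g, vc$e)
  expect_gt(r2, 0); expect_lt(r2, 1)
})

test_that("Wald r-squared matches its defining formula and midpoint", {
  b <- fit_full$beta_hat
  vb <- fit_full$var_beta$vb
  n <- length(fit_full$design$y)
  p <- length(b)
  Fstat <- as.numeric(t(b) %*% solve(vb) %*% b) / p
  expect_equal(r2_beta(b, vb, n),
               (p - 1) * Fstat / ((n - p) + (p - 1) * Fstat),
               tolerance = 1e-10)
  # algebraic midpoint: (q-1)F = nu gives 1/2 -- construct a 2-effect case
  # with Var = I and beta chosen so the Wald statistic hits 2 * nu / (p - 1)
  n2 <- 10; p2 <- 2; nu <- n2 - p2
  w_target <- p2 * nu / (p2 - 1)        # so (q-1)F = nu
  b2 <- c(sqrt(w_target), 0)
  expect_equal(r2_beta(b2, diag(2), n2), 0.5, tolerance = 1e-12)
  expect_error(r2_beta(b2, diag(2), 2), "exceed")
})

test_that("operation count follows the closed form and is quadratic in p1", {
  expect_equal(op_count(1, 0), 8)
  expect_equal(op_count(202, 9), 996062)
  # quadratic growth: doubling p1 at fixed p2 multiplies the count by ~4
  ratio <- op_count(2000, 9) / op_count(1000, 9)
  expect_gt(ratio, 3.5); expect_lt(ratio, 4.5)
})

test_that("the diagnostics bundle and glance expose consistent values", {
  g <- glance(fit_full)
  expect_equal(g$correction_trace,
               correction_trace(fit_full$var_beta, fit_full$design))
  expect_equal(g$op_count, op_count(fit_full$design$p1, fit_full$design$p2))
  expect_equal(g$lambda, vc$e / vc$g)
  expect_lt(g$max_dev_direct, 1e-8)
})
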