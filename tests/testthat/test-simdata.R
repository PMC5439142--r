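test_that("identical scenario and seed reproduce the dataset exactly", {
  sc <- sim_scenario(n_cgs = 3, offspring_per_cg = 8,
                     factor_levels = 2, covariate_means = 10,
                     covariate_sds = 2, covariate_slopes = 0.5, seed = 99)
  h1 <- simulate_herd(sc)
  h2 <- simulate_herd(sc)
  expect_identical(h1$records, h2$records)
  expect_identical(h1$pedigree, h2$pedigree)
  h3 <- simulate_herd(sim_scenario(n_cgs = 3, offspring_per_cg = 8,
                                   factor_levels = 2, covariate_means = 10,
                                   covariate_sds = 2, covariate_slopes = 0.5,
                                   seed = 100))
  expect_false(identical(h1$records$y, h3$records$y))
})

test_that("the generator emits a valid multi-flock structure", {
  sc <- sim_scenario(n_cgs = 4, offspring_per_cg = 10, n_generations = 2,
                     seed = 101)
  herd <- simulate_herd(sc)
  expect_true(all(herd$records$animal %in% herd$pedigree$animal))
  expect_equal(sort(unique(herd$records$cg)), sprintf("CG%02d", 1:4))
  expect_equal(unname(table(herd$records$cg))[1], 20)  # offspring x gens
  # link sires connect flocks: some sire serves in >= 2 CGs
  rec_flock <- herd$truth$flock[herd$records$animal]
  sires <- herd$pedigree$sire[match(herd$records$animal,
                                    herd$pedigree$animal)]
  served <- tapply(rec_flock, sires, function(x) length(unique(x)))
  expect_gt(max(served), 1)
})

test_that("zero link-sire fraction yields disconnected flocks", {
  sc <- sim_scenario(n_cgs = 3, offspring_per_cg = 10,
                     link_sire_fraction = 0, seed = 102)
  herd <- simulate_herd(sc)
  fit <- fit_connectedness(herd$records, herd$pedigree,
                           sc$sigma_g2, sc$sigma_e2)
  pm <- fit$pevmean_direct
  off <- pm[upper.tri(pm)]
  expect_lt(max(abs(off)), 1e-10)
  expect_true(all(abs(fit$report$flock_r) < 1e-10))
})

test_that("breeding values reproduce sigma_g2 * A over replicates", {
  trio <- order_pedigree(data.frame(animal = c("1", "2", "3"),
                                    sire = c("0", "0", "1"),
                                    dam = c("0", "0", "2")), quiet = TRUE)
  set.seed(103)
  U <- t(replicate(500, simulate_breeding_values(trio, 1.81)))
  C <- stats::cov(U) / 1.81
  expect_lt(abs(C[1, 3] - 0.5), 0.1)
  expect_lt(abs(C[1, 2] - 0), 0.1)
  expect_lt(abs(C[3, 3] - 1), 0.15)
})

test_that("Mendelian sampling variance uses exact parental inbreeding", {
  # father-daughter loop: offspring of an inbred sire has reduced sampling
  # variance; check the replicate variance of the terminal animal against
  # sigma_g2 * A_ii
  ped <- order_pedigree(data.frame(
    animal = c("1", "2", "3", "4", "5"),
    sire = c("0", "0", "1", "3", "4"),
    dam = c("0", "0", "2", "1", "3")), quiet = TRUE)
  A <- build_A(ped)
  set.seed(104)
  U <- t(replicate(800, simulate_breeding_values(ped, 1)))
  expect_lt(abs(stats::var(U[, 5]) - A[5, 5]), 0.15 * A[5, 5])
})

test_that("balanced scenarios equalise covariate means and factor shares", {
  sc <- sim_scenario(n_cgs = 3, offspring_per_cg = 12, n_generations = 1,
                     factor_levels = 3, covariate_means = 20,
                     covariate_sds = 4, covariate_slopes = 0.3,
                     balanced = TRUE, seed = 105)
  herd <- simulate_herd(sc)
  cg_means <- tapply(herd$records$cov1, herd$records$cg, mean)
  expect_lt(diff(range(cg_means)), 1e-10)
  shares <- table(herd$records$cg, herd$records$factor1)
  expect_true(all(shares == shares[1, 1]))
})

test_that("parameter recovery: CG estimates within 3 SE of the truth", {
  sc <- sim_scenario(n_founders = 120, n_cgs = 4, offspring_per_cg = 60,
                     n_generations = 1, link_sire_fraction = 0, seed = 106)
  herd <- simulate_herd(sc)
  fit <- fit_connectedness(herd$records, herd$pedigree,
                           sc$sigma_g2, sc$sigma_e2)
  est <- fit$beta_hat[seq_len(4)]
  se <- sqrt(diag(fit$var_beta$vb1))
  truth <- herd$truth$beta_cg
  expect_true(all(abs(est - truth) < 3 * se))
})

test_that("gene dropping is deterministic and flags monomorphic markers", {
  ped <- random_pedigree(40, seed = 107)
  sc <- sim_scenario(seed = 107, n_markers = 100, genotyped_fraction = 0.5)
  g1 <- simulate_genotypes(ped, sc)
  g2 <- simulate_genotypes(ped, sc)
  expect_identical(g1$dosages, g2$dosages)
  expect_equal(nrow(g1$dosages), 20)
  expect_true(all(g1$dosages %in% 0:2))
  expect_type(g1$monomorphic, "logical")
  no_var <- apply(g1$dosages, 2, function(x) length(unique(x)) == 1)
  expect_identical(unname(g1$monomorphic), unname(no_var))
})

test_that("scenario validation rejects impossible settings", {
  expect_error(sim_scenario(n_cgs = 10, n_founders = 10), "n_founders")
  expect_error(sim_scenario(link_sire_fraction = 2))
  expect_error(sim_scenario(sigma_g2 = 0))
})
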