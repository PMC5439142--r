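# Independent brute-force oracles used across the suite. These deliberately
# re-derive every quantity from dense textbook formulas, not from the package
# internals they are checking.

# Random pedigree with overlapping generations and inbreeding loops.
# Parents are drawn from earlier animals (or unknown), so loops and
# half/full-sib matings arise naturally.
random_pedigree <- function(n, n_founders = max(5, n %/% 5),
                            p_unknown = 0.1, seed = 1) {
  set.seed(seed)
  animal <- sprintf("P%04d", seq_len(n))
  sire <- dam <- rep("0", n)
  for (i in (n_founders + 1):n) {
    pool <- seq_len(i - 1)
    if (stats::runif(1) > p_unknown) sire[i] <- animal[sample(pool, 1)]
    if (stats::runif(1) > p_unknown) dam[i] <- animal[sample(pool, 1)]
  }
  order_pedigree(data.frame(animal = animal, sire = sire, dam = dam),
                 quiet = TRUE)
}

# Dense GLS: Var(beta_hat) = (X' V^-1 X)^-1 and
# PEV = sigma_g2 K - sigma_g2^2 K Z' P Z K with P the GLS projection.
gls_oracle <- function(design, K, sigma_g2, sigma_e2) {
  X <- cbind(as.matrix(design$X1), design$X2)
  Z <- as.matrix(design$Z)
  K <- as.matrix(K)
  n <- length(design$y)
  V <- sigma_g2 * Z %*% K %*% t(Z) + diag(sigma_e2, n)
  Vi <- solve(V)
  vb <- solve(t(X) %*% Vi %*% X)
  vb <- (vb + t(vb)) / 2
  P <- Vi - Vi %*% X %*% vb %*% t(X) %*% Vi
  pev <- sigma_g2 * K - sigma_g2^2 * K %*% t(Z) %*% P %*% Z %*% K
  list(vb = vb, pev = (pev + t(pev)) / 2)
}

# Explicit row-averaging of PEV sub-blocks by CG membership of records.
pevmean_avg_oracle <- function(pev, records_cg, animal_idx, cg_labels) {
  p1 <- length(cg_labels)
  out <- matrix(0, p1, p1, dimnames = list(cg_labels, cg_labels))
  for (i in seq_len(p1)) {
    for (j in seq_len(p1)) {
      ri <- animal_idx[records_cg == cg_labels[i]]
      rj <- animal_idx[records_cg == cg_labels[j]]
      out[i, j] <- mean(pev[ri, rj, drop = FALSE])
    }
  }
  out
}

# Dense H from its partitioned definition (genotyped block replaced by G,
# non-genotyped block conditioned through A): with subscript 1 =
# non-genotyped, 2 = genotyped,
#   H11 = A11 + A12 A22^-1 (G - A22) A22^-1 A21
#   H12 = A12 A22^-1 G,  H22 = G.
dense_H_oracle <- function(A, G, idx2) {
  n <- nrow(A)
  idx1 <- setdiff(seq_len(n), idx2)
  A22i <- solve(A[idx2, idx2])
  H <- matrix(0, n, n)
  H[idx1, idx1] <- A[idx1, idx1] +
    A[idx1, idx2] %*% A22i %*% (G - A[idx2, idx2]) %*% A22i %*% A[idx2, idx1]
  H[idx1, idx2] <- A[idx1, idx2] %*% A22i %*% G
  H[idx2, idx1] <- t(H[idx1, idx2])
  H[idx2, idx2] <- G
  (H + t(H)) / 2
}

# Quick fit wrapper used by many tests
quick_fit <- function(scenario, ...) {
  herd <- simulate_herd(scenario)
  fit <- fit_connectedness(herd$records, herd$pedigree,
                           sigma_g2 = scenario$sigma_g2,
                           sigma_e2 = scenario$sigma_e2, ...)
  list(herd = herd, fit = fit)
}

# A disconnected two-CG design over unrelated recorded animals: every animal
# a founder, one record each. Exact closed forms hold here.
unrelated_two_cg <- function(n1 = 1, n2 = 1, sigma_g2 = 1.81,
                             sigma_e2 = 7.43, seed = 5) {
  set.seed(seed)
  n <- n1 + n2
  ped <- order_pedigree(data.frame(animal = as.character(seq_len(n)),
                                   sire = "0", dam = "0"), quiet = TRUE)
  records <- tibble::tibble(
    animal = as.character(seq_len(n)),
    cg = rep(c("G1", "G2"), c(n1, n2)),
    y = stats::rnorm(n, 10, 2)
  )
  fit_connectedness(records, ped, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2)
}
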