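#' Assemble Henderson's mixed model equations
#'
#' Builds the symmetric coefficient matrix
#' \deqn{C = [[X'X, X'Z], [Z'X, Z'Z + \lambda K^{-1}]]}
#' and right-hand side `[X'y, Z'y]`, with \eqn{\lambda = \sigma^2_e /
#' \sigma^2_g} and `X = [X1 X2]`. The system is assembled on the lambda scale
#' (residual variance factored out under \eqn{R = \sigma^2_e I}); variance
#' blocks extracted from its inverse are multiplied back by \eqn{\sigma^2_e}.
#'
#' @param design A `conn_design` from [build_design()].
#' @param K_inv Sparse inverse relationship matrix (A-inverse or H-inverse)
#'   over the pedigree animals, in pedigree order.
#' @param sigma_g2,sigma_e2 Additive genetic and residual variances (trait
#'   units squared), both > 0.
#' @return An object of class `mme_system`.
#' @export
assemble_mme <- function(design, K_inv, sigma_g2, sigma_e2) {
  stopifnot(inherits(design, "conn_design"), sigma_g2 > 0, sigma_e2 > 0)
  q <- ncol(design$Z)
  if (nrow(K_inv) != q) {
    stop("K_inv dimension (", nrow(K_inv), ") does not match the ", q,
         " pedigree animals in Z", call. = FALSE)
  }
  lambda <- sigma_e2 / sigma_g2
  X <- Matrix::cbind2(design$X1, Matrix::Matrix(design$X2, sparse = TRUE))
  Z <- design$Z
  W <- Matrix::cbind2(X, Z)
  p <- design$p1 + design$p2
  C <- Matrix::crossprod(W) +
    Matrix::bdiag(Matrix::Matrix(0, p, p, sparse = TRUE), lambda * K_inv)
  C <- Matrix::forceSymmetric((C + Matrix::t(C)) / 2)
  rhs <- c(as.numeric(Matrix::crossprod(X, design$y)),
           as.numeric(Matrix::crossprod(Z, design$y)))
  structure(
    list(C = C, rhs = rhs, p1 = design$p1, p2 = design$p2, q = q,
         p = design$p1 + design$p2, lambda = lambda,
         sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
         effect_names = c(design$cg_labels, design$x2_names,
                          design$animal_ids)),
    class = "mme_system"
  )
}

#' @export
print.mme_system <- function(x, ...) {
  cat("<mme_system> p1 =", x$p1, ", p2 =", x$p2, ", q =", x$q,
      ", lambda =", format(x$lambda, digits = 6), "\n")
  invisible(x)
}

check_system <- function(system) {
  stopifnot(inherits(system, "mme_system"))
  # sparse 1-norm condition estimate; > 1e12 marks a confounded design
  # rather than an ill-scaled covariate
  rc <- tryCatch({
    est <- Matrix::condest(as(system$C, "generalMatrix"))$est
    1 / est
  }, error = function(e) 0)
  if (!is.finite(rc) || rc < 1e-12) {
    stop("mixed model equations are singular or near-singular ",
         "(reciprocal condition estimate ", format(rc, digits = 3),
         "); check the design for confounded fixed effects", call. = FALSE)
  }
  invisible(TRUE)
}

#' Solve the mixed model equations for the effect estimates
#'
#' @param system An `mme_system` from [assemble_mme()].
#' @return List with `beta_hat` (named, length p1 + p2) and `u_hat` (named,
#'   length q).
#' @export
solve_mme <- function(system) {
  check_system(system)
  sol <- as.numeric(Matrix::solve(system$C, system$rhs))
  names(sol) <- system$effect_names
  list(beta_hat = sol[seq_len(system$p)],
       u_hat = sol[system$p + seq_len(system$q)])
}

#' Fixed-effect variance block of the mixed model equation inverse
#'
#' Computes \eqn{Var(\hat\beta) = \sigma^2_e C^{pp}} by solving
#' `C B = [I_p; 0]` -- only the p fixed-effect columns of the inverse are ever
#' formed, never the random-effect block. The result is partitioned into the
#' contemporary-group block `vb1` (p1 x p1), the other-effects block `vb2`
#' (p2 x p2) and the cross block `vb12` (p1 x p2).
#'
#' @inheritParams solve_mme
#' @return List of class `var_beta` with elements `vb`, `vb1`, `vb2`, `vb12`.
#' @export
solve_fixed_block <- function(system) {
  check_system(system)
  p <- system$p
  B <- Matrix::sparseMatrix(i = seq_len(p), j = seq_len(p), x = 1,
                            dims = c(p + system$q, p))
  cols <- Matrix::solve(system$C, B)
  vb <- system$sigma_e2 * as.matrix(cols[seq_len(p), , drop = FALSE])
  vb <- (vb + t(vb)) / 2
  dimnames(vb) <- list(system$effect_names[seq_len(p)],
                       system$effect_names[seq_len(p)])
  i1 <- seq_len(system$p1)
  i2 <- if (system$p2 > 0) system$p1 + seq_len(system$p2) else integer(0)
  structure(
    list(vb = vb,
         vb1 = vb[i1, i1, drop = FALSE],
         vb2 = vb[i2, i2, drop = FALSE],
         vb12 = vb[i1, i2, drop = FALSE]),
    class = "var_beta"
  )
}

#' Prediction error variance block of the mixed model equation inverse
#'
#' Extracts \eqn{PEV = Var(\hat u - u) = \sigma^2_e C^{uu}}, the q x q
#' random-effect block of the inverse coefficient matrix. Dense and
#' quadratic in the number of animals: intended for validation and small
#' evaluations; large evaluations should use [pevmean_function3()] instead,
#' which needs only the fixed-effect block.
#'
#' @inheritParams solve_mme
#' @param dense_limit Refuse instances with more animals than this.
#' @return Dense symmetric q x q matrix (trait units squared), animal ids as
#'   dimnames.
#' @export
extract_pev <- function(system, dense_limit = 5000) {
  check_system(system)
  if (system$q > dense_limit) {
    stop("q = ", system$q, " animals exceeds the dense PEV limit (",
         dense_limit, "); use the fixed-effect-block path (pevmean_function3)",
         call. = FALSE)
  }
  Cinv <- solve(as.matrix(system$C))
  iu <- system$p + seq_len(system$q)
  pev <- system$sigma_e2 * Cinv[iu, iu, drop = FALSE]
  pev <- (pev + t(pev)) / 2
  dimnames(pev) <- list(system$effect_names[iu], system$effect_names[iu])
  pev
}
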