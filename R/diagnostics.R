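#' Trace of the other-fixed-effects correction factor
#'
#' A scalar diagnostic of whether the record-count-corrected CG variance
#' block suffices as an approximation of PEVMean. Computed in the rearranged
#' form \eqn{2\,Tr(Var(\hat\beta_2,\hat\beta_1) W) + Tr(Var(\hat\beta_2)
#' W'W)} with `W = (X1'X1)^{-1} X1'X2`, which touches only p2-dimensional
#' products; it equals the trace of the full [correction_factor()] matrix.
#' Traces far from zero mean the other fixed effects materially distort
#' CG-variance-based connectedness measures.
#'
#' @inheritParams pevmean_function3
#' @return Numeric scalar (trait units squared); 0 when `p2 = 0` or the
#'   design is orthogonal.
#' @export
correction_trace <- function(var_beta, design) {
  stopifnot(inherits(var_beta, "var_beta"))
  if (design$p2 == 0) return(0)
  W <- cg_mean_x2(design)
  2 * sum(diag(t(var_beta$vb12) %*% W)) +
    sum(diag(var_beta$vb2 %*% crossprod(W)))
}

#' Covariance ratio between nested models
#'
#' Ratio of determinants of the CG fixed-effect variance blocks of two
#' models sharing the same contemporary groups:
#' \eqn{\det(Var(\hat\beta_1)_A \, Var(\hat\beta_1)_B^{-1})}. Equal to 1 when
#' the added fixed effects leave the CG-effect variances untouched (e.g.
#' orthogonal additions); drift from 1 flags confounding with CG. Computed
#' via log-determinant differences for stability.
#'
#' @param vb1_a,vb1_b CG variance blocks of models A and B, same CG order.
#' @return Numeric scalar > 0.
#' @export
covariance_ratio <- function(vb1_a, vb1_b) {
  vb1_a <- as.matrix(vb1_a)
  vb1_b <- as.matrix(vb1_b)
  stopifnot(all(dim(vb1_a) == dim(vb1_b)))
  la <- determinant(vb1_a, logarithm = TRUE)
  lb <- determinant(vb1_b, logarithm = TRUE)
  if (la$sign <= 0 || lb$sign <= 0) {
    stop("variance block is not positive definite", call. = FALSE)
  }
  exp(as.numeric(la$modulus) - as.numeric(lb$modulus))
}

#' Marginal r-squared of the fixed-effect component
#'
#' \eqn{r^2_m = Var(\hat y) / (Var(\hat y) + \sigma^2_e + \sigma^2_g)} with
#' \eqn{\hat y = X \hat\beta} the fitted values without the random effects and
#' the population (divide-by-n) variance.
#'
#' @param yhat_fixed Numeric vector of fixed-effect fitted values, one per
#'   record.
#' @param sigma_g2,sigma_e2 Variance components.
#' @return Numeric scalar in [0, 1).
#' @export
r2_marginal <- function(yhat_fixed, sigma_g2, sigma_e2) {
  v <- mean((yhat_fixed - mean(yhat_fixed))^2)
  v / (v + sigma_e2 + sigma_g2)
}

#' Wald-based r-squared of the fixed effects
#'
#' From the Wald statistic \eqn{w = \hat\beta' Var(\hat\beta)^{-1} \hat\beta}
#' an F statistic `F = w / p` is formed and converted to
#' \eqn{r^2_\beta = (q-1)F / (\nu + (q-1)F)} with \eqn{\nu = n - p}. The
#' contrast dimension q is taken as the total number of estimated fixed
#' effects (q = p); see the package vignette for why this convention is
#' adopted and what remains open about the residual degrees of freedom.
#'
#' @param beta_hat Estimated fixed effects (length p).
#' @param var_beta_full Full p x p fixed-effect variance matrix.
#' @param n_records Number of records n (must exceed p).
#' @return Numeric scalar in [0, 1).
#' @export
r2_beta <- function(beta_hat, var_beta_full, n_records) {
  p <- length(beta_hat)
  if (n_records <= p) stop("n must exceed the number of fixed effects",
                           call. = FALSE)
  w <- as.numeric(t(beta_hat) %*% solve(var_beta_full, beta_hat))
  Fstat <- w / p
  nu <- n_records - p
  (p - 1) * Fstat / (nu + (p - 1) * Fstat)
}

#' Predicted operation count for the post-solve correction
#'
#' Closed-form count of arithmetic operations needed to turn the fixed-effect
#' variance matrix into the exact PEVMean:
#' \eqn{2 p_1 + 6 p_1^2 + p_1 p_2 (2 p_1 + p_2)}. Quadratic in the number of
#' contemporary groups, independent of the number of animals -- the point of
#' the fixed-effect-block route.
#'
#' @param p1 Number of contemporary groups (>= 1).
#' @param p2 Number of other estimated fixed effects (>= 0).
#' @return Numeric count.
#' @export
op_count <- function(p1, p2) {
  stopifnot(p1 >= 1, p2 >= 0)
  2 * p1 + 6 * p1^2 + p1 * p2 * (2 * p1 + p2)
}

#' Bundle of model diagnostics for a fitted connectedness model
#'
#' @param fit A `conn_fit` from [fit_connectedness()].
#' @return A one-row tibble: `correction_trace`, `r2_marginal`, `r2_beta`,
#'   `op_count`, plus dimensions.
#' @export
diagnostics_bundle <- function(fit) {
  stopifnot(inherits(fit, "conn_fit"))
  tibble::tibble(
    p1 = fit$design$p1,
    p2 = fit$design$p2,
    q = ncol(fit$design$Z),
    n_records = length(fit$design$y),
    correction_trace = correction_trace(fit$var_beta, fit$design),
    r2_marginal = r2_marginal(fit$yhat_fixed, fit$sigma_g2, fit$sigma_e2),
    r2_beta = r2_beta(fit$beta_hat, fit$var_beta$vb, length(fit$design$y)),
    op_count = op_count(fit$design$p1, fit$design$p2)
  )
}
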