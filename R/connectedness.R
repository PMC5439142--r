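#' Contemporary-group averaged PEV, directly from the PEV block
#'
#' Averages the prediction error variance-covariance matrix of breeding
#' values by contemporary group:
#' \deqn{\overline{PEV} = (X_1'X_1)^{-1} X_1'Z \; PEV \; Z'X_1 (X_1'X_1)^{-1}.}
#' A CG's mean is taken over records, so an animal with several records would
#' be weighted by its record count.
#'
#' @param pev Dense PEV matrix from [extract_pev()].
#' @param design The `conn_design` the model was fitted with.
#' @return A `pevmean` matrix (p1 x p1, trait units squared), CG labels as
#'   dimnames, attribute `source = "direct"`.
#' @export
pevmean_direct <- function(pev, design) {
  Tm <- cg_average_operator(design)
  out <- Tm %*% pev %*% t(Tm)
  new_pevmean(out, design$cg_labels, "direct")
}

#' PEVMean approximation: the CG fixed-effect variance block unchanged
#'
#' The crude approximation that treats \eqn{Var(\hat\beta_1)} itself as the
#' CG-averaged PEV. Its off-diagonals equal those of the exact PEVMean in a
#' CG-only model; its diagonals are inflated by \eqn{\sigma^2_e / n_i}.
#'
#' @param var_beta1 The p1 x p1 CG block of the fixed-effect variance matrix.
#' @param cg_labels Optional CG labels.
#' @return A `pevmean` matrix, attribute `source = "function1"`.
#' @export
pevmean_function1 <- function(var_beta1, cg_labels = rownames(var_beta1)) {
  new_pevmean(as.matrix(var_beta1), cg_labels, "function1")
}

#' PEVMean from the fixed-effect variance block, CG-only model
#'
#' Exact when contemporary group is the only fixed effect:
#' \deqn{\overline{PEV} = Var(\hat\beta) - \sigma^2_e (X'X)^{-1},}
#' i.e. subtract the record-count correction \eqn{\sigma^2_e / n_i} from each
#' diagonal; off-diagonals are untouched.
#'
#' @inheritParams pevmean_function1
#' @param n_per_cg Records per contemporary group, in CG order.
#' @param sigma_e2 Residual variance.
#' @return A `pevmean` matrix, attribute `source = "function2"`.
#' @export
pevmean_function2 <- function(var_beta1, n_per_cg, sigma_e2,
                              cg_labels = rownames(var_beta1)) {
  var_beta1 <- as.matrix(var_beta1)
  stopifnot(length(n_per_cg) == nrow(var_beta1), all(n_per_cg >= 1))
  out <- var_beta1 - diag(sigma_e2 / n_per_cg, nrow(var_beta1))
  new_pevmean(out, cg_labels, "function2")
}

#' Exact PEVMean from the fixed-effect variance matrix, any fixed effects
#'
#' The central identity: with `W = (X1'X1)^{-1} X1'X2`,
#' \deqn{\overline{PEV} = Var(\hat\beta_1) + W Var(\hat\beta_2) W' +
#'   W Var(\hat\beta_2, \hat\beta_1) + Var(\hat\beta_1, \hat\beta_2) W' -
#'   \sigma^2_e (X_1'X_1)^{-1}.}
#' Requires only the (p1 + p2)-dimensional fixed-effect block of the mixed
#' model equation inverse, never the q x q PEV block. Reduces to
#' [pevmean_function2()] when `X1'X2 = 0` or `p2 = 0`.
#'
#' @param var_beta A `var_beta` partition from [solve_fixed_block()].
#' @param design The `conn_design` the model was fitted with.
#' @param sigma_e2 Residual variance.
#' @param tol Asymmetry beyond this (relative) is an error; smaller asymmetry
#'   is symmetrised away.
#' @return A `pevmean` matrix, attribute `source = "function3"` (or
#'   `"function2"` when `p2 = 0`).
#' @export
pevmean_function3 <- function(var_beta, design, sigma_e2, tol = 1e-8) {
  stopifnot(inherits(var_beta, "var_beta"))
  if (design$p2 == 0) {
    return(pevmean_function2(var_beta$vb1, design$n_per_cg, sigma_e2,
                             design$cg_labels))
  }
  if (ncol(var_beta$vb2) != design$p2) {
    stop("var_beta partition does not match the design's X2 (",
         ncol(var_beta$vb2), " vs ", design$p2, " columns)", call. = FALSE)
  }
  W <- cg_mean_x2(design)
  out <- var_beta$vb1 +
    W %*% var_beta$vb2 %*% t(W) +
    W %*% t(var_beta$vb12) +
    var_beta$vb12 %*% t(W) -
    diag(sigma_e2 / design$n_per_cg, design$p1)
  asym <- max(abs(out - t(out)))
  if (asym > tol * (1 + max(abs(out)))) {
    stop("function-3 PEVMean asymmetric beyond tolerance (", asym, ")",
         call. = FALSE)
  }
  out <- (out + t(out)) / 2
  new_pevmean(out, design$cg_labels, "function3")
}

#' Correction factor for other fixed effects in the model
#'
#' The matrix added to the record-count-corrected CG variance block to
#' recover the exact PEVMean when fixed effects besides contemporary group
#' are fitted: \eqn{W Var(\hat\beta_2) W' + W Var(\hat\beta_2, \hat\beta_1) +
#' Var(\hat\beta_1, \hat\beta_2) W'}. Zero when `X1'X2 = 0`.
#'
#' @inheritParams pevmean_function3
#' @return p1 x p1 matrix (trait units squared).
#' @export
correction_factor <- function(var_beta, design) {
  stopifnot(inherits(var_beta, "var_beta"))
  if (design$p2 == 0) {
    return(matrix(0, design$p1, design$p1,
                  dimnames = list(design$cg_labels, design$cg_labels)))
  }
  W <- cg_mean_x2(design)
  out <- W %*% var_beta$vb2 %*% t(W) + W %*% t(var_beta$vb12) +
    var_beta$vb12 %*% t(W)
  dimnames(out) <- list(design$cg_labels, design$cg_labels)
  out
}

new_pevmean <- function(m, cg_labels, source) {
  m <- as.matrix(m)
  if (!is.null(cg_labels)) dimnames(m) <- list(cg_labels, cg_labels)
  attr(m, "source") <- source
  class(m) <- c("pevmean", class(m))
  m
}

#' @export
print.pevmean <- function(x, ...) {
  cat("<pevmean> source =", attr(x, "source"), ",", nrow(x),
      "contemporary groups\n")
  print(unclass_pevmean(x), ...)
  invisible(x)
}

unclass_pevmean <- function(x) {
  attr(x, "source") <- NULL
  class(x) <- setdiff(class(x), "pevmean")
  x
}

pair_index <- function(pm, i, j) {
  labs <- rownames(pm)
  ix <- if (is.character(i)) match(i, labs) else as.integer(i)
  jx <- if (is.character(j)) match(j, labs) else as.integer(j)
  if (anyNA(c(ix, jx))) stop("unknown contemporary group", call. = FALSE)
  c(ix, jx)
}

#' Prediction error variance of a contemporary-group difference (PEVD)
#'
#' \eqn{PEVD_{ij} = \bar P_{ii} + \bar P_{jj} - 2 \bar P_{ij}} where
#' \eqn{\bar P} is a PEVMean matrix. Small PEVD = the difference in mean
#' breeding value between the two groups is well predicted = well connected.
#'
#' @param pm A `pevmean` matrix (or any symmetric matrix with CG dimnames).
#' @param i,j Two distinct contemporary groups (index or label).
#' @return Numeric scalar (trait units squared).
#' @export
pevd <- function(pm, i, j) {
  ix <- pair_index(pm, i, j)
  if (ix[1] == ix[2]) stop("PEVD requires two distinct groups", call. = FALSE)
  pm[ix[1], ix[1]] + pm[ix[2], ix[2]] - 2 * pm[ix[1], ix[2]]
}

#' Flock correlation between two contemporary groups
#'
#' Correlation form of PEVMean: \eqn{r_{ij} = \bar P_{ij} /
#' \sqrt{\bar P_{ii} \bar P_{jj}}}. High correlation = well connected.
#'
#' @inheritParams pevd
#' @param eps_var Guard on near-zero diagonals; pairs at or below it return
#'   `NA` (flagged in reports rather than silently computed).
#' @return Numeric scalar in [-1, 1], or `NA` if a diagonal is ~ 0.
#' @export
flock_correlation <- function(pm, i, j, eps_var = 1e-12) {
  ix <- pair_index(pm, i, j)
  if (ix[1] == ix[2]) return(1)
  d1 <- pm[ix[1], ix[1]]
  d2 <- pm[ix[2], ix[2]]
  if (d1 <= eps_var || d2 <= eps_var) return(NA_real_)
  pm[ix[1], ix[2]] / sqrt(d1 * d2)
}

#' Variance of the difference of estimated CG effects (VED), and its
#' record-count-corrected version
#'
#' `ved()` is \eqn{Var(\hat\beta_1)_{ii} + Var(\hat\beta_1)_{jj} -
#' 2 Var(\hat\beta_1)_{ij}}, the classical approximation to PEVD.
#' `corrected_ved()` subtracts \eqn{\sigma^2_e / n_i + \sigma^2_e / n_j}; in a
#' CG-only model (and for balanced other effects) it equals PEVD exactly.
#'
#' @param var_beta1 p1 x p1 CG block of the fixed-effect variance matrix.
#' @param i,j Two distinct contemporary groups (index or label).
#' @return Numeric scalar (trait units squared).
#' @export
ved <- function(var_beta1, i, j) {
  ix <- pair_index(var_beta1, i, j)
  if (ix[1] == ix[2]) stop("VED requires two distinct groups", call. = FALSE)
  var_beta1[ix[1], ix[1]] + var_beta1[ix[2], ix[2]] -
    2 * var_beta1[ix[1], ix[2]]
}

#' @rdname ved
#' @param n_per_cg Records per contemporary group, in CG order.
#' @param sigma_e2 Residual variance.
#' @export
corrected_ved <- function(var_beta1, n_per_cg, sigma_e2, i, j) {
  ix <- pair_index(var_beta1, i, j)
  as.numeric(ved(var_beta1, i, j) - sigma_e2 / n_per_cg[ix[1]] -
               sigma_e2 / n_per_cg[ix[2]])
}

#' Connectedness rating (CR) between two contemporary groups
#'
#' Correlation form of the CG fixed-effect variance block:
#' \eqn{CR_{ij} = Var(\hat\beta_1)_{ij} / \sqrt{Var(\hat\beta_1)_{ii}
#' Var(\hat\beta_1)_{jj}}}. Approximates the flock correlation; in CG-only
#' models its inflated denominator makes it systematically smaller.
#'
#' @inheritParams ved
#' @param eps_var Guard on near-zero diagonals (returns `NA`).
#' @return Numeric scalar in [-1, 1].
#' @export
cr <- function(var_beta1, i, j, eps_var = 1e-12) {
  ix <- pair_index(var_beta1, i, j)
  if (ix[1] == ix[2]) return(1)
  d1 <- var_beta1[ix[1], ix[1]]
  d2 <- var_beta1[ix[2], ix[2]]
  if (d1 <= eps_var || d2 <= eps_var) return(NA_real_)
  var_beta1[ix[1], ix[2]] / sqrt(d1 * d2)
}

#' Group-averaged prior variance of breeding values
#'
#' \eqn{\bar K = (X_1'X_1)^{-1} X_1'Z \,\sigma^2_g K\, Z'X_1 (X_1'X_1)^{-1}},
#' the prior (no-data) counterpart of PEVMean, needed as the denominator of
#' the coefficient of determination of CG contrasts.
#'
#' @param K Dense relationship matrix fitted for the random effect (A, or H).
#' @param design The `conn_design`.
#' @param sigma_g2 Additive genetic variance.
#' @return p1 x p1 matrix (trait units squared).
#' @export
prior_cg_variance <- function(K, design, sigma_g2) {
  Tm <- cg_average_operator(design)
  out <- sigma_g2 * (Tm %*% as.matrix(K) %*% t(Tm))
  dimnames(out) <- list(design$cg_labels, design$cg_labels)
  (out + t(out)) / 2
}

#' Coefficient of determination of a contemporary-group contrast
#'
#' \eqn{CD(x_{ij}) = 1 - PEVD_{ij} / PriorVD_{ij}} where the prior variance
#' of the difference is read off the group-averaged prior variance matrix
#' `kbar` (see [prior_cg_variance()]). 0 = no information on the contrast,
#' 1 = the contrast is predicted without error.
#'
#' @param pm A `pevmean` matrix.
#' @param kbar Group-averaged prior variance matrix, same CG order.
#' @param i,j Two distinct contemporary groups (index or label).
#' @return Numeric scalar in [0, 1], `NA` if the prior contrast variance is 0.
#' @export
cd_contrast <- function(pm, kbar, i, j) {
  prior <- pevd(kbar, i, j)
  if (prior <= 0) return(NA_real_)
  1 - pevd(pm, i, j) / prior
}

#' Pairwise connectedness report over all contemporary-group pairs
#'
#' Tabulates every statistic for every unordered CG pair. Statistics based on
#' PEVMean (`pevd`, `flock_r`, `cd`) use the supplied `pm`; statistics based
#' on the raw CG fixed-effect variance block (`ved`, `corrected_ved`, `cr`)
#' use `var_beta1`. When a second PEVMean `pm_check` is supplied (e.g. the
#' direct PEV path next to the function-3 path), a `max_dev` column reports
#' the largest absolute elementwise deviation for each pair's 2 x 2 block.
#'
#' @param pm A `pevmean` matrix.
#' @param var_beta1 CG block of the fixed-effect variance matrix.
#' @param n_per_cg Records per CG, in CG order.
#' @param sigma_e2 Residual variance.
#' @param kbar Optional group-averaged prior variance matrix for the CD
#'   column.
#' @param pm_check Optional second PEVMean to compare against.
#' @param eps_var Near-zero diagonal guard; affected pairs have
#'   `flagged = TRUE` and `NA` correlations.
#' @return A tibble of class `conn_report`: one row per pair with columns
#'   `cg_i`, `cg_j`, `n_i`, `n_j`, `harmonic_mean_n`, `pevd`, `flock_r`,
#'   `ved`, `corrected_ved`, `cr`, `cd`, `flagged` (and `max_dev`).
#' @export
connectedness_report <- function(pm, var_beta1, n_per_cg, sigma_e2,
                                 kbar = NULL, pm_check = NULL,
                                 eps_var = 1e-12) {
  labs <- rownames(pm)
  p1 <- length(labs)
  stopifnot(p1 >= 2, nrow(var_beta1) == p1, length(n_per_cg) == p1)
  pairs <- utils::combn(p1, 2)
  rows <- purrr::map(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    fr <- flock_correlation(pm, i, j, eps_var = eps_var)
    crv <- cr(var_beta1, i, j, eps_var = eps_var)
    tibble::tibble(
      cg_i = labs[i], cg_j = labs[j],
      n_i = n_per_cg[i], n_j = n_per_cg[j],
      harmonic_mean_n = 2 / (1 / n_per_cg[i] + 1 / n_per_cg[j]),
      pevd = pevd(pm, i, j),
      flock_r = fr,
      ved = ved(var_beta1, i, j),
      corrected_ved = corrected_ved(var_beta1, n_per_cg, sigma_e2, i, j),
      cr = crv,
      cd = if (is.null(kbar)) NA_real_ else cd_contrast(pm, kbar, i, j),
      flagged = is.na(fr) || is.na(crv),
      max_dev = if (is.null(pm_check)) NA_real_ else
        max(abs(pm[c(i, j), c(i, j)] - pm_check[c(i, j), c(i, j)]))
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("conn_report", class(out))
  out
}
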