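#' Fit the animal model and compute connectedness between contemporary groups
#'
#' The pipeline entry point: orders the pedigree, builds the design, assembles
#' and solves Henderson's mixed model equations under the requested
#' relationship matrix (pedigree `A` or single-step `H`), extracts the
#' fixed-effect variance block, and computes PEVMean by the exact
#' fixed-effect-block route ([pevmean_function3()]). Optionally also extracts
#' the full PEV block and computes PEVMean directly, for validation.
#'
#' @param records Record table (one row per record); see [build_design()].
#' @param pedigree Pedigree table or `conn_pedigree`.
#' @param sigma_g2,sigma_e2 Variance components (trait units squared).
#' @param cg,factors,covariates,centre,standardise,trait Model specification,
#'   passed to [build_design()].
#' @param genotypes Optional dosage matrix (animals x markers, rownames =
#'   ids) for `relationship = "H"`.
#' @param relationship `"A"` (pedigree only) or `"H"` (single-step).
#' @param blend_weight Genomic blending weight passed to [blend_G()].
#' @param pev `"auto"` (direct PEV when the pedigree is within
#'   `dense_limit`), `"direct"` (force; error beyond the limit) or `"none"`.
#' @param dense_limit Animal count above which the dense PEV block is not
#'   extracted.
#' @param quiet Suppress progress messages.
#' @return An object of class `conn_fit`: list with the design, MME system,
#'   `beta_hat`, `u_hat`, `var_beta` (partitioned), `pevmean` (function-3
#'   route), `pevmean_direct` (or `NULL`), `kbar` (group-averaged prior
#'   variance, when computable), `report` (tibble of pairwise statistics) and
#'   scalars `sigma_g2`, `sigma_e2`, `relationship`, `max_dev`
#'   (largest deviation between the two PEVMean routes, when both exist).
#' @examples
#' sc <- sim_scenario(n_cgs = 4, offspring_per_cg = 10, seed = 42)
#' herd <- simulate_herd(sc)
#' fit <- fit_connectedness(herd$records, herd$pedigree,
#'                          sigma_g2 = 1.81, sigma_e2 = 7.43)
#' tidy(fit)
#' glance(fit)
#' @export
fit_connectedness <- function(records, pedigree, sigma_g2, sigma_e2,
                              cg = "cg", factors = character(),
                              covariates = character(), centre = FALSE,
                              standardise = FALSE, trait = "y",
                              genotypes = NULL,
                              relationship = c("A", "H"),
                              blend_weight = 0.95,
                              pev = c("auto", "direct", "none"),
                              dense_limit = 5000, quiet = TRUE) {
  relationship <- match.arg(relationship)
  pev <- match.arg(pev)
  pedigree <- assert_pedigree(pedigree)
  design <- build_design(records, pedigree, cg = cg, factors = factors,
                         covariates = covariates, centre = centre,
                         standardise = standardise, trait = trait)
  q <- nrow(pedigree)
  A_inv <- build_A_inverse(pedigree)
  if (relationship == "H") {
    if (is.null(genotypes)) {
      stop("relationship 'H' requires a genotype dosage matrix", call. = FALSE)
    }
    geno_ids <- rownames(genotypes)
    if (is.null(geno_ids) || !all(geno_ids %in% pedigree$animal)) {
      stop("genotype rownames must be animal ids present in the pedigree",
           call. = FALSE)
    }
    G <- build_G(genotypes, quiet = quiet)
    A22 <- build_A22(pedigree, geno_ids, dense_limit = dense_limit)
    Gb <- blend_G(G, A22, weight = blend_weight)
    K_inv <- build_H_inverse(A_inv, A22, Gb,
                             match(geno_ids, pedigree$animal))
  } else {
    K_inv <- A_inv
  }
  system <- assemble_mme(design, K_inv, sigma_g2, sigma_e2)
  sol <- solve_mme(system)
  var_beta <- solve_fixed_block(system)
  pm3 <- pevmean_function3(var_beta, design, sigma_e2)

  pm_direct <- NULL
  kbar <- NULL
  if (pev == "direct" || (pev == "auto" && q <= dense_limit)) {
    pev_mat <- extract_pev(system, dense_limit = dense_limit)
    pm_direct <- pevmean_direct(pev_mat, design)
    # prior variance under the fitted K (dense inverse feasible at this size)
    K <- solve(as.matrix(K_inv))
    K <- (K + t(K)) / 2
    kbar <- prior_cg_variance(K, design, sigma_g2)
  }
  max_dev <- if (is.null(pm_direct)) NA_real_ else max(abs(pm3 - pm_direct))
  if (!quiet) {
    message("p1 = ", design$p1, ", p2 = ", design$p2, ", q = ", q,
            if (!is.na(max_dev))
              paste0(", max |function3 - direct| = ",
                     format(max_dev, digits = 3)))
  }
  report <- if (design$p1 >= 2) {
    connectedness_report(
      pm = if (is.null(pm_direct)) pm3 else pm_direct,
      var_beta1 = var_beta$vb1, n_per_cg = design$n_per_cg,
      sigma_e2 = sigma_e2, kbar = kbar,
      pm_check = if (is.null(pm_direct)) NULL else pm3)
  } else NULL
  X <- cbind(as.matrix(design$X1), design$X2)
  structure(
    list(design = design, system = system,
         beta_hat = sol$beta_hat, u_hat = sol$u_hat,
         var_beta = var_beta, pevmean = pm3, pevmean_direct = pm_direct,
         kbar = kbar, report = report,
         yhat_fixed = as.numeric(X %*% sol$beta_hat),
         sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
         relationship = relationship, max_dev = max_dev),
    class = "conn_fit"
  )
}

#' @export
print.conn_fit <- function(x, ...) {
  cat("<conn_fit> relationship =", x$relationship,
      "| p1 =", x$design$p1, ", p2 =", x$design$p2,
      ", q =", ncol(x$design$Z), ", n =", length(x$design$y), "\n")
  cat("  lambda =", format(x$system$lambda, digits = 6))
  if (!is.na(x$max_dev)) {
    cat(" | max |function3 - direct PEVMean| =", format(x$max_dev, digits = 3))
  }
  cat("\n")
  if (!is.null(x$report)) {
    cat("  pairwise report:", nrow(x$report), "contemporary-group pairs\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the pairwise connectedness report of a fit
#'
#' @param x A `conn_fit`.
#' @param ... Unused.
#' @return The pairwise report tibble (one row per CG pair).
#' @method tidy conn_fit
#' @export
tidy.conn_fit <- function(x, ...) {
  if (is.null(x$report)) {
    stop("fit has fewer than two contemporary groups", call. = FALSE)
  }
  x$report
}

#' One-row model summary of a connectedness fit
#'
#' @param x A `conn_fit`.
#' @param ... Unused.
#' @return One-row tibble: dimensions, variance components, lambda, the
#'   diagnostics bundle and the function-3 vs direct PEVMean deviation.
#' @export
glance.conn_fit <- function(x, ...) {
  dplyr::bind_cols(
    diagnostics_bundle(x),
    tibble::tibble(
      sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2,
      lambda = x$system$lambda, relationship = x$relationship,
      max_dev_direct = x$max_dev
    )
  )
}

#' Heatmap of a pairwise connectedness statistic
#'
#' @param object A `conn_report` tibble (or a `conn_fit`).
#' @param statistic Column to plot (default `"flock_r"`).
#' @param ... Unused.
#' @return A ggplot object: lower-triangle CG-by-CG heatmap.
#' @method autoplot conn_report
#' @export
autoplot.conn_report <- function(object, statistic = "flock_r", ...) {
  if (inherits(object, "conn_fit")) object <- object$report
  stopifnot(statistic %in% names(object))
  labs <- sort(unique(c(object$cg_i, object$cg_j)))
  df <- dplyr::mutate(object,
                      cg_i = factor(.data$cg_i, levels = labs),
                      cg_j = factor(.data$cg_j, levels = labs))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cg_i, y = .data$cg_j,
                                   fill = .data[[statistic]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = statistic) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste("Pairwise", statistic,
                                "between contemporary groups")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.conn_report
#' @method autoplot conn_fit
#' @export
autoplot.conn_fit <- function(object, statistic = "flock_r", ...) {
  autoplot.conn_report(object$report, statistic = statistic, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
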