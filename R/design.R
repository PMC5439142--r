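#' Build design matrices for the contemporary-group animal model
#'
#' Constructs the three incidence matrices of the single-trait animal model
#' \eqn{y = X_1 \beta_1 + X_2 \beta_2 + Z u + e}: `X1`, the full 0/1 incidence
#' of contemporary group (no reference level -- the intercept is absorbed into
#' the CG effect), `X2`, the incidence of all other fixed effects (categorical
#' effects in drop-first treatment coding, covariates optionally centred
#' and/or standardised on their global mean/sd), and `Z`, the 0/1 incidence
#' mapping records to animals in pedigree order.
#'
#' @param records Data frame with one row per record: an `animal` column, the
#'   contemporary-group column named by `cg`, any factor/covariate columns,
#'   and the trait column named by `trait`.
#' @param pedigree Ordered pedigree ([order_pedigree()]); every recorded
#'   animal must appear in it.
#' @param cg Name of the contemporary-group column.
#' @param factors Character vector of categorical fixed-effect columns.
#' @param covariates Character vector of continuous fixed-effect columns, or a
#'   data frame with columns `name`, `centre`, `standardise`.
#' @param centre,standardise Logical, recycled over `covariates` when given as
#'   a character vector.
#' @param trait Name of the trait column.
#' @return An object of class `conn_design`: list with `X1`, `X2`, `Z`
#'   (sparse), `y`, `cg_labels`, `n_per_cg`, `p1`, `p2`, `x2_names`,
#'   `animal_ids`.
#' @details CG labels are ordered lexicographically once and that order is
#'   propagated to every downstream matrix and report. Full column rank of
#'   `[X1 X2]` is verified; a rank-deficient coding (e.g. a factor constant
#'   within every CG) is an error naming the confounded columns.
#' @export
build_design <- function(records, pedigree, cg = "cg", factors = character(),
                         covariates = character(), centre = FALSE,
                         standardise = FALSE, trait = "y") {
  stopifnot(is.data.frame(records))
  pedigree <- assert_pedigree(pedigree)
  for (col in c("animal", cg, trait)) {
    if (!col %in% names(records)) {
      stop("records is missing column '", col, "'", call. = FALSE)
    }
  }
  if (anyNA(records[[cg]]) || anyNA(records[[trait]])) {
    stop("records with missing contemporary group or trait value", call. = FALSE)
  }
  animal <- as.character(records$animal)
  missing_ped <- setdiff(animal, pedigree$animal)
  if (length(missing_ped) > 0) {
    stop("recorded animal(s) absent from the pedigree: ",
         paste(utils::head(missing_ped, 5), collapse = ", "), call. = FALSE)
  }
  cov_spec <- normalise_cov_spec(covariates, centre, standardise)
  for (col in c(factors, cov_spec$name)) {
    if (!col %in% names(records)) {
      stop("model column '", col, "' not found in records", call. = FALSE)
    }
  }
  nrec <- nrow(records)

  cg_fac <- factor(as.character(records[[cg]]))
  cg_labels <- sort(levels(cg_fac))
  cg_fac <- factor(cg_fac, levels = cg_labels)
  X1 <- Matrix::sparseMatrix(i = seq_len(nrec), j = as.integer(cg_fac), x = 1,
                             dims = c(nrec, length(cg_labels)),
                             dimnames = list(NULL, cg_labels))
  n_per_cg <- as.integer(table(cg_fac))
  names(n_per_cg) <- cg_labels

  # X2: drop-first coding for factors, optionally transformed covariates
  x2_cols <- list()
  for (f in factors) {
    fv <- factor(as.character(records[[f]]))
    if (nlevels(fv) < 2) {
      stop("factor '", f, "' has a single level", call. = FALSE)
    }
    mm <- stats::model.matrix(~fv)[, -1, drop = FALSE]
    colnames(mm) <- paste0(f, levels(fv)[-1])
    x2_cols[[f]] <- mm
  }
  if (nrow(cov_spec) > 0) {
    for (r in seq_len(nrow(cov_spec))) {
      v <- as.numeric(records[[cov_spec$name[r]]])
      if (anyNA(v)) stop("covariate '", cov_spec$name[r], "' has missing values",
                         call. = FALSE)
      if (cov_spec$centre[r] || cov_spec$standardise[r]) v <- v - mean(v)
      if (cov_spec$standardise[r]) v <- v / stats::sd(v)
      x2_cols[[paste0("cov_", cov_spec$name[r])]] <-
        matrix(v, ncol = 1, dimnames = list(NULL, cov_spec$name[r]))
    }
  }
  X2 <- if (length(x2_cols) > 0) do.call(cbind, unname(x2_cols)) else
    matrix(0, nrec, 0)
  p1 <- length(cg_labels)
  p2 <- ncol(X2)
  Xfull <- cbind(as.matrix(X1), X2)
  qr_x <- qr(Xfull)
  if (qr_x$rank < p1 + p2) {
    dropped <- colnames(Xfull)[qr_x$pivot[seq(qr_x$rank + 1, p1 + p2)]]
    stop("design is rank deficient; confounded column(s): ",
         paste(dropped, collapse = ", "),
         " (a factor constant within every contemporary group?)", call. = FALSE)
  }

  q <- nrow(pedigree)
  ai <- match(animal, pedigree$animal)
  Z <- Matrix::sparseMatrix(i = seq_len(nrec), j = ai, x = 1,
                            dims = c(nrec, q),
                            dimnames = list(NULL, pedigree$animal))
  structure(
    list(X1 = X1, X2 = X2, Z = Z, y = as.numeric(records[[trait]]),
         cg_labels = cg_labels, n_per_cg = n_per_cg, p1 = p1, p2 = p2,
         x2_names = colnames(X2), animal_ids = pedigree$animal,
         cg_of_record = as.integer(cg_fac)),
    class = "conn_design"
  )
}

normalise_cov_spec <- function(covariates, centre, standardise) {
  if (is.data.frame(covariates)) {
    stopifnot("name" %in% names(covariates))
    out <- tibble::tibble(
      name = as.character(covariates$name),
      centre = if ("centre" %in% names(covariates)) covariates$centre else FALSE,
      standardise = if ("standardise" %in% names(covariates))
        covariates$standardise else FALSE
    )
    return(out)
  }
  covariates <- as.character(covariates)
  tibble::tibble(
    name = covariates,
    centre = rep_len(as.logical(centre), length(covariates)),
    standardise = rep_len(as.logical(standardise), length(covariates))
  )
}

#' @export
print.conn_design <- function(x, ...) {
  cat("<conn_design> ", length(x$y), " records, p1 =", x$p1,
      "contemporary groups, p2 =", x$p2, "other fixed-effect columns, q =",
      ncol(x$Z), "animals\n")
  invisible(x)
}

#' Orthogonality between contemporary groups and other fixed effects
#'
#' Checks whether `X1'X2 = 0`. When it holds the other-fixed-effects
#' correction factor vanishes and PEVMean can be computed as if contemporary
#' group were the only fixed effect. Element (i, j) of `X1'X2` is the count of
#' level j in CG i for a categorical effect, or the within-CG sum of the
#' covariate for a continuous effect.
#'
#' @param design A `conn_design`, or the `X1` matrix if `X2` is also given.
#' @param X2 Optional second design block when `design` is `X1`.
#' @param tol Absolute tolerance on the largest element.
#' @return Logical scalar with attribute `cross` holding `X1'X2`.
#' @export
check_orthogonality <- function(design, X2 = NULL, tol = 1e-10) {
  if (inherits(design, "conn_design")) {
    X1 <- design$X1
    X2 <- design$X2
  } else {
    X1 <- design
    stopifnot(!is.null(X2))
  }
  cross <- as.matrix(Matrix::crossprod(X1, X2))
  ok <- ncol(cross) == 0 || max(abs(cross)) < tol
  structure(ok, cross = cross)
}

# (X1'X1)^{-1} X1'Z: record-weighted CG averaging operator (p1 x q)
cg_average_operator <- function(design) {
  XtZ <- Matrix::crossprod(design$X1, design$Z)
  as.matrix(XtZ / design$n_per_cg)
}

# (X1'X1)^{-1} X1'X2: per-CG means of the X2 columns (p1 x p2)
cg_mean_x2 <- function(design) {
  if (design$p2 == 0) return(matrix(0, design$p1, 0))
  as.matrix(Matrix::crossprod(design$X1, design$X2) / design$n_per_cg)
}
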