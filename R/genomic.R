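#' Genomic relationship matrix (VanRaden method 1)
#'
#' G = M M' / (2 * sum_j p_j (1 - p_j)) where M is the dosage matrix centred
#' by twice the allele frequency per marker. Allele frequencies default to the
#' observed frequencies in the genotyped sample; a per-marker override can be
#' supplied (e.g. base-population frequencies).
#'
#' @param dosages Numeric matrix, animals x markers, entries 0/1/2, rownames =
#'   animal ids.
#' @param allele_freq Optional numeric vector of per-marker allele frequencies
#'   in (0, 1); defaults to `colMeans(dosages) / 2`.
#' @param quiet Suppress the message about dropped monomorphic markers.
#' @return Dense symmetric matrix over genotyped animals, attribute
#'   `kind = "G"` and attribute `n_markers_used`.
#' @export
build_G <- function(dosages, allele_freq = NULL, quiet = FALSE) {
  dosages <- as.matrix(dosages)
  stopifnot(nrow(dosages) >= 2, ncol(dosages) >= 1)
  if (!all(dosages %in% c(0, 1, 2))) {
    stop("dosages must be coded 0/1/2", call. = FALSE)
  }
  p <- if (is.null(allele_freq)) colMeans(dosages) / 2 else allele_freq
  stopifnot(length(p) == ncol(dosages))
  poly <- p > 0 & p < 1
  if (!any(poly)) {
    stop("all markers are monomorphic: VanRaden denominator is zero", call. = FALSE)
  }
  if (any(!poly) && !quiet) {
    message(sum(!poly), " monomorphic marker(s) dropped")
  }
  M <- sweep(dosages[, poly, drop = FALSE], 2, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- tcrossprod(M) / denom
  G <- (G + t(G)) / 2
  attr(G, "kind") <- "G"
  attr(G, "n_markers_used") <- sum(poly)
  G
}

#' Blend a genomic relationship matrix with its pedigree counterpart
#'
#' Returns `weight * G + (1 - weight) * A22`. Blending guarantees
#' invertibility of G when genotyped animals are duplicated or the marker
#' panel is small; `weight = 1` leaves G unchanged.
#'
#' @param G Genomic relationship matrix from [build_G()].
#' @param A22 Pedigree relationships among the same animals, same order.
#' @param weight Fraction in (0, 1]; default 0.95, standard single-step
#'   practice.
#' @return Dense symmetric matrix, attribute `kind = "G"`.
#' @export
blend_G <- function(G, A22, weight = 0.95) {
  stopifnot(weight > 0, weight <= 1)
  if (!all(dim(G) == dim(A22))) {
    stop("G and A22 have mismatched dimensions", call. = FALSE)
  }
  out <- weight * as.matrix(G) + (1 - weight) * as.matrix(A22)
  dimnames(out) <- dimnames(G)
  attr(out, "kind") <- "G"
  out
}

#' Single-step H-inverse (Aguilar construction)
#'
#' H-inverse equals A-inverse plus the genomic increment
#' \eqn{G^{-1} - A_{22}^{-1}} added into the block of genotyped animals. When
#' G equals A22 the increment vanishes and H-inverse reduces to A-inverse.
#' The tau/omega scalings are fixed at 1 (the plain construction).
#'
#' @param A_inv Sparse A-inverse over the full pedigree, from
#'   [build_A_inverse()].
#' @param A22 Pedigree relationship block among genotyped animals.
#' @param G Blended genomic relationship matrix, same animals and order as
#'   `A22`.
#' @param genotyped_index Integer positions of the genotyped animals in
#'   pedigree order, or character ids.
#' @return Sparse symmetric [Matrix::Matrix], attribute `kind = "H_inverse"`.
#' @export
build_H_inverse <- function(A_inv, A22, G, genotyped_index) {
  n <- nrow(A_inv)
  if (is.character(genotyped_index)) {
    genotyped_index <- match(genotyped_index, rownames(A_inv))
  }
  idx <- as.integer(genotyped_index)
  stopifnot(!anyNA(idx), all(idx >= 1), all(idx <= n),
            nrow(A22) == length(idx), nrow(G) == length(idx))
  Ginv <- try_inverse(G, "G (blend with A22 via blend_G)")
  A22inv <- try_inverse(A22, "A22")
  H_inv <- as(A_inv, "generalMatrix")
  H_inv[idx, idx] <- H_inv[idx, idx] + (Ginv - A22inv)
  H_inv <- Matrix::forceSymmetric((H_inv + Matrix::t(H_inv)) / 2)
  attr(H_inv, "kind") <- "H_inverse"
  H_inv
}

try_inverse <- function(M, what) {
  M <- as.matrix(M)
  rc <- rcond(M)
  if (!is.finite(rc) || rc < 1e-12) {
    stop("matrix ", what, " is singular or near-singular (rcond = ",
         format(rc, digits = 3), ")", call. = FALSE)
  }
  solve(M)
}
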