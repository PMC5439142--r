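#' Order a pedigree so parents precede offspring
#'
#' Takes a raw pedigree table (one row per animal, with its sire and dam) and
#' returns a topologically ordered pedigree in which every parent appears
#' before any of its offspring. Unknown parents are coded `"0"`, `""` or `NA`.
#' Animals that appear only as parents are promoted to founders with a message.
#'
#' @param ped A data frame with columns `animal`, `sire`, `dam` (ids coerced to
#'   character).
#' @param quiet Suppress the message about auto-promoted founders.
#' @return A tibble of class `conn_pedigree` with columns `animal`, `sire`,
#'   `dam` (character, `"0"` = unknown) and integer columns `sire_idx`,
#'   `dam_idx` (0 = unknown) giving parent positions in the returned order.
#' @details Ordering is a stable topological sort: ties are broken by first
#'   appearance in the input, so re-running on an already ordered pedigree is a
#'   no-op. Cyclic ancestry (an animal being its own ancestor) is an error and
#'   the offending id chain is reported.
#' @examples
#' ped <- data.frame(animal = c("3", "1", "2"),
#'                   sire   = c("1", "0", "0"),
#'                   dam    = c("2", "0", "0"))
#' order_pedigree(ped)
#' @export
order_pedigree <- function(ped, quiet = FALSE) {
  stopifnot(is.data.frame(ped))
  cols <- c("animal", "sire", "dam")
  if (!all(cols %in% names(ped))) {
    stop("pedigree must have columns 'animal', 'sire', 'dam'", call. = FALSE)
  }
  animal <- as.character(ped$animal)
  sire <- norm_parent(ped$sire)
  dam <- norm_parent(ped$dam)
  if (anyNA(animal) || any(animal == "0") || any(animal == "")) {
    stop("animal ids must be non-missing and not the sentinel '0'", call. = FALSE)
  }
  if (anyDuplicated(animal)) {
    dup <- unique(animal[duplicated(animal)])
    stop("duplicate animal id(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  parents <- setdiff(unique(c(sire, dam)), c("0", animal))
  if (length(parents) > 0) {
    if (!quiet) {
      message(length(parents), " animal(s) appearing only as parents promoted to founders")
    }
    animal <- c(parents, animal)
    sire <- c(rep("0", length(parents)), sire)
    dam <- c(rep("0", length(parents)), dam)
  }
  n <- length(animal)
  pos <- stats::setNames(seq_len(n), animal)
  si <- ifelse(sire == "0", 0L, pos[sire])
  di <- ifelse(dam == "0", 0L, pos[dam])

  if (all(si < seq_len(n)) && all(di < seq_len(n))) {
    order_out <- seq_len(n)            # already parents-first: keep as is
  } else {
    # Kahn's algorithm; ties broken by input position (smallest ready index
    # first), so ordering is stable and idempotent
    indeg <- integer(n)
    kids <- vector("list", n)
    for (i in seq_len(n)) {
      for (p in c(si[i], di[i])) {
        if (p > 0L) {
          indeg[i] <- indeg[i] + 1L
          kids[[p]] <- c(kids[[p]], i)
        }
      }
    }
    order_out <- integer(0)
    ready <- indeg == 0L
    while (any(ready)) {
      v <- which.max(ready)            # smallest index currently ready
      ready[v] <- FALSE
      indeg[v] <- -1L
      order_out <- c(order_out, v)
      for (k in kids[[v]]) {
        indeg[k] <- indeg[k] - 1L
        if (indeg[k] == 0L) ready[k] <- TRUE
      }
    }
    if (length(order_out) < n) {
      bad <- setdiff(seq_len(n), order_out)
      chain <- cycle_chain(bad[1], si, di, animal)
      stop("cyclic ancestry detected involving: ",
           paste(chain, collapse = " -> "), call. = FALSE)
    }
  }
  newpos <- integer(n)
  newpos[order_out] <- seq_len(n)
  out <- tibble::tibble(
    animal = animal[order_out],
    sire = sire[order_out],
    dam = dam[order_out],
    sire_idx = ifelse(si[order_out] > 0L, newpos[pmax(si[order_out], 1L)], 0L),
    dam_idx = ifelse(di[order_out] > 0L, newpos[pmax(di[order_out], 1L)], 0L)
  )
  out$sire_idx <- as.integer(out$sire_idx)
  out$dam_idx <- as.integer(out$dam_idx)
  class(out) <- c("conn_pedigree", class(out))
  out
}

norm_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- "0"
  x
}

# follow parent links from a node stuck in a cycle until an id repeats
cycle_chain <- function(start, si, di, ids) {
  seen <- integer(0)
  v <- start
  repeat {
    if (v %in% seen) {
      seen <- c(seen, v)
      return(ids[seen])
    }
    seen <- c(seen, v)
    nxt <- if (si[v] > 0L) si[v] else di[v]
    if (is.na(nxt) || nxt == 0L) return(ids[seen])
    v <- nxt
  }
}

is_ordered_pedigree <- function(ped) {
  inherits(ped, "conn_pedigree") &&
    all(ped$sire_idx < seq_len(nrow(ped))) &&
    all(ped$dam_idx < seq_len(nrow(ped)))
}

assert_pedigree <- function(ped) {
  if (!inherits(ped, "conn_pedigree")) ped <- order_pedigree(ped, quiet = TRUE)
  stopifnot(is_ordered_pedigree(ped))
  ped
}

#' Numerator relationship matrix by the tabular method
#'
#' Builds the dense additive (numerator) relationship matrix A by the tabular
#' recursion: \eqn{A_{ij} = (A_{j,s_i} + A_{j,d_i})/2} for \eqn{j < i} and
#' \eqn{A_{ii} = 1 + A_{s_i d_i}/2}, so the diagonal is \eqn{1 + F_i} with
#' \eqn{F_i} the inbreeding coefficient.
#'
#' @param ped An ordered pedigree from [order_pedigree()] (unordered input is
#'   ordered internally).
#' @param dense_limit Refuse to build a dense A beyond this many animals.
#' @return A dense symmetric matrix with animal ids as dimnames and attribute
#'   `kind = "A"`.
#' @export
build_A <- function(ped, dense_limit = 5000) {
  ped <- assert_pedigree(ped)
  n <- nrow(ped)
  if (n > dense_limit) {
    stop("pedigree has ", n, " animals; dense A limited to ", dense_limit,
         " (use build_A_inverse for the mixed model equations)", call. = FALSE)
  }
  A <- matrix(0, n, n)
  s <- ped$sire_idx
  d <- ped$dam_idx
  for (i in seq_len(n)) {
    if (i > 1) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s[i] > 0L) row <- row + 0.5 * A[s[i], j]
      if (d[i] > 0L) row <- row + 0.5 * A[d[i], j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (s[i] > 0L && d[i] > 0L) 0.5 * A[s[i], d[i]] else 0
  }
  dimnames(A) <- list(ped$animal, ped$animal)
  attr(A, "kind") <- "A"
  A
}

#' Inbreeding coefficients by the Meuwissen-Luo recursion
#'
#' Computes per-animal inbreeding coefficients F without forming A, by tracing
#' each animal's ancestors and accumulating the squared path contributions
#' against the Mendelian sampling variances. This is the recursion used inside
#' [build_A_inverse()]; it is independent of the tabular method in [build_A()].
#'
#' @inheritParams build_A
#' @return Named numeric vector of inbreeding coefficients in pedigree order.
#' @export
inbreeding <- function(ped) {
  ped <- assert_pedigree(ped)
  ml_recursion(ped)$F
}

# Meuwissen-Luo: per-animal Mendelian sampling variance coefficients d_i and
# inbreeding F_i. For animal i, A_ii = sum_j L_j^2 d_j over ancestors j, with
# L the gene-contribution vector of i; F_i = A_ii - 1. Unknown parents are
# unrelated, non-inbred base animals.
ml_recursion <- function(ped) {
  n <- nrow(ped)
  s <- ped$sire_idx
  d <- ped$dam_idx
  F <- numeric(n)
  D <- numeric(n)
  for (i in seq_len(n)) {
    fs <- if (s[i] > 0L) F[s[i]] else -1
    fd <- if (d[i] > 0L) F[d[i]] else -1
    D[i] <- 0.5 - 0.25 * (fs + fd)
    if (s[i] == 0L || d[i] == 0L) {
      F[i] <- 0
      next
    }
    # trace ancestors of i: L starts at 1 for i, each parent receives half
    L <- numeric(i)
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      lj <- L[j]
      if (lj == 0) next
      if (s[j] > 0L) L[s[j]] <- L[s[j]] + 0.5 * lj
      if (d[j] > 0L) L[d[j]] <- L[d[j]] + 0.5 * lj
      aii <- aii + lj * lj * D[j]
    }
    F[i] <- aii - 1
  }
  list(F = stats::setNames(F, ped$animal), D = D)
}

#' Sparse inverse of the numerator relationship matrix (Meuwissen-Luo)
#'
#' Assembles A-inverse directly from per-animal contributions without ever
#' forming A: each animal adds \eqn{\alpha_i = 1/d_i} to its own diagonal,
#' \eqn{-\alpha_i/2} to the animal-parent cells and \eqn{\alpha_i/4} to the
#' parent-parent cells, where \eqn{d_i} is the Mendelian sampling variance
#' coefficient computed with exact parental inbreeding.
#'
#' @inheritParams build_A
#' @return A sparse symmetric [Matrix::Matrix] with animal ids as dimnames and
#'   attribute `kind = "A_inverse"`.
#' @export
build_A_inverse <- function(ped) {
  ped <- assert_pedigree(ped)
  n <- nrow(ped)
  D <- ml_recursion(ped)$D
  s <- ped$sire_idx
  d <- ped$dam_idx
  alpha <- 1 / D
  # triplet accumulation: diagonal of animal, cross terms with known parents
  tr_i <- list(); tr_j <- list(); tr_x <- list(); k <- 1L
  push <- function(i, j, x) {
    tr_i[[k]] <<- i; tr_j[[k]] <<- j; tr_x[[k]] <<- x; k <<- k + 1L
  }
  idx <- seq_len(n)
  push(idx, idx, alpha)
  hs <- s > 0L
  hd <- d > 0L
  push(idx[hs], s[hs], -0.5 * alpha[hs])
  push(s[hs], idx[hs], -0.5 * alpha[hs])
  push(idx[hd], d[hd], -0.5 * alpha[hd])
  push(d[hd], idx[hd], -0.5 * alpha[hd])
  push(s[hs], s[hs], 0.25 * alpha[hs])
  push(d[hd], d[hd], 0.25 * alpha[hd])
  both <- hs & hd
  push(s[both], d[both], 0.25 * alpha[both])
  push(d[both], s[both], 0.25 * alpha[both])
  Ainv <- Matrix::sparseMatrix(
    i = unlist(tr_i), j = unlist(tr_j), x = unlist(tr_x),
    dims = c(n, n), dimnames = list(ped$animal, ped$animal)
  )
  Ainv <- Matrix::forceSymmetric((Ainv + Matrix::t(Ainv)) / 2)
  attr(Ainv, "kind") <- "A_inverse"
  Ainv
}

#' Pedigree relationships among a subset of animals
#'
#' Extracts the block of the numerator relationship matrix for a set of
#' animals (typically the genotyped subset, the A22 block of single-step
#' evaluations).
#'
#' @inheritParams build_A
#' @param animals Character vector of animal ids.
#' @return Dense symmetric matrix over `animals`, attribute `kind = "A22"`.
#' @export
build_A22 <- function(ped, animals, dense_limit = 5000) {
  ped <- assert_pedigree(ped)
  stopifnot(all(animals %in% ped$animal))
  A <- build_A(ped, dense_limit = dense_limit)
  out <- A[animals, animals, drop = FALSE]
  attr(out, "kind") <- "A22"
  out
}
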