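#' Define a synthetic multi-flock breeding scenario
#'
#' Parameters for the synthetic herd generator, which emulates a multi-flock
#' sheep evaluation: several flocks (one contemporary group each), founder
#' animals per flock, discrete generations of offspring, link sires shared
#' across flocks, a quantitative trait \eqn{y = X\beta + Zu + e} with
#' \eqn{u \sim N(0, \sigma^2_g A)}, and optionally gene-dropped SNP genotypes
#' for a subset of animals.
#'
#' @param n_founders Total founder animals, split evenly across flocks
#'   (>= 4 per flock).
#' @param n_generations Discrete offspring generations.
#' @param n_cgs Number of flocks = contemporary groups.
#' @param offspring_per_cg Offspring born per flock per generation.
#' @param link_sire_fraction Probability that a mating uses a sire from the
#'   shared cross-flock ram team rather than a flock-private sire; 0 gives
#'   fully disconnected flocks.
#' @param sigma_g2,sigma_e2 Variance components of the trait (defaults 1.81
#'   and 7.43 trait units squared, heritability 0.20).
#' @param cg_effect_sd Standard deviation of the contemporary-group fixed
#'   effects (trait units).
#' @param factor_levels Integer vector: one entry per extra categorical fixed
#'   effect, giving its number of levels (empty = none).
#' @param factor_effect_sd Standard deviation of non-reference factor-level
#'   effects.
#' @param covariate_means,covariate_sds,covariate_slopes Numeric vectors, one
#'   entry per extra continuous fixed effect (empty = none). A non-zero mean
#'   makes the absorbed-intercept CG variances sensitive to the covariate
#'   scale, which is the behaviour the correction factor addresses.
#' @param balanced If `TRUE`, factor levels are allocated in equal proportion
#'   within every CG and covariates are shifted to an identical mean in every
#'   CG (the balanced-effects regime in which corrected VED equals PEVD).
#' @param n_markers SNP markers for gene dropping (0 = no genotypes).
#' @param genotyped_fraction Fraction of animals genotyped.
#' @param seed Integer seed; identical scenario + seed reproduces the data
#'   exactly.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_founders = 80, n_generations = 2, n_cgs = 8,
                         offspring_per_cg = 25, link_sire_fraction = 0.5,
                         sigma_g2 = 1.81, sigma_e2 = 7.43,
                         cg_effect_sd = 2,
                         factor_levels = integer(),
                         factor_effect_sd = 1,
                         covariate_means = numeric(),
                         covariate_sds = numeric(),
                         covariate_slopes = numeric(),
                         balanced = FALSE,
                         n_markers = 0L, genotyped_fraction = 0,
                         seed = 1L) {
  stopifnot(n_cgs >= 1, n_founders >= 4 * n_cgs, n_generations >= 1,
            offspring_per_cg >= 1,
            link_sire_fraction >= 0, link_sire_fraction <= 1,
            sigma_g2 > 0, sigma_e2 > 0,
            genotyped_fraction >= 0, genotyped_fraction <= 1)
  k <- length(covariate_means)
  stopifnot(length(covariate_sds) == k, length(covariate_slopes) == k)
  structure(
    list(n_founders = n_founders, n_generations = n_generations,
         n_cgs = n_cgs, offspring_per_cg = offspring_per_cg,
         link_sire_fraction = link_sire_fraction,
         sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
         cg_effect_sd = cg_effect_sd,
         factor_levels = as.integer(factor_levels),
         factor_effect_sd = factor_effect_sd,
         covariate_means = covariate_means, covariate_sds = covariate_sds,
         covariate_slopes = covariate_slopes, balanced = balanced,
         n_markers = as.integer(n_markers),
         genotyped_fraction = genotyped_fraction, seed = as.integer(seed)),
    class = "sim_scenario"
  )
}

#' Simulate a multi-flock pedigree and record table
#'
#' Founders are split across flocks; each generation every flock produces
#' `offspring_per_cg` lambs from flock dams and either flock-private sires or
#' shared link sires. Breeding values follow the pedigree recursion
#' \eqn{u_i = (u_s + u_d)/2 + m_i} with Mendelian sampling variance
#' \eqn{\sigma^2_g (0.5 - 0.25(F_s + F_d))} using exact parental inbreeding,
#' so the covariance of `u` is exactly \eqn{\sigma^2_g A}. One record per
#' non-founder animal, in the contemporary group (flock) of its birth.
#'
#' @param sc A [sim_scenario()].
#' @return List with `pedigree` (a `conn_pedigree`), `records` (tibble:
#'   `animal`, `cg`, factor/covariate columns, `y`) and `truth` (list of the
#'   simulated fixed effects, breeding values and residuals).
#' @export
simulate_herd <- function(sc) {
  stopifnot(inherits(sc, "sim_scenario"))
  set.seed(sc$seed)
  per_flock <- sc$n_founders %/% sc$n_cgs
  id <- character(0); sire <- character(0); dam <- character(0)
  sex <- character(0); flock <- integer(0); gen <- integer(0)
  counter <- 0L
  new_id <- function() {
    counter <<- counter + 1L
    sprintf("ID%05d", counter)
  }
  for (f in seq_len(sc$n_cgs)) {
    n_m <- max(1L, per_flock %/% 4L)
    for (k in seq_len(per_flock)) {
      id <- c(id, new_id()); sire <- c(sire, "0"); dam <- c(dam, "0")
      sex <- c(sex, if (k <= n_m) "M" else "F")
      flock <- c(flock, f); gen <- c(gen, 0L)
    }
  }
  for (g in seq_len(sc$n_generations)) {
    # snapshot of candidates born before this generation; vectors grow below
    n_avail <- length(id)
    avail_sex <- sex[seq_len(n_avail)]
    avail_flock <- flock[seq_len(n_avail)]
    avail_gen <- gen[seq_len(n_avail)]
    males_all <- which(avail_gen < g & avail_sex == "M")
    link_team <- if (length(males_all) > 1)
      resample(males_all, min(length(males_all),
                              max(2L, ceiling(0.25 * sc$n_cgs)))) else males_all
    for (f in seq_len(sc$n_cgs)) {
      fl_m <- which(avail_gen < g & avail_sex == "M" & avail_flock == f)
      fl_f <- which(avail_gen < g & avail_sex == "F" & avail_flock == f)
      if (length(fl_m) == 0 || length(fl_f) == 0) {
        stop("flock ", f, " has no available sires or dams", call. = FALSE)
      }
      for (k in seq_len(sc$offspring_per_cg)) {
        use_link <- sc$link_sire_fraction > 0 &&
          stats::runif(1) < sc$link_sire_fraction
        s <- if (use_link) resample(link_team, 1) else resample(fl_m, 1)
        d <- resample(fl_f, 1)
        id <- c(id, new_id()); sire <- c(sire, id[s]); dam <- c(dam, id[d])
        sex <- c(sex, sample(c("M", "F"), 1))
        flock <- c(flock, f); gen <- c(gen, g)
      }
    }
  }
  ped <- order_pedigree(
    data.frame(animal = id, sire = sire, dam = dam), quiet = TRUE)
  # generator emits parents before offspring, so order is unchanged
  stopifnot(identical(ped$animal, id))

  u <- simulate_breeding_values(ped, sc$sigma_g2)

  rec_sel <- gen > 0L
  rec_ids <- id[rec_sel]
  rec_cg <- sprintf("CG%02d", flock[rec_sel])
  nrec <- length(rec_ids)
  cg_labels <- sprintf("CG%02d", seq_len(sc$n_cgs))
  beta_cg <- stats::rnorm(sc$n_cgs, 0, sc$cg_effect_sd)
  names(beta_cg) <- cg_labels
  records <- tibble::tibble(animal = rec_ids, cg = rec_cg)
  mu_fixed <- beta_cg[rec_cg]

  factor_effects <- list()
  for (fk in seq_along(sc$factor_levels)) {
    L <- sc$factor_levels[fk]
    lv <- paste0("L", seq_len(L))
    if (sc$balanced) {
      lev <- character(nrec)
      for (ix in split(seq_len(nrec), rec_cg)) {
        lev[ix] <- lv[(seq_along(ix) - 1L) %% L + 1L]
      }
    } else {
      lev <- sample(lv, nrec, replace = TRUE)
    }
    eff <- c(0, stats::rnorm(L - 1, 0, sc$factor_effect_sd))
    names(eff) <- lv
    records[[paste0("factor", fk)]] <- lev
    mu_fixed <- mu_fixed + eff[lev]
    factor_effects[[paste0("factor", fk)]] <- eff
  }
  cov_slopes <- sc$covariate_slopes
  for (ck in seq_along(sc$covariate_means)) {
    v <- stats::rnorm(nrec, sc$covariate_means[ck], sc$covariate_sds[ck])
    if (sc$balanced) {
      cg_means <- tapply(v, rec_cg, mean)
      v <- v - cg_means[rec_cg] + sc$covariate_means[ck]
    }
    records[[paste0("cov", ck)]] <- as.numeric(v)
    mu_fixed <- mu_fixed + cov_slopes[ck] * v
  }
  e <- stats::rnorm(nrec, 0, sqrt(sc$sigma_e2))
  records$y <- as.numeric(mu_fixed + u[rec_ids] + e)
  list(
    pedigree = ped,
    records = records,
    truth = list(beta_cg = beta_cg, factor_effects = factor_effects,
                 covariate_slopes = cov_slopes, u = u, e = e,
                 sex = stats::setNames(sex, id),
                 flock = stats::setNames(flock, id),
                 generation = stats::setNames(gen, id))
  )
}

# sample() treats a length-1 numeric as 1:x; this never does
resample <- function(x, size) x[sample.int(length(x), size)]

#' Draw breeding values with covariance sigma_g2 * A
#'
#' Cholesky-free pedigree recursion: \eqn{u_i = (u_s + u_d)/2 + m_i} with
#' Mendelian sampling variance \eqn{\sigma^2_g (0.5 - 0.25 (F_s + F_d))}
#' (exact parental inbreeding; unknown parents contribute variance as
#' unrelated, non-inbred base animals). The sample covariance over replicates
#' converges to \eqn{\sigma^2_g A}.
#'
#' @param ped An ordered pedigree.
#' @param sigma_g2 Additive genetic variance.
#' @return Named numeric vector of breeding values in pedigree order. Uses
#'   the current RNG state; seed control is the caller's responsibility.
#' @export
simulate_breeding_values <- function(ped, sigma_g2) {
  ped <- assert_pedigree(ped)
  Fcoef <- unname(inbreeding(ped))
  n <- nrow(ped)
  u <- numeric(n)
  for (i in seq_len(n)) {
    s <- ped$sire_idx[i]; d <- ped$dam_idx[i]
    if (s == 0L && d == 0L) {
      u[i] <- stats::rnorm(1, 0, sqrt(sigma_g2))
    } else if (s > 0L && d > 0L) {
      v <- sigma_g2 * (0.5 - 0.25 * (Fcoef[s] + Fcoef[d]))
      u[i] <- 0.5 * (u[s] + u[d]) + stats::rnorm(1, 0, sqrt(v))
    } else {
      p <- max(s, d)
      v <- sigma_g2 * (0.75 - 0.25 * Fcoef[p])
      u[i] <- 0.5 * u[p] + stats::rnorm(1, 0, sqrt(v))
    }
  }
  stats::setNames(u, ped$animal)
}

#' Gene-drop SNP genotypes down a pedigree
#'
#' Per marker, a founder allele frequency is drawn from Uniform(0.1, 0.9),
#' founder haplotypes are Bernoulli draws at that frequency, and each
#' offspring inherits one uniformly chosen haplotype allele from each parent
#' (markers independent, i.e. no linkage). Expected genomic relationships
#' among genotyped animals equal their pedigree relationships.
#'
#' @param ped An ordered pedigree.
#' @param sc A [sim_scenario()] with `n_markers >= 1`; `genotyped_fraction`
#'   controls the genotyped subset.
#' @param animals Optional character vector forcing the genotyped subset.
#' @return List with `dosages` (genotyped animals x markers, 0/1/2, rownames
#'   = ids), `founder_freq` (the simulated per-marker frequencies) and
#'   `monomorphic` (logical flags for markers with no variation among the
#'   genotyped subset).
#' @export
simulate_genotypes <- function(ped, sc, animals = NULL) {
  stopifnot(inherits(sc, "sim_scenario"), sc$n_markers >= 1)
  ped <- assert_pedigree(ped)
  set.seed(sc$seed + 1000003L)
  n <- nrow(ped)
  m <- sc$n_markers
  p <- stats::runif(m, 0.1, 0.9)
  h1 <- matrix(0L, n, m)
  h2 <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    s <- ped$sire_idx[i]; d <- ped$dam_idx[i]
    h1[i, ] <- if (s > 0L) {
      ifelse(stats::runif(m) < 0.5, h1[s, ], h2[s, ])
    } else {
      as.integer(stats::runif(m) < p)
    }
    h2[i, ] <- if (d > 0L) {
      ifelse(stats::runif(m) < 0.5, h1[d, ], h2[d, ])
    } else {
      as.integer(stats::runif(m) < p)
    }
  }
  dos <- h1 + h2
  rownames(dos) <- ped$animal
  colnames(dos) <- sprintf("SNP%04d", seq_len(m))
  if (is.null(animals)) {
    n_geno <- ceiling(sc$genotyped_fraction * n)
    if (n_geno == 0) n_geno <- n   # fraction 0 with markers requested: all
    animals <- sort(resample(ped$animal, n_geno))
  }
  dos <- dos[animals, , drop = FALSE]
  mono <- apply(dos, 2, function(x) length(unique(x)) == 1L)
  list(dosages = dos, founder_freq = p, monomorphic = mono)
}
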