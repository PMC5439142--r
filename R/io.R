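#' Read and write the pedigree CSV dialect
#'
#' Header `animal,sire,dam`; ids are strings; `0` or empty = unknown parent.
#'
#' @param path File path.
#' @return `read_pedigree()`: an ordered `conn_pedigree`.
#' @export
read_pedigree <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  order_pedigree(as.data.frame(df), quiet = TRUE)
}

#' @rdname read_pedigree
#' @param ped Pedigree to write.
#' @export
write_pedigree <- function(ped, path) {
  ped <- assert_pedigree(ped)
  readr::write_csv(ped[, c("animal", "sire", "dam")], path)
  invisible(path)
}

#' Read and write the record-table CSV dialect
#'
#' One row per record; an `animal` column, a contemporary-group column, any
#' factor/covariate columns and the trait column. Column types other than
#' `animal` and `cg` (kept as character) are guessed by readr.
#'
#' @param path File path.
#' @param cg Name of the contemporary-group column (read as character).
#' @return `read_records()`: a tibble.
#' @export
read_records <- function(path, cg = "cg") {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                        show_col_types = FALSE)
  df$animal <- as.character(df$animal)
  if (cg %in% names(df)) df[[cg]] <- as.character(df[[cg]])
  df
}

#' @rdname read_records
#' @param records Record table to write.
#' @export
write_records <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' Read a genotype dosage matrix
#'
#' Accepts two dialects: plain CSV with first column `animal` and remaining
#' columns 0/1/2 marker dosages, and the PLINK RAW dialect (whitespace
#' separated, header `FID IID PAT MAT SEX PHENOTYPE SNP1 ...`) where `IID` is
#' used as the animal id.
#'
#' @param path File path.
#' @return Numeric matrix animals x markers with animal-id rownames.
#' @export
read_genotypes <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("^FID[ \t]", first)) {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    ids <- as.character(df$IID)
    M <- as.matrix(df[, -(1:6), drop = FALSE])
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    ids <- as.character(df$animal)
    M <- as.matrix(df[, setdiff(names(df), "animal"), drop = FALSE])
  }
  storage.mode(M) <- "double"
  rownames(M) <- ids
  M
}

#' @rdname read_genotypes
#' @param dosages Dosage matrix (rownames = animal ids) to write as CSV.
#' @export
write_genotypes <- function(dosages, path) {
  df <- tibble::as_tibble(dosages, rownames = "animal")
  readr::write_csv(df, path)
  invisible(path)
}

#' Write and read a labelled square matrix as CSV
#'
#' Row labels in the first column `label`, column labels in the header.
#'
#' @param m Square matrix with dimnames.
#' @param path File path.
#' @export
write_matrix_csv <- function(m, path) {
  df <- tibble::as_tibble(as.matrix(m), rownames = "label")
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' Generate a synthetic dataset on disk
#'
#' Runs the simulator for a scenario (an R object or a YAML file of scenario
#' fields) and writes `pedigree.csv`, `records.csv`, `scenario.yaml` and,
#' when markers are requested, `genotypes.csv`, into `dir`.
#'
#' @param scenario A [sim_scenario()] or path to a YAML file of its fields.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list returned by [simulate_herd()] (plus
#'   `genotypes` when simulated).
#' @export
run_simulate <- function(scenario, dir) {
  if (is.character(scenario)) {
    scenario <- do.call(sim_scenario, yaml::read_yaml(scenario))
  }
  stopifnot(inherits(scenario, "sim_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  herd <- simulate_herd(scenario)
  write_pedigree(herd$pedigree, file.path(dir, "pedigree.csv"))
  write_records(herd$records, file.path(dir, "records.csv"))
  yaml::write_yaml(unclass(scenario), file.path(dir, "scenario.yaml"))
  if (scenario$n_markers > 0) {
    gen <- simulate_genotypes(herd$pedigree, scenario)
    write_genotypes(gen$dosages, file.path(dir, "genotypes.csv"))
    herd$genotypes <- gen
  }
  invisible(herd)
}

#' Run a full connectedness evaluation from a configuration
#'
#' Reads the input files named in the configuration, fits the model with
#' [fit_connectedness()], and writes the PEVMean matrix, the CG variance
#' block, the pairwise report and the diagnostics bundle into the output
#' directory.
#'
#' @param config A named list (or path to a YAML file) with fields:
#'   `pedigree`, `records`, optional `genotypes` (file paths); `sigma_g2`,
#'   `sigma_e2`; optional `cg`, `factors`, `covariates`, `centre`,
#'   `standardise`, `trait`, `relationship` ("A"/"H"), `blend_weight`, `pev`,
#'   `dense_limit`; `outdir`.
#' @return Invisibly, the `conn_fit`.
#' @export
run_fit <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (f in c("pedigree", "records")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      stop("config field '", f, "' must name an existing file", call. = FALSE)
    }
  }
  stopifnot(!is.null(config$sigma_g2), !is.null(config$sigma_e2))
  relationship <- config$relationship %||% "A"
  if (relationship == "H" &&
      (is.null(config$genotypes) || !file.exists(config$genotypes))) {
    stop("relationship 'H' requires a 'genotypes' file in the config",
         call. = FALSE)
  }
  ped <- read_pedigree(config$pedigree)
  records <- read_records(config$records, cg = config$cg %||% "cg")
  genotypes <- if (!is.null(config$genotypes))
    read_genotypes(config$genotypes) else NULL
  fit <- fit_connectedness(
    records, ped,
    sigma_g2 = config$sigma_g2, sigma_e2 = config$sigma_e2,
    cg = config$cg %||% "cg",
    factors = config$factors %||% character(),
    covariates = config$covariates %||% character(),
    centre = config$centre %||% FALSE,
    standardise = config$standardise %||% FALSE,
    trait = config$trait %||% "y",
    genotypes = genotypes,
    relationship = relationship,
    blend_weight = config$blend_weight %||% 0.95,
    pev = config$pev %||% "auto",
    dense_limit = config$dense_limit %||% 5000
  )
  outdir <- config$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_csv(unclass_pevmean(fit$pevmean),
                   file.path(outdir, "pevmean.csv"))
  write_matrix_csv(fit$var_beta$vb1, file.path(outdir, "var_beta_cg.csv"))
  if (!is.null(fit$report)) {
    readr::write_csv(fit$report, file.path(outdir, "report.csv"))
  }
  readr::write_csv(glance(fit), file.path(outdir, "diagnostics.csv"))
  invisible(fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
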