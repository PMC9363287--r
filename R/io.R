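#' Cohort tables
#'
#' A `cohort_table` is a data.frame with one row per subject and
#' measurement occasion and the canonical columns
#' `subject_id, arm, occasion_months, age_years, selenium_ugL`, the 13
#' biomarker concentrations (see [panel_markers()]) and `cv_death_5y`.
#' Generator provenance (mode, seed, config hash) and the true latent
#' values travel as attributes.
#'
#' @param tab data.frame with the canonical columns.
#' @param config the [generator_config] that produced it (optional).
#' @param seed the seed used (optional).
#' @param latents optional data.frame of true latent values.
#' @return `cohort_table`.
#' @export
as_cohort_table <- function(tab, config = NULL, seed = NA_integer_,
                            latents = NULL) {
  missing <- setdiff(cohort_columns(), names(tab))
  if (length(missing))
    stop(sprintf("cohort table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  tab <- tab[, cohort_columns()]
  if (any(!is.na(tab$cv_death_5y) & !tab$cv_death_5y %in% c(0L, 1L)))
    stop("cv_death_5y must be 0/1", call. = FALSE)
  conc <- as.matrix(tab[, panel_markers()])
  if (any(!is.na(conc) & conc <= 0))
    stop("biomarker concentrations must be strictly positive", call. = FALSE)
  structure(tab,
            class = c("cohort_table", "data.frame"),
            mode = if (!is.null(config)) config$mode else NA_character_,
            seed = seed,
            config_hash = if (!is.null(config)) config_hash(config) else NA_character_,
            latents = latents)
}

cohort_columns <- function() {
  c("subject_id", "arm", "occasion_months", "age_years", "selenium_ugL",
    panel_markers(), "cv_death_5y")
}

#' Read / write cohort CSV files
#'
#' RFC-4180 CSV with the canonical header, decimal point, empty fields for
#' missing values. `read_cohort` validates the header (misspelled or
#' missing columns are named in the error), coerces types and reports
#' non-numeric cells with their row and column.
#'
#' @param path file path.
#' @param cohort a `cohort_table`.
#' @return `read_cohort`: a `cohort_table`. `write_cohort`: `path`,
#'   invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  unknown <- setdiff(names(tab), cohort_columns())
  missing <- setdiff(cohort_columns(), names(tab))
  if (length(unknown) || length(missing))
    stop(sprintf("non-canonical cohort header:%s%s",
                 if (length(missing)) paste0(" missing [",
                   paste(missing, collapse = ", "), "]") else "",
                 if (length(unknown)) paste0(" unknown [",
                   paste(unknown, collapse = ", "), "]") else ""),
         call. = FALSE)
  num_cols <- setdiff(cohort_columns(), c("subject_id", "arm"))
  for (cn in num_cols) {
    raw <- tab[[cn]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(raw) & is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                   raw[bad[1]], cn, bad[1]), call. = FALSE)
    v[!nzchar(raw)] <- NA_real_
    tab[[cn]] <- v
  }
  tab$occasion_months <- as.integer(tab$occasion_months)
  tab$cv_death_5y <- as.integer(tab$cv_death_5y)
  message(sprintf("read_cohort: %d rows, %d with missing values",
                  nrow(tab), sum(!stats::complete.cases(
                    tab[, setdiff(num_cols, "cv_death_5y")]))))
  as_cohort_table(tab)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort)[, cohort_columns()], path,
                   row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read / write labeled covariance matrices
#'
#' Full symmetric matrix as delimited text: header row with variable
#' names, row labels in the first column.
#'
#' @param S a [cov_matrix]; `path` a file path; `sep` field separator.
#' @return `read_cov_matrix`: a `cov_matrix`.
#' @export
write_cov_matrix <- function(S, path, sep = "\t") {
  utils::write.table(format(S$values, digits = 15, trim = TRUE),
                     path, sep = sep, quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_cov_matrix
#' @param n observation count to attach (read side).
#' @export
read_cov_matrix <- function(path, n = NA_integer_, sep = "\t") {
  m <- as.matrix(utils::read.table(path, sep = sep, header = TRUE,
                                   row.names = 1, check.names = FALSE))
  cov_matrix(m, labels = rownames(m), n = n)
}

#' Load / save generator configurations
#'
#' Flat JSON mirroring [generator_config()]; unknown keys are rejected
#' and all range checks re-applied. An empty file (or empty object) yields
#' the full documented defaults.
#'
#' @param path JSON file.
#' @return a `generator_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  vals <- if (!nzchar(trimws(txt))) list()
          else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  if (length(vals) && is.null(names(vals)))
    stop("config must be a key-value object", call. = FALSE)
  do.call(generator_config, as.list(vals))
}

#' @rdname load_config
#' @param config a `generator_config`.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# stable dependency-free checksum of the serialized config
config_hash <- function(config) {
  bytes <- as.double(utf8ToInt(jsonlite::toJSON(unclass(config),
                                                auto_unbox = TRUE,
                                                digits = NA)))
  w <- rep_len(c(1, 31, 961, 29791, 923521), length(bytes))
  sprintf("%08x", as.integer((sum(bytes * w) + length(bytes)) %% 2^30))
}

#' Serialize a fitted model as a structured report
#'
#' JSON with an estimates table (parameter, estimate, SE, z, p,
#' standardized), a fit block (chi-square, df, p, RMSEA, CFI, F_min, n,
#' convergence), and the construct reliabilities.
#'
#' @param fit a `sem_fit`.
#' @param path output file; if `NULL` the report list is returned.
#' @return the report list, invisibly when written.
#' @export
write_fit_report <- function(fit, path = NULL) {
  rep <- list(
    fit = list(chi_square = fit$T, df = fit$df, p_value = fit$p_value,
               rmsea = fit$rmsea, cfi = fit$cfi, F_min = fit$F_min,
               n = fit$n, converged = fit$converged,
               heywood = as.list(fit$heywood)),
    estimates = fit$param_table,
    construct_reliabilities = as.list(fit$construct_reliabilities))
  if (is.null(path)) return(rep)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(rep)
}

#' Run manifests
#'
#' A small provenance record written alongside every CLI output: package
#' version, config hash, seed, input digests and the stages executed.
#' Re-running with an identical manifest reproduces identical outputs.
#'
#' @param seed integer seed; `config` a `generator_config` or NULL;
#'   `inputs` named character vector of input paths; `stages` character
#'   vector.
#' @param path where to write (JSON); NULL to return only.
#' @return the manifest list.
#' @export
run_manifest <- function(seed, config = NULL, inputs = character(0),
                         stages = character(0), path = NULL) {
  digest_file <- function(p) {
    if (!file.exists(p)) return(NA_character_)
    bytes <- as.double(readBin(p, "raw", file.info(p)$size))
    # vectorized weighted checksum; provenance marker, not cryptographic
    w <- rep_len(c(1, 31, 961, 29791, 923521), length(bytes))
    sprintf("%08x", as.integer((sum(bytes * w) + length(bytes)) %% 2^30))
  }
  man <- list(tool = "cohortsem",
              version = as.character(utils::packageVersion("cohortsem")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed,
              config_hash = if (!is.null(config)) config_hash(config)
                            else NA_character_,
              inputs = as.list(vapply(inputs, digest_file, character(1))),
              stages = as.list(stages))
  if (!is.null(path))
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                         na = "null")
  man
}
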