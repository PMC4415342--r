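#' Validate a county measure table against a catalog
#'
#' Collects every structural defect — missing required columns, duplicate
#' FIPS codes, missing or non-positive populations, and (with
#' `strict = FALSE`) unknown columns — into a report rather than failing
#' on the first. FIPS codes are county identifiers and are kept as text
#' so leading zeros survive.
#'
#' @param table a candidate county measure table.
#' @param catalog a [chr_catalog].
#' @param strict if `TRUE`, raise an error listing all defects instead of
#'   returning the report.
#' @return A tibble `check`, `detail` (zero rows if valid), invisibly when
#'   `strict = TRUE`.
#' @export
validate_measure_table <- function(table, catalog = default_catalog(),
                                   strict = FALSE) {
  issues <- list()
  add <- function(check, detail) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(check = check,
                                                     detail = detail)
  }
  required <- c("fips", "state", "population")
  miss <- setdiff(required, names(table))
  if (length(miss) > 0) {
    add("missing_columns",
        paste("missing required column(s):", paste(miss, collapse = ", ")))
  } else {
    dup <- unique(table$fips[duplicated(table$fips)])
    if (length(dup) > 0)
      add("duplicate_fips",
          paste("duplicated fips:", paste(dup, collapse = ", ")))
    bad_pop <- table$fips[is.na(table$population) | table$population <= 0]
    if (length(bad_pop) > 0)
      add("bad_population",
          paste("non-positive or missing population for:",
                paste(bad_pop, collapse = ", ")))
    if (any(is.na(table$state) | !nzchar(table$state)))
      add("missing_state", "every county must carry a state code")
  }
  known <- c(required, catalog$measure_id, paste0(catalog$measure_id, "_se"))
  unknown <- setdiff(names(table), known)
  if (length(unknown) > 0 && !strict)
    add("unknown_columns",
        paste("columns not in catalog:", paste(unknown, collapse = ", ")))
  report <- if (length(issues) == 0) {
    tibble::tibble(check = character(), detail = character())
  } else {
    dplyr::bind_rows(issues)
  }
  if (strict && nrow(report) > 0)
    stop("invalid county measure table:\n  ",
         paste(report$detail, collapse = "\n  "), call. = FALSE)
  if (strict) invisible(report) else report
}

#' Read / write a county measure table
#'
#' County tables are CSV with a header row and columns
#' `fips,state,population,<measure_id>[,<measure_id>_se]...`; empty fields
#' are missing values and FIPS codes are read as zero-padded text. Reading
#' validates against the catalog (all defects reported at once) and warns
#' about columns the catalog does not know. Writing uses full precision so
#' a round trip reproduces values exactly.
#'
#' @param path CSV file path.
#' @param catalog a [chr_catalog].
#' @param table a county measure table.
#' @return `read_measure_table()` returns a validated tibble;
#'   `write_measure_table()` returns `path` invisibly.
#' @export
read_measure_table <- function(path, catalog = default_catalog()) {
  tab <- readr::read_csv(
    path,
    col_types = readr::cols(
      fips = readr::col_character(),
      state = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE)
  report <- validate_measure_table(tab, catalog, strict = FALSE)
  unknown <- report$detail[report$check == "unknown_columns"]
  if (length(unknown) > 0) warning(unknown, call. = FALSE)
  hard <- report[report$check != "unknown_columns", ]
  if (nrow(hard) > 0)
    stop("invalid county measure table '", path, "':\n  ",
         paste(hard$detail, collapse = "\n  "), call. = FALSE)
  tab
}

#' @rdname read_measure_table
#' @export
write_measure_table <- function(table, path) {
  readr::write_csv(table, path, na = "")
  invisible(path)
}

#' Assemble a run configuration
#'
#' Bundles the pipeline's tunable constants with their conventional
#' defaults: sample-SD standardization, the 20,000-resident truncation
#' threshold, the 20% relative-standard-error reliability cutoff,
#' competition ranking, the best-10% benchmark, and five-county extreme
#' groups drawn from states with at least ten counties.
#'
#' @param sd_method `"sample"` or `"population"` state SD.
#' @param truncation_population small-county cutoff (inclusive).
#' @param rse_threshold unreliability cutoff as a proportion.
#' @param benchmark_percentile best-tail size in percent, in (0, 50].
#' @param extremes_k extreme group size per state.
#' @param extremes_min_counties minimum counties for a state to enter the
#'   extremes comparison.
#' @return A list of class `chr_run_config`.
#' @export
ranking_config <- function(sd_method = "sample",
                           truncation_population = 20000,
                           rse_threshold = 0.20,
                           benchmark_percentile = 10,
                           extremes_k = 5,
                           extremes_min_counties = 10) {
  stopifnot(truncation_population > 0, rse_threshold > 0,
            benchmark_percentile > 0, benchmark_percentile <= 50,
            extremes_k >= 1, extremes_min_counties >= 1)
  structure(list(
    sd_method = match.arg(sd_method, c("sample", "population")),
    truncation_population = truncation_population,
    rse_threshold = rse_threshold,
    benchmark_percentile = benchmark_percentile,
    extremes_k = extremes_k,
    extremes_min_counties = extremes_min_counties
  ), class = "chr_run_config")
}

#' Run the full ranking pipeline
#'
#' Standardize, aggregate, flag, rank, group, benchmark, compare: the
#' whole chain from a raw county measure table to within-state ranks. If
#' `output_dir` is given, writes `rankings.csv` (per county: scores,
#' ranks, quartiles, unranked flag/reason), `benchmarks.csv` and
#' `extremes.csv`, and logs counts of imputed, truncated, unreliable and
#' unranked cells/counties via `message()`.
#'
#' @param table a county measure table (tibble or CSV path).
#' @param catalog a [chr_catalog] (or path to a catalog file).
#' @param config a [ranking_config()].
#' @param output_dir optional directory for output CSVs.
#' @param quiet suppress the summary messages.
#' @return A list: `std`, `composites`, `unranked`, `rankings` (with
#'   quartiles), `benchmarks`, `extremes`.
#' @examples
#' sim <- simulate_counties(simulation_config(n_states = 3,
#'                                            counties_per_state = 12,
#'                                            seed = 9))
#' res <- run_rankings(sim$table, quiet = TRUE)
#' head(res$rankings[c("fips", "rank_outcomes", "quartile_outcomes")])
#' @export
run_rankings <- function(table, catalog = default_catalog(),
                         config = ranking_config(), output_dir = NULL,
                         quiet = FALSE) {
  if (is.character(catalog) && length(catalog) == 1)
    catalog <- read_catalog(catalog)
  if (is.character(table) && length(table) == 1)
    table <- read_measure_table(table, catalog)
  stopifnot(inherits(config, "chr_run_config"))

  std <- compute_zscores(
    table, catalog, sd_method = config$sd_method,
    rse_threshold = config$rse_threshold,
    truncation_population = config$truncation_population)
  composites <- compute_composites(std, catalog)
  unranked <- determine_unranked(std, catalog)
  rankings <- rank_within_state(composites, unranked) |>
    assign_quartiles()
  benchmarks <- national_benchmark(
    table, catalog, percentile = config$benchmark_percentile)
  extremes <- compare_extremes(
    rankings, table, catalog, k = config$extremes_k,
    min_counties_per_state = config$extremes_min_counties)

  if (!quiet) {
    n <- nrow(table)
    n_unranked <- sum(rankings$unranked)
    message(sprintf(
      "counties: %d ranked, %d unranked (%.1f%%)",
      n - n_unranked, n_unranked, 100 * n_unranked / n))
    message(sprintf(
      "cells: %d imputed, %d truncated, %d unreliable",
      sum(std$imputed), sum(std$truncated), sum(std$unreliable)))
  }

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    fmt <- function(df) {
      num <- vapply(df, is.double, logical(1))
      df[num] <- lapply(df[num], function(x) round(x, 6))
      df
    }
    readr::write_csv(fmt(rankings), file.path(output_dir, "rankings.csv"),
                     na = "")
    readr::write_csv(fmt(benchmarks), file.path(output_dir, "benchmarks.csv"),
                     na = "")
    readr::write_csv(fmt(extremes), file.path(output_dir, "extremes.csv"),
                     na = "")
  }

  list(std = std, composites = composites, unranked = unranked,
       rankings = rankings, benchmarks = benchmarks, extremes = extremes)
}
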