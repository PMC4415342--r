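#' Flag unreliable estimates by relative standard error
#'
#' An estimate is deemed unreliable when its relative standard error (RSE =
#' standard error / |estimate|) exceeds the threshold, the conventional 20%
#' cutoff beyond which small-area estimates should be interpreted with
#' caution. A zero estimate with a positive standard error is unreliable by
#' convention (the RSE diverges as the estimate approaches zero).
#'
#' @param value numeric vector of estimates.
#' @param se numeric vector of standard errors, non-negative.
#' @param threshold RSE cutoff as a proportion (default 0.20).
#' @return Logical vector: `TRUE` where `se / |value| > threshold`; `NA`
#'   where `value` or `se` is missing.
#' @examples
#' flag_unreliable(100, 25)  # TRUE: RSE 25%
#' flag_unreliable(100, 10)  # FALSE
#' @export
flag_unreliable <- function(value, se, threshold = 0.20) {
  if (any(se < 0, na.rm = TRUE))
    stop("standard errors must be non-negative", call. = FALSE)
  out <- ifelse(value == 0, se > 0, se / abs(value) > threshold)
  out[is.na(value) | is.na(se)] <- NA
  out
}

#' Flip the sign of reverse-coded Z-scores
#'
#' Composite scores are oriented so that higher always means poorer health.
#' Measures where a higher raw value indicates better health (reverse-coded
#' measures such as high school graduation) have their Z-scores multiplied
#' by -1 before weighting.
#'
#' @param z numeric vector of Z-scores.
#' @param direction `"higher_is_worse"` (identity) or `"higher_is_better"`
#'   (negate); recycled against `z`.
#' @return Numeric vector of direction-aligned Z-scores.
#' @export
apply_direction <- function(z, direction) {
  bad <- !direction %in% c("higher_is_worse", "higher_is_better")
  if (any(bad)) stop("unknown direction: ",
                     paste(unique(direction[bad]), collapse = ", "),
                     call. = FALSE)
  ifelse(direction == "higher_is_better", -z, z)
}

#' Truncate outlier Z-scores for small counties
#'
#' Counties at or below the population threshold (default 20,000 residents)
#' have Z-scores outside \[-3, 3\] clamped to +/-3, damping small-area
#' outliers whose extreme values mostly reflect sampling variation. Larger
#' counties are never truncated.
#'
#' @param z numeric vector of Z-scores.
#' @param population county populations, recycled against `z`.
#' @param threshold population cutoff, inclusive (default 20000).
#' @return Numeric vector with small-county values clamped to \[-3, 3\].
#' @examples
#' truncate_small_county(3.7, 15000)  # 3.0
#' truncate_small_county(3.7, 25000)  # 3.7 (untouched)
#' @export
truncate_small_county <- function(z, population, threshold = 20000) {
  ifelse(!is.na(z) & population <= threshold, pmin(pmax(z, -3), 3), z)
}

#' Standardize county measures to within-state Z-scores
#'
#' The scoring engine's core transform. Measures live on incommensurable
#' scales (rates, percentages, survey means), so each is standardized to the
#' counties of its own state:
#' \deqn{Z = (county value - state mean of counties) / (state SD of counties)}
#' yielding scores in standard-deviation units with mean 0 and SD 1 among
#' the observed counties of each state. The full cell-level treatment, in
#' order:
#'
#' 1. **Reliability**: cells with a standard error whose RSE exceeds
#'    `rse_threshold` are flagged unreliable and treated as missing for
#'    scoring (the flag is retained for the unrankable rules).
#' 2. **Standardization**: state mean and SD are computed from observed
#'    (non-missing, reliable) counties only; a zero-variance state-measure
#'    yields Z = 0 for all its observed counties.
#' 3. **Mean imputation**: missing or unreliable cells receive Z = 0 —
#'    equivalent to assigning the county the state mean — with the
#'    `imputed` flag set, so they contribute nothing to composites.
#' 4. **Whole-state missingness**: a state-measure with fewer than two
#'    observed counties (e.g. a measure not collected in a state at all)
#'    is dropped for that state (`state_dropped`, Z = NA); downstream the
#'    remaining weights of the same composite family are renormalized.
#' 5. **Direction alignment**: reverse-coded measures are negated
#'    ([apply_direction()]).
#' 6. **Small-county truncation**: Z outside +/-3 is clamped for counties
#'    with `population <= truncation_population`
#'    ([truncate_small_county()]); the band is symmetric, so flipping and
#'    truncation commute.
#'
#' @param table a county measure table as returned by
#'   [read_measure_table()] or [simulate_counties()]: columns `fips`,
#'   `state`, `population`, one column per catalog measure and optional
#'   `<measure_id>_se` columns.
#' @param catalog a [chr_catalog]; defaults to [default_catalog()].
#' @param sd_method `"sample"` (n-1 denominator, the default: a state's
#'   counties are treated as draws from a wider process) or `"population"`
#'   (n denominator), for compatibility with other implementations.
#' @param rse_threshold relative-standard-error cutoff (default 0.20).
#' @param truncation_population small-county population cutoff, inclusive
#'   (default 20000).
#' @return A tibble of class `chr_std`, one row per county x measure:
#'   `fips`, `state`, `population`, `measure_id`, `value`, `se`, `z`
#'   (direction-aligned, truncated), and logical flags `imputed`,
#'   `truncated`, `unreliable`, `state_dropped`.
#' @examples
#' cat34 <- default_catalog()
#' sim <- simulate_counties(simulation_config(n_states = 3,
#'                                            counties_per_state = 10,
#'                                            seed = 1), cat34)
#' std <- compute_zscores(sim$table, cat34)
#' dplyr::count(std, imputed, truncated, unreliable)
#' @export
compute_zscores <- function(table, catalog = default_catalog(),
                            sd_method = c("sample", "population"),
                            rse_threshold = 0.20,
                            truncation_population = 20000) {
  sd_method <- match.arg(sd_method)
  stop_if_invalid_catalog(catalog)
  validate_measure_table(table, catalog, strict = TRUE)

  ids <- catalog$measure_id
  nonnum <- !vapply(table[intersect(ids, names(table))],
                    is.numeric, logical(1))
  if (any(nonnum))
    stop("non-numeric measure column(s): ",
         paste(names(nonnum)[nonnum], collapse = ", "), call. = FALSE)

  # matrix kernel: counties x measures, states resolved by row indexing
  n <- nrow(table)
  m <- length(ids)
  V <- matrix(NA_real_, n, m, dimnames = list(NULL, ids))
  for (id in intersect(ids, names(table))) V[, id] <- table[[id]]
  SE <- matrix(NA_real_, n, m, dimnames = list(NULL, ids))
  for (id in ids) {
    sc <- paste0(id, "_se")
    if (sc %in% names(table)) SE[, id] <- table[[sc]]
  }
  if (any(SE < 0, na.rm = TRUE))
    stop("standard errors must be non-negative", call. = FALSE)

  unrel <- !is.na(V) & !is.na(SE) &
    ifelse(V == 0, SE > 0, SE / abs(V) > rse_threshold)
  obs <- !is.na(V) & !unrel

  g <- match(table$state, unique(table$state))   # state index per county
  n_obs <- rowsum(obs + 0, g)                    # states x measures
  Vo <- V
  Vo[!obs] <- 0
  state_mean <- rowsum(Vo, g) / n_obs
  Mx <- state_mean[g, , drop = FALSE]
  D <- V - Mx
  D[!obs] <- 0
  denom <- if (sd_method == "sample") pmax(n_obs - 1, 1) else pmax(n_obs, 1)
  state_sd <- sqrt(rowsum(D * D, g) / denom)
  Sx <- state_sd[g, , drop = FALSE]

  droppedx <- (n_obs < 2)[g, , drop = FALSE]     # whole-state missing
  z_raw <- (V - Mx) / Sx
  z_raw[obs & Sx == 0] <- 0                      # zero-variance guard
  imputed <- !obs & !droppedx
  z_raw[imputed] <- 0                            # state-mean imputation
  z_raw[droppedx] <- NA_real_

  better <- catalog$direction == "higher_is_better"
  z_dir <- z_raw
  z_dir[, better] <- -z_dir[, better]
  small <- table$population <= truncation_population
  z <- z_dir
  z[small, ] <- pmin(pmax(z[small, , drop = FALSE], -3), 3)
  trunc_flag <- !is.na(z_dir) & z != z_dir

  # long county-major layout: all measures of county 1, then county 2, ...
  out <- tibble::tibble(
    fips = rep(table$fips, each = m),
    state = rep(table$state, each = m),
    population = rep(table$population, each = m),
    measure_id = rep(ids, n),
    value = as.vector(t(V)),
    se = as.vector(t(SE)),
    z = as.vector(t(z)),
    imputed = as.vector(t(imputed)),
    truncated = as.vector(t(trunc_flag)),
    unreliable = as.vector(t(unrel)),
    state_dropped = as.vector(t(droppedx))
  )
  structure(out,
            class = c("chr_std", class(tibble::tibble())),
            sd_method = sd_method,
            rse_threshold = rse_threshold,
            truncation_population = truncation_population)
}

# wide county table -> long (fips, state, population, measure_id, value, se)
pivot_measures_long <- function(table, catalog) {
  ids <- catalog$measure_id
  base <- tibble::as_tibble(table)
  for (id in setdiff(ids, names(base))) base[[id]] <- NA_real_
  vals <- base |>
    dplyr::select("fips", "state", "population",
                  dplyr::all_of(ids)) |>
    tidyr::pivot_longer(dplyr::all_of(ids), names_to = "measure_id",
                        values_to = "value")
  se_cols <- paste0(ids, "_se")
  present <- se_cols[se_cols %in% names(base)]
  if (length(present) > 0) {
    ses <- base |>
      dplyr::select("fips", dplyr::all_of(present)) |>
      tidyr::pivot_longer(dplyr::all_of(present), names_to = "measure_id",
                          values_to = "se") |>
      dplyr::mutate(measure_id = sub("_se$", "", .data$measure_id))
    vals <- dplyr::left_join(vals, ses, by = c("fips", "measure_id"))
  } else {
    vals$se <- NA_real_
  }
  vals
}
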