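composite_cols <- c("outcomes", "mortality", "morbidity", "factors",
                    "health_behaviors", "clinical_care", "social_economic",
                    "physical_environment")

#' Per-state effective measure weights
#'
#' When a measure is entirely unavailable in a state (fewer than two
#' observed counties, e.g. particulate air pollution in Alaska and Hawaii),
#' it is dropped for that state and the remaining weights of the same
#' composite family are scaled proportionally so the family still sums to
#' 100, preserving the composite scale across states.
#'
#' @param std a `chr_std` table from [compute_zscores()].
#' @param catalog the catalog used to produce `std`.
#' @return A tibble `state`, `measure_id`, `weight_pct` (effective percent
#'   of the composite family in that state).
#' @export
effective_weights <- function(std, catalog) {
  wide <- std_wide(std, catalog)
  Weff <- effective_weight_matrix(wide$dropped, catalog)
  keep <- !is.na(as.vector(Weff)) & as.vector(Weff) > 0
  out <- tibble::tibble(
    state = rep(rownames(Weff), ncol(Weff)),
    measure_id = rep(colnames(Weff), each = nrow(Weff)),
    weight_pct = as.vector(Weff)
  )[keep, ]
  out |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(catalog), "measure_id", "component",
                    "composite_family"),
      by = "measure_id") |>
    dplyr::arrange(.data$state) |>
    dplyr::select("state", "measure_id", "component", "composite_family",
                  "weight_pct")
}

# states x measures matrix of family-renormalized weights; dropped cells 0
effective_weight_matrix <- function(dropped, catalog) {
  w <- matrix(rep(catalog$weight_pct, each = nrow(dropped)),
              nrow(dropped), nrow(catalog),
              dimnames = dimnames(dropped))
  w[dropped] <- 0
  for (fam in catalog_families) {
    cols <- which(catalog$composite_family == fam)
    if (length(cols) == 0) next
    tot <- rowSums(w[, cols, drop = FALSE])
    w[, cols] <- w[, cols, drop = FALSE] * ifelse(tot > 0, 100 / tot, 0)
  }
  w
}

# reshape a chr_std long table into county x measure matrices
std_wide <- function(std, catalog) {
  ids <- catalog$measure_id
  fips <- unique(std$fips)
  ridx <- match(std$fips, fips)
  cidx <- match(std$measure_id, ids)
  if (anyNA(cidx))
    stop("standardized table carries measures absent from the catalog: ",
         paste(unique(std$measure_id[is.na(cidx)]), collapse = ", "),
         call. = FALSE)
  shape <- function(x, default = NA) {
    m <- matrix(default, length(fips), length(ids),
                dimnames = list(NULL, ids))
    m[cbind(ridx, cidx)] <- x
    m
  }
  state <- std$state[match(fips, std$fips)]
  states <- unique(state)
  g <- match(state, states)
  # per-state dropped pattern (constant within a state by construction;
  # cells absent from std count as dropped)
  Dm <- shape(std$state_dropped + 0, default = 1)
  dropped <- rowsum(Dm, g) > 0
  dimnames(dropped) <- list(states, ids)
  list(fips = fips, state = state, states = states, g = g,
       Z = shape(std$z), dropped = dropped,
       value = shape(std$value),
       unreliable = shape(std$unreliable, default = FALSE) > 0)
}

#' Aggregate Z-scores into the eight composite scores
#'
#' Each direction-aligned Z-score is multiplied by its measure weight
#' (percent of composite family / 100) and summed into eight composites per
#' county: the two family scores (`outcomes`, `factors`) and their six
#' component scores (`mortality`, `morbidity`, `health_behaviors`,
#' `clinical_care`, `social_economic`, `physical_environment`). Component
#' scores partition the family score exactly: `outcomes = mortality +
#' morbidity` and `factors` is the sum of its four components. Imputed
#' cells carry Z = 0 and so contribute nothing; state-dropped measures are
#' excluded with their family weights renormalized ([effective_weights()]).
#' Higher scores mean poorer health.
#'
#' @inheritParams effective_weights
#' @return A tibble of class `chr_composites`: `fips`, `state`, and the
#'   eight composite columns, ordered by state then fips.
#' @examples
#' cat34 <- default_catalog()
#' sim <- simulate_counties(simulation_config(n_states = 2,
#'                                            counties_per_state = 8,
#'                                            seed = 7), cat34)
#' scores <- compute_composites(compute_zscores(sim$table, cat34), cat34)
#' head(scores[c("fips", "outcomes", "factors")])
#' @export
compute_composites <- function(std, catalog = default_catalog()) {
  stop_if_invalid_catalog(catalog)
  wide <- std_wide(std, catalog)
  Weff <- effective_weight_matrix(wide$dropped, catalog)
  Wx <- Weff[wide$g, , drop = FALSE] / 100     # per-county weights
  Zc <- wide$Z
  Zc[is.na(Zc)] <- 0                           # dropped cells carry weight 0
  contrib <- Zc * Wx

  out <- tibble::tibble(fips = wide$fips, state = wide$state)
  for (cc in unname(catalog_components)) {
    cols <- which(catalog$component == cc)
    out[[cc]] <- if (length(cols) > 0)
      rowSums(contrib[, cols, drop = FALSE]) else 0
  }
  out$outcomes <- out$mortality + out$morbidity
  out$factors <- out$health_behaviors + out$clinical_care +
    out$social_economic + out$physical_environment
  out <- out |>
    dplyr::select("fips", "state", dplyr::all_of(composite_cols)) |>
    dplyr::arrange(.data$state, .data$fips)
  structure(out, class = c("chr_composites", class(tibble::tibble())))
}

#' Flag counties that cannot be ranked
#'
#' A county is excluded from ranking when its mortality anchor is too weak
#' to score: (1) its premature-death value is missing; (2) its
#' premature-death value is unreliable and no other morbidity measure is
#' available; or (3) its premature-death and low-birthweight values are
#' both unreliable and no other morbidity measure is available. A measure
#' is "available" when a value is present; the morbidity measures are the
#' catalog's `morbidity` component (rule 3 covers the case where low
#' birthweight is present but itself unreliable). The first matching rule
#' is recorded as the reason.
#'
#' @inheritParams effective_weights
#' @param premature_death,low_birthweight measure ids of the mortality
#'   anchor and the birthweight morbidity measure in `catalog`.
#' @return A tibble `fips`, `state`, `unranked` (logical),
#'   `unranked_reason` (`"missing_premature_death"`,
#'   `"unreliable_pd_no_morbidity"`, `"unreliable_pd_lbw_no_morbidity"` or
#'   `"none"`).
#' @export
determine_unranked <- function(std, catalog = default_catalog(),
                               premature_death = "premature_death",
                               low_birthweight = "low_birthweight") {
  morbidity_ids <- catalog$measure_id[catalog$component == "morbidity"]
  wide <- std_wide(std, catalog)
  col <- function(M, id, default) {
    if (id %in% colnames(M)) M[, id] else rep(default, nrow(M))
  }
  pd_missing <- is.na(col(wide$value, premature_death, NA_real_))
  pd_unreliable <- col(wide$unreliable, premature_death, FALSE)
  lbw_unreliable <- col(wide$unreliable, low_birthweight, FALSE)
  morb_present <- !is.na(wide$value[, intersect(morbidity_ids,
                                                colnames(wide$value)),
                                    drop = FALSE])
  n_morbidity <- rowSums(morb_present)
  n_morbidity_non_lbw <- rowSums(
    morb_present[, setdiff(colnames(morb_present), low_birthweight),
                 drop = FALSE])
  reason <- dplyr::case_when(
    pd_missing ~ "missing_premature_death",
    pd_unreliable & n_morbidity == 0 ~ "unreliable_pd_no_morbidity",
    pd_unreliable & lbw_unreliable &
      n_morbidity_non_lbw == 0 ~ "unreliable_pd_lbw_no_morbidity",
    TRUE ~ "none"
  )
  tibble::tibble(fips = wide$fips, state = wide$state,
                 unranked = reason != "none", unranked_reason = reason) |>
    dplyr::arrange(.data$state, .data$fips)
}

#' Rank counties within their state on each composite
#'
#' For each of the eight composites independently, the ranked counties of a
#' state are sorted from lowest (best health) to highest score; the lowest
#' score gets rank 1. Ties share the minimal position and the next rank is
#' skipped (competition ranking), so the published ranks are always
#' integers. Unranked counties get `NA` ranks.
#'
#' @param scores a `chr_composites` tibble from [compute_composites()].
#' @param unranked optional tibble from [determine_unranked()]; omit to
#'   rank every county.
#' @return A tibble of class `chr_ranking`: `fips`, `state`, the eight
#'   composite scores, `rank_<composite>` for each of the eight,
#'   `unranked`, `unranked_reason`; rows ordered by state then fips.
#' @export
rank_within_state <- function(scores, unranked = NULL) {
  if (is.null(unranked)) {
    unranked <- tibble::tibble(fips = scores$fips, state = scores$state,
                               unranked = FALSE, unranked_reason = "none")
  }
  out <- scores |>
    dplyr::left_join(dplyr::select(unranked, "fips", "unranked",
                                   "unranked_reason"),
                     by = "fips") |>
    dplyr::arrange(.data$state, .data$fips)
  g <- factor(out$state, levels = unique(out$state))
  for (comp in composite_cols) {
    s <- ifelse(out$unranked, NA_real_, out[[comp]])
    r <- stats::ave(s, g, FUN = function(x)
      rank(x, ties.method = "min", na.last = "keep"))
    out[[paste0("rank_", comp)]] <- as.integer(r)
  }
  structure(out, class = c("chr_ranking", class(tibble::tibble())))
}

#' Group ranked counties into quartiles
#'
#' Individual ranks overstate the precision of an ordinal scale, so
#' counties are also grouped into quartiles of their health-outcomes and
#' health-factors ranks: quartile = ceiling(4 * rank / n_ranked), clamped
#' to 1-4, where n_ranked counts the ranked counties of the state. Tied
#' counties inherit their shared rank's quartile. Quartile 1 is the
#' healthiest group.
#'
#' @param result a `chr_ranking` tibble from [rank_within_state()].
#' @return `result` with `quartile_outcomes` and `quartile_factors`
#'   columns added (`NA` for unranked counties).
#' @export
assign_quartiles <- function(result) {
  result |>
    dplyr::group_by(.data$state) |>
    dplyr::mutate(
      n_ranked = sum(!.data$unranked),
      quartile_outcomes = quartile_of_rank(.data$rank_outcomes,
                                           .data$n_ranked),
      quartile_factors = quartile_of_rank(.data$rank_factors,
                                          .data$n_ranked)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"n_ranked")
}

quartile_of_rank <- function(rank, n_ranked) {
  q <- ceiling(4 * rank / n_ranked)
  as.integer(pmin(pmax(q, 1L), 4L))
}

#' National best-10% benchmarks
#'
#' Within-state ranks say nothing about how a county compares nationally,
#' so each measure also gets a benchmark marking the boundary of the best
#' 10% of counties across all states, in the measure's raw units: the 10th
#' percentile of observed values for measures where higher is worse, the
#' 90th for reverse-coded measures. Percentiles use linear interpolation
#' between order statistics (R quantile type 7). Measures observed in
#' fewer than `min_counties` counties get `NA`.
#'
#' @param table a county measure table.
#' @param catalog a [chr_catalog].
#' @param percentile benchmark tail size in percent (default 10).
#' @param min_counties minimum observed counties required (default 10).
#' @return A tibble `measure_id`, `direction`, `n_observed`, `benchmark`.
#' @examples
#' # a measure observed as 1..100 across counties benchmarks at 10.9
#' @export
national_benchmark <- function(table, catalog = default_catalog(),
                               percentile = 10, min_counties = 10) {
  stopifnot(percentile > 0, percentile <= 50)
  long <- pivot_measures_long(table, catalog)
  long |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(catalog), "measure_id", "direction"),
      by = "measure_id") |>
    dplyr::group_by(.data$measure_id, .data$direction) |>
    dplyr::summarise(
      n_observed = sum(!is.na(.data$value)),
      benchmark = {
        v <- .data$value[!is.na(.data$value)]
        p <- if (.data$direction[1] == "higher_is_worse")
          percentile / 100 else 1 - percentile / 100
        if (length(v) >= min_counties)
          unname(stats::quantile(v, p, type = 7)) else NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::left_join(tibble::tibble(measure_id = catalog$measure_id,
                                    .ord = seq_along(catalog$measure_id)),
                     by = "measure_id") |>
    dplyr::arrange(.data$.ord) |>
    dplyr::select("measure_id", "direction", "n_observed", "benchmark")
}

#' Ratio of least-healthy to healthiest group means
#'
#' The extremes comparison reports, per measure, the ratio of the
#' least-healthy group's mean to the healthiest group's mean, rounded to
#' one decimal — e.g. least-healthy counties averaging 10,862 years of
#' potential life lost against 5,113 for the healthiest gives 2.1.
#'
#' @param lh_mean,h_mean group means in the measure's raw units.
#' @return `round(lh_mean / h_mean, 1)`.
#' @export
extremes_ratio <- function(lh_mean, h_mean) {
  round(lh_mean / h_mean, 1)
}

#' Compare the healthiest and least-healthy counties per state
#'
#' Pools the `k` best-ranked (Healthy) and `k` worst-ranked (Least
#' Healthy) counties by health-outcomes rank from every state with at
#' least `min_counties_per_state` counties, and reports per-measure
#' unweighted means for All ranked counties, the two extreme groups, the
#' remaining Others, and the LH/H ratio rounded to one decimal. Group
#' selection orders by rank with fips as tie-break, and the two groups are
#' kept disjoint (in a state with fewer than 2k ranked counties the
#' healthiest set is filled first). A mean-population row is appended, and
#' group sizes are returned as the first row (`n_counties`).
#'
#' @param result a `chr_ranking` from [rank_within_state()] (quartiles
#'   optional).
#' @param table the raw county measure table the ranking came from.
#' @param catalog a [chr_catalog].
#' @param k extreme group size per state (default 5).
#' @param min_counties_per_state states with fewer counties are excluded
#'   from this comparison only — they are still ranked (default 10).
#' @return A tibble `measure_id`, `all`, `least_healthy`, `healthy`,
#'   `others`, `ratio_lh_h`; first row `n_counties` holds group sizes,
#'   last row `population_mean` the mean populations.
#' @export
compare_extremes <- function(result, table, catalog = default_catalog(),
                             k = 5, min_counties_per_state = 10) {
  counts <- table |>
    dplyr::count(.data$state, name = "n_state")
  eligible <- counts$state[counts$n_state >= min_counties_per_state]
  ranked <- result |>
    dplyr::filter(.data$state %in% eligible, !.data$unranked) |>
    dplyr::select("fips", "state", "rank_outcomes")

  grouped <- ranked |>
    dplyr::group_by(.data$state) |>
    dplyr::arrange(.data$rank_outcomes, .data$fips, .by_group = TRUE) |>
    dplyr::mutate(
      .pos = dplyr::row_number(),
      .n = dplyr::n(),
      group = dplyr::case_when(
        .data$.pos <= k ~ "healthy",
        .data$.pos > .data$.n - k & .data$.pos > k ~ "least_healthy",
        TRUE ~ "others"
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::select("fips", "group")

  long <- pivot_measures_long(table, catalog) |>
    dplyr::inner_join(grouped, by = "fips")

  means_for <- function(df) {
    df |>
      dplyr::group_by(.data$measure_id) |>
      dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                       .groups = "drop")
  }
  pieces <- list(
    all = means_for(long),
    least_healthy = means_for(dplyr::filter(long, .data$group == "least_healthy")),
    healthy = means_for(dplyr::filter(long, .data$group == "healthy")),
    others = means_for(dplyr::filter(long, .data$group == "others"))
  )
  wide <- Reduce(function(a, b) dplyr::left_join(a, b, by = "measure_id"),
                 mapply(function(df, nm) stats::setNames(df, c("measure_id", nm)),
                        pieces, names(pieces), SIMPLIFY = FALSE))
  wide <- wide |>
    dplyr::left_join(tibble::tibble(measure_id = catalog$measure_id,
                                    .ord = seq_along(catalog$measure_id)),
                     by = "measure_id") |>
    dplyr::arrange(.data$.ord) |>
    dplyr::select(-".ord")

  pops <- table |>
    dplyr::inner_join(grouped, by = "fips") |>
    dplyr::select("population", "group")
  pop_row <- tibble::tibble(
    measure_id = "population_mean",
    all = mean(pops$population),
    least_healthy = mean(pops$population[pops$group == "least_healthy"]),
    healthy = mean(pops$population[pops$group == "healthy"]),
    others = mean(pops$population[pops$group == "others"])
  )
  n_row <- tibble::tibble(
    measure_id = "n_counties",
    all = nrow(pops),
    least_healthy = sum(pops$group == "least_healthy"),
    healthy = sum(pops$group == "healthy"),
    others = sum(pops$group == "others")
  )
  out <- dplyr::bind_rows(n_row, wide, pop_row) |>
    dplyr::mutate(ratio_lh_h = ifelse(
      .data$measure_id == "n_counties", NA_real_,
      extremes_ratio(.data$least_healthy, .data$healthy)))
  out
}
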