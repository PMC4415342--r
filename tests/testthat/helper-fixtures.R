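# Fixture builders and independent oracle implementations used across the
# suite. The oracles deliberately use plain per-cell loops / direct sorting
# so they share no code path with the package internals they check.

# minimal valid catalog: one weight-100 outcomes measure plus optional
# factor measures (weights must sum to 100 within the factors family)
mini_catalog <- function(factor_ids = character(),
                         factor_weights = numeric(),
                         factor_directions = rep("higher_is_worse",
                                                 length(factor_ids)),
                         outcome_id = "m_out",
                         outcome_direction = "higher_is_worse") {
  out <- tibble::tibble(
    measure_id = c(outcome_id, factor_ids),
    display_name = c(outcome_id, factor_ids),
    composite_family = c("outcomes", rep("factors", length(factor_ids))),
    component = c("mortality", rep("health_behaviors", length(factor_ids))),
    subcomponent = "x",
    weight_pct = c(100, factor_weights),
    direction = c(outcome_direction, factor_directions),
    has_standard_error = FALSE,
    source_label = "synthetic", years_label = "n/a"
  )
  out
}

# one-state wide table from a vector of values for a single measure
one_state_table <- function(values, population = 50000,
                            measure_id = "m_out", se = NULL,
                            state = "S1") {
  n <- length(values)
  tab <- tibble::tibble(
    fips = sprintf("%05d", seq_len(n)),
    state = state,
    population = rep_len(population, n)
  )
  tab[[measure_id]] <- values
  if (!is.null(se)) tab[[paste0(measure_id, "_se")]] <- se
  tab
}

# a hand-built standardized table covering every catalog measure, with all
# z = 0 except those named in `z`; used to feed compute_composites directly
manual_std <- function(catalog, z = c(), n_counties = 1, state = "S1") {
  grid <- expand.grid(fips = sprintf("%05d", seq_len(n_counties)),
                      measure_id = catalog$measure_id,
                      stringsAsFactors = FALSE)
  std <- tibble::tibble(
    fips = grid$fips, state = state, population = 50000,
    measure_id = grid$measure_id, value = 1, se = NA_real_,
    z = 0, imputed = FALSE, truncated = FALSE, unreliable = FALSE,
    state_dropped = FALSE
  )
  for (id in names(z)) std$z[std$measure_id == id] <- z[[id]]
  std
}

# Oracle: per-cell loop standardization (sample SD, state-mean imputation,
# direction flip, truncation), written naively.
naive_zscores <- function(table, catalog, truncation_population = 20000,
                          rse_threshold = 0.2) {
  out <- list()
  for (i in seq_len(nrow(catalog))) {
    id <- catalog$measure_id[i]
    dir <- catalog$direction[i]
    for (st in unique(table$state)) {
      rows <- which(table$state == st)
      vals <- table[[id]][rows]
      ses <- table[[paste0(id, "_se")]]
      unrel <- rep(FALSE, length(rows))
      if (!is.null(ses)) {
        ses <- ses[rows]
        for (j in seq_along(rows)) {
          if (!is.na(vals[j]) && !is.na(ses[j])) {
            rse_bad <- if (vals[j] == 0) ses[j] > 0 else
              ses[j] / abs(vals[j]) > rse_threshold
            if (rse_bad) unrel[j] <- TRUE
          }
        }
      }
      obs <- !is.na(vals) & !unrel
      if (sum(obs) < 2) {
        z <- rep(NA_real_, length(rows))
      } else {
        m <- mean(vals[obs]); s <- sd(vals[obs])
        z <- numeric(length(rows))
        for (j in seq_along(rows)) {
          if (!obs[j]) {
            z[j] <- 0
          } else if (s == 0) {
            z[j] <- 0
          } else {
            z[j] <- (vals[j] - m) / s
          }
        }
        if (dir == "higher_is_better") z <- -z
        for (j in seq_along(rows)) {
          if (table$population[rows[j]] <= truncation_population &&
              !is.na(z[j])) {
            if (z[j] > 3) z[j] <- 3
            if (z[j] < -3) z[j] <- -3
          }
        }
      }
      out[[paste(id, st)]] <- tibble::tibble(
        fips = table$fips[rows], measure_id = id, z_oracle = z)
    }
  }
  dplyr::bind_rows(out)
}

# Oracle: sort-based competition ranking of a score vector
naive_rank <- function(scores) {
  r <- integer(length(scores))
  for (i in seq_along(scores)) r[i] <- 1L + sum(scores < scores[i])
  r
}

composite_names <- function() {
  c("outcomes", "mortality", "morbidity", "factors", "health_behaviors",
    "clinical_care", "social_economic", "physical_environment")
}

# a composites table where every one of the eight scores equals `scores`
manual_composites <- function(scores, state = "S1") {
  out <- tibble::tibble(fips = sprintf("%05d", seq_along(scores)),
                        state = rep_len(state, length(scores)))
  for (cc in composite_names()) out[[cc]] <- scores
  out
}
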