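#' Configure the synthetic county generator
#'
#' Builds the configuration for [simulate_counties()]. The generator's
#' model is a single latent "true health" factor per county: lower latent
#' health means a healthier county, every measure loads on it with a
#' direction-consistent sign, and independent noise plus missingness and
#' sampling error are layered on top. Defaults emulate a US-like panel:
#' 50 states of realistically varied size (four with fewer than ten
#' counties, as with CT, DE, HI and RI), log-normal county populations
#' with roughly 40% of counties at or below 20,000 residents (so the
#' truncation path is exercised), survey-style standard errors shrinking
#' with the square root of population, and the per-measure missingness
#' profile of the 2014 data ([default_missingness_profile()]).
#'
#' @param n_states number of states.
#' @param counties_per_state `NULL` for the built-in US-like size
#'   distribution ([default_state_sizes()]), a single count, a length-2
#'   range to sample uniformly, or a length-`n_states` vector.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @param latent_effect per-measure loading of latent health on the raw
#'   value, in raw measure units per latent SD; a named vector (defaults
#'   to 15% of each measure's baseline), or a single number recycled.
#' @param noise_sd per-measure independent noise SD in raw units; named
#'   vector or single number (default: half the latent effect — moderate
#'   noise under which within-state orderings remain recoverable).
#' @param missing_rate per-measure missingness probability; named vector,
#'   single number, or `NULL` for [default_missingness_profile()].
#' @param se_scale scale of reported standard errors:
#'   `se = se_scale * measure_sd / sqrt(population)` where `measure_sd`
#'   is the measure's marginal SD. The default (60) makes roughly the
#'   smallest 2% of counties unreliable (RSE > 20%) on survey measures.
#' @param population_log_mean,population_log_sd log-normal population
#'   parameters (defaults give median ~26,000 and ~40% of counties at or
#'   below 20,000).
#' @param whole_state_missing named list `measure_id -> state codes` whose
#'   values are wholly absent in those states; the default drops air
#'   pollution in two small states, mirroring its unavailability in
#'   Alaska and Hawaii.
#' @return A list of class `chr_sim_config`.
#' @export
simulation_config <- function(n_states = 50,
                              counties_per_state = NULL,
                              seed = 1,
                              latent_effect = NULL,
                              noise_sd = NULL,
                              missing_rate = NULL,
                              se_scale = 60,
                              population_log_mean = 10.18,
                              population_log_sd = 1.1,
                              whole_state_missing = list(
                                air_pollution = c("S02", "S03"))) {
  stopifnot(n_states >= 1, se_scale >= 0,
            population_log_sd > 0)
  if (!is.null(missing_rate))
    stopifnot(all(missing_rate >= 0), all(missing_rate <= 1))
  if (!is.null(noise_sd)) stopifnot(all(noise_sd >= 0))
  structure(list(
    n_states = as.integer(n_states),
    counties_per_state = counties_per_state,
    seed = as.integer(seed),
    latent_effect = latent_effect,
    noise_sd = noise_sd,
    missing_rate = missing_rate,
    se_scale = se_scale,
    population_log_mean = population_log_mean,
    population_log_sd = population_log_sd,
    whole_state_missing = whole_state_missing
  ), class = "chr_sim_config")
}

#' Built-in US-like distribution of counties per state
#'
#' A fixed vector of state sizes: four small states (3, 5, 5, 8 counties,
#' the CT/DE/HI/RI analogue) followed by sizes spread along a log-normal
#' quantile grid from 10 up to ~250 counties, totalling about 3,100
#' counties across 50 states — so exactly 46 states reach the 10-county
#' floor used by the extremes comparison.
#'
#' @param n_states number of states (sizes are recycled/truncated to it).
#' @return Integer vector of length `n_states`.
#' @export
default_state_sizes <- function(n_states = 50) {
  small <- c(3L, 5L, 5L, 8L)
  big <- pmax(10L, as.integer(round(
    stats::qlnorm(stats::ppoints(46), meanlog = log(55), sdlog = 0.7))))
  sizes <- c(small, big)
  rep_len(sizes, n_states)
}

# Raw-unit baselines for the default catalog, matching the magnitudes of
# the published 2014 all-county means (see extremes_reference_2014()).
default_baselines <- function(catalog) {
  base <- c(
    premature_death = 7746, poor_or_fair_health = 17,
    poor_physical_health_days = 3.7, poor_mental_health_days = 3.5,
    low_birthweight = 8, adult_smoking = 21, adult_obesity = 31,
    food_environment_index = 2.4, physical_inactivity = 28,
    access_to_exercise = 54, excessive_drinking = 16,
    alcohol_impaired_driving_deaths = 31,
    sexually_transmitted_infections = 271, teen_births = 42.4,
    uninsured = 18, primary_care_physicians = 1980, dentists = 2730,
    mental_health_providers = 1640, preventable_hospital_stays = 71,
    diabetic_screening = 85, mammography_screening = 61,
    high_school_graduation = 83, some_college = 55, unemployment = 8,
    children_in_poverty = 24, inadequate_social_support = 19,
    children_single_parent = 31, violent_crime = 204.5,
    injury_deaths = 73, air_pollution = 11.93,
    drinking_water_violations = 1, severe_housing_problems = 14,
    driving_alone_to_work = 80, long_commute_driving_alone = 29
  )
  out <- base[catalog$measure_id]
  # unknown (user-catalog) measures default to a unit scale
  out[is.na(out)] <- 10
  names(out) <- catalog$measure_id
  out
}

#' Default per-measure missingness profile
#'
#' Reproduces the banded missingness of the 2014 county data: 12 measures
#' fully observed, six with under 1% missing (rate 0.005), nine in the
#' 1-10% band (rate 0.05), and seven above 10% (rate 0.15), with
#' excessive/binge drinking the worst at 28%. Band membership follows the
#' data sources: the survey (BRFSS) measures are the most missing, the
#' vital-statistics and provider-count measures nearly complete, and the
#' modeled or census-derived measures complete. For a catalog that is not
#' the default 34 measures, every measure gets `fallback_rate`.
#'
#' @param catalog a [chr_catalog].
#' @param fallback_rate uniform rate for non-default catalogs (default 0.05).
#' @return Named numeric vector of missingness probabilities, one per
#'   catalog measure.
#' @export
default_missingness_profile <- function(catalog = default_catalog(),
                                        fallback_rate = 0.05) {
  bands <- list(
    none = c("adult_obesity", "physical_inactivity", "uninsured",
             "preventable_hospital_stays", "some_college", "unemployment",
             "children_in_poverty", "children_single_parent",
             "air_pollution", "severe_housing_problems",
             "driving_alone_to_work", "long_commute_driving_alone"),
    under_1pct = c("premature_death", "low_birthweight", "injury_deaths",
                   "primary_care_physicians", "dentists",
                   "mental_health_providers"),
    one_to_10pct = c("teen_births", "sexually_transmitted_infections",
                     "violent_crime", "drinking_water_violations",
                     "food_environment_index", "access_to_exercise",
                     "high_school_graduation", "mammography_screening",
                     "diabetic_screening"),
    over_10pct = c("poor_or_fair_health", "poor_physical_health_days",
                   "poor_mental_health_days", "adult_smoking",
                   "alcohol_impaired_driving_deaths",
                   "inadequate_social_support")
  )
  rate_of <- c(none = 0, under_1pct = 0.005, one_to_10pct = 0.05,
               over_10pct = 0.15)
  ids <- catalog$measure_id
  if (!setequal(ids, c(unlist(bands, use.names = FALSE),
                       "excessive_drinking"))) {
    out <- rep(fallback_rate, length(ids))
    names(out) <- ids
    return(out)
  }
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (b in names(bands)) out[bands[[b]]] <- rate_of[[b]]
  out["excessive_drinking"] <- 0.28
  out
}

#' Generate a synthetic multi-state county measure table
#'
#' Draws a panel of counties with known latent structure so the whole
#' ranking pipeline can be validated end to end: log-normal populations;
#' per-county latent health \eqn{h \sim N(0,1)} (lower = healthier); raw
#' measure values `baseline + sign * latent_effect * h + noise`, where the
#' sign makes unhealthy counties score high on higher-is-worse measures
#' and low on reverse-coded ones; standard errors for the survey measures
#' shrinking with `sqrt(population)`; cells masked missing completely at
#' random per measure; and optionally whole states missing a measure.
#'
#' @param config a [simulation_config()].
#' @param catalog a [chr_catalog]; defaults to [default_catalog()].
#' @return A list with `table` (county measure table: `fips`, `state`,
#'   `population`, measure and `_se` columns) and `truth` (tibble `fips`,
#'   `state`, `latent_health`).
#' @examples
#' sim <- simulate_counties(simulation_config(n_states = 2,
#'                                            counties_per_state = 5,
#'                                            seed = 42))
#' sim$table[1:3, 1:5]
#' @export
simulate_counties <- function(config = simulation_config(),
                              catalog = default_catalog()) {
  stopifnot(inherits(config, "chr_sim_config"))
  stop_if_invalid_catalog(catalog)
  set.seed(config$seed)

  cps <- config$counties_per_state
  n_states <- config$n_states
  sizes <- if (is.null(cps)) {
    default_state_sizes(n_states)
  } else if (length(cps) == 1) {
    rep(as.integer(cps), n_states)
  } else if (length(cps) == 2 && n_states != 2) {
    sample(seq(cps[1], cps[2]), n_states, replace = TRUE)
  } else if (length(cps) == n_states) {
    as.integer(cps)
  } else {
    stop("counties_per_state must be NULL, a count, a range, or one per state",
         call. = FALSE)
  }
  stopifnot(all(sizes >= 1))

  states <- sprintf("S%02d", seq_len(n_states))
  state_col <- rep(states, sizes)
  n <- sum(sizes)
  fips <- sprintf("%02d%03d", rep(seq_len(n_states), sizes),
                  unlist(lapply(sizes, seq_len)))
  population <- pmax(100, round(stats::rlnorm(
    n, config$population_log_mean, config$population_log_sd)))
  latent <- stats::rnorm(n)

  baselines <- default_baselines(catalog)
  effect <- resolve_per_measure(config$latent_effect, catalog,
                                default = 0.15 * baselines)
  noise <- resolve_per_measure(config$noise_sd, catalog,
                               default = 0.5 * effect)
  miss <- if (is.null(config$missing_rate)) {
    default_missingness_profile(catalog)
  } else {
    resolve_per_measure(config$missing_rate, catalog, default = NULL)
  }

  tab <- tibble::tibble(fips = fips, state = state_col,
                        population = as.numeric(population))
  truth <- tibble::tibble(fips = fips, state = state_col,
                          latent_health = latent)

  for (i in seq_len(nrow(catalog))) {
    id <- catalog$measure_id[i]
    sgn <- if (catalog$direction[i] == "higher_is_worse") 1 else -1
    vals <- baselines[[id]] + sgn * effect[[id]] * latent +
      stats::rnorm(n, sd = noise[[id]])
    if (miss[[id]] > 0)
      vals[stats::runif(n) < miss[[id]]] <- NA_real_
    drop_states <- config$whole_state_missing[[id]]
    if (!is.null(drop_states))
      vals[state_col %in% drop_states] <- NA_real_
    tab[[id]] <- vals
    if (isTRUE(catalog$has_standard_error[i])) {
      scale_m <- sqrt(effect[[id]]^2 + noise[[id]]^2)
      se <- config$se_scale * scale_m / sqrt(population)
      se[is.na(vals)] <- NA_real_
      tab[[paste0(id, "_se")]] <- se
    }
  }
  list(table = tab, truth = truth)
}

# named vector / scalar / NULL -> one value per catalog measure
resolve_per_measure <- function(x, catalog, default) {
  ids <- catalog$measure_id
  if (is.null(x)) {
    out <- default
  } else if (is.null(names(x))) {
    out <- stats::setNames(rep_len(x, length(ids)), ids)
  } else {
    out <- default
    if (is.null(out)) out <- stats::setNames(numeric(length(ids)), ids)
    out[names(x)] <- x
  }
  stopifnot(all(ids %in% names(out)))
  out[ids]
}
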