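#' Measure catalogs
#'
#' A measure catalog is the weighted hierarchy behind the composite scores:
#' one row per measure, each assigned to a composite family (`outcomes` or
#' `factors`), a component within that family, a weight expressed as percent
#' of the family total, and a direction saying whether higher raw values mean
#' worse health (`higher_is_worse`) or better health (`higher_is_better`,
#' i.e. reverse-coded measures whose Z-scores are negated before
#' aggregation).
#'
#' Catalogs are ordinary tibbles with class `chr_catalog`, so they can be
#' built, filtered and re-weighted with the usual tidyverse verbs and then
#' re-validated with [validate_catalog()]. User-supplied catalogs (e.g. a
#' state adaptation with different measures or weights) are first-class:
#' every downstream function takes the catalog as an argument.
#'
#' @section Columns:
#' \describe{
#'   \item{measure_id}{short stable token, unique.}
#'   \item{display_name}{human-readable name.}
#'   \item{composite_family}{`"outcomes"` or `"factors"`.}
#'   \item{component}{`"mortality"` or `"morbidity"` (outcomes family);
#'     `"health_behaviors"`, `"clinical_care"`, `"social_economic"` or
#'     `"physical_environment"` (factors family).}
#'   \item{subcomponent}{free-text grouping label (e.g. "tobacco use").}
#'   \item{weight_pct}{percent of the composite family total, in (0, 100].}
#'   \item{direction}{`"higher_is_worse"` or `"higher_is_better"`.}
#'   \item{has_standard_error}{whether paired `<measure_id>_se` columns are
#'     expected in input tables, enabling the reliability filter.}
#'   \item{source_label, years_label}{provenance strings, not interpreted.}
#' }
#' @name chr_catalog
NULL

catalog_families <- c("outcomes", "factors")
catalog_components <- c(
  outcomes = "mortality", outcomes = "morbidity",
  factors = "health_behaviors", factors = "clinical_care",
  factors = "social_economic", factors = "physical_environment"
)

new_catalog <- function(df) {
  df <- tibble::as_tibble(df)
  class(df) <- c("chr_catalog", class(tibble::tibble()))
  df
}

#' The default 2014 measure catalog
#'
#' Returns the 34-measure catalog used by the 2014 County Health Rankings:
#' five health-outcome measures (premature death carrying 50% of the
#' outcomes family, the four morbidity measures the other 50%) and 29
#' health-factor measures split 30/20/40/10 across health behaviors,
#' clinical care, social and economic factors, and the physical environment.
#' Six measures are reverse-coded (`higher_is_better`): food environment
#' index, access to exercise opportunities, diabetic screening, mammography
#' screening, high school graduation, and some college.
#'
#' @return A [chr_catalog] tibble with 34 rows.
#' @examples
#' cat34 <- default_catalog()
#' dplyr::count(cat34, composite_family, wt = weight_pct)
#' @export
default_catalog <- function() {
  m <- function(id, name, family, comp, sub, w, dir, se, src, yrs) {
    tibble::tibble(
      measure_id = id, display_name = name, composite_family = family,
      component = comp, subcomponent = sub, weight_pct = w, direction = dir,
      has_standard_error = se, source_label = src, years_label = yrs
    )
  }
  worse <- "higher_is_worse"
  better <- "higher_is_better"
  df <- dplyr::bind_rows(
    # -- health outcomes ---------------------------------------------------
    m("premature_death", "Premature death (YPLL before 75 per 100,000)",
      "outcomes", "mortality", "length of life", 50, worse, TRUE,
      "National Center for Health Statistics", "2008-2010"),
    m("poor_or_fair_health", "Poor or fair health (%)",
      "outcomes", "morbidity", "quality of life", 10, worse, TRUE,
      "Behavioral Risk Factor Surveillance System", "2006-2012"),
    m("poor_physical_health_days", "Poor physical health days (per month)",
      "outcomes", "morbidity", "quality of life", 10, worse, TRUE,
      "Behavioral Risk Factor Surveillance System", "2006-2012"),
    m("poor_mental_health_days", "Poor mental health days (per month)",
      "outcomes", "morbidity", "quality of life", 10, worse, TRUE,
      "Behavioral Risk Factor Surveillance System", "2006-2012"),
    m("low_birthweight", "Low birthweight (% live births < 2500 g)",
      "outcomes", "morbidity", "quality of life", 20, worse, TRUE,
      "National Center for Health Statistics", "2005-2011"),
    # -- health behaviors (30) ---------------------------------------------
    m("adult_smoking", "Adult smoking (%)",
      "factors", "health_behaviors", "tobacco use", 10, worse, TRUE,
      "Behavioral Risk Factor Surveillance System", "2006-2012"),
    m("adult_obesity", "Adult obesity (%)",
      "factors", "health_behaviors", "diet and exercise", 5, worse, FALSE,
      "NCCDPHP", "2010"),
    m("food_environment_index", "Food environment index",
      "factors", "health_behaviors", "diet and exercise", 2, better, FALSE,
      "USDA Food Environment Atlas, Map the Meal Gap", "2010-2011"),
    m("physical_inactivity", "Physical inactivity (%)",
      "factors", "health_behaviors", "diet and exercise", 2, worse, FALSE,
      "NCCDPHP", "2010"),
    m("access_to_exercise", "Access to exercise opportunities (%)",
      "factors", "health_behaviors", "diet and exercise", 1, better, FALSE,
      "Business analyst, Delorme map data, Esri, US Census Tigerline",
      "2010 & 2012"),
    m("excessive_drinking", "Excessive drinking (%)",
      "factors", "health_behaviors", "alcohol and drug use", 2.5, worse, TRUE,
      "Behavioral Risk Factor Surveillance System", "2006-2012"),
    m("alcohol_impaired_driving_deaths", "Alcohol-impaired driving deaths (%)",
      "factors", "health_behaviors", "alcohol and drug use", 2.5, worse, FALSE,
      "Fatality Analysis Reporting System", "2008-2012"),
    m("sexually_transmitted_infections", "Sexually transmitted infections (per 100,000)",
      "factors", "health_behaviors", "sexual activity", 2.5, worse, FALSE,
      "NCHHSTP", "2011"),
    m("teen_births", "Teen births (per 1,000 females 15-19)",
      "factors", "health_behaviors", "sexual activity", 2.5, worse, FALSE,
      "National Center for Health Statistics", "2005-2011"),
    # -- clinical care (20) ------------------------------------------------
    m("uninsured", "Uninsured under 65 (%)",
      "factors", "clinical_care", "access to care", 5, worse, FALSE,
      "Small Area Health Insurance Estimates", "2011"),
    m("primary_care_physicians", "Primary care physicians (population ratio)",
      "factors", "clinical_care", "access to care", 3, worse, FALSE,
      "HRSA Area Resource File", "2011"),
    m("dentists", "Dentists (population ratio)",
      "factors", "clinical_care", "access to care", 1, worse, FALSE,
      "HRSA Area Resource File", "2012"),
    m("mental_health_providers", "Mental health providers (population ratio)",
      "factors", "clinical_care", "access to care", 1, worse, FALSE,
      "CMS National Provider Identification", "2013"),
    m("preventable_hospital_stays", "Preventable hospital stays (per 1,000 Medicare enrollees)",
      "factors", "clinical_care", "quality of care", 5, worse, FALSE,
      "Medicare/Dartmouth Institute", "2011"),
    m("diabetic_screening", "Diabetic screening (%)",
      "factors", "clinical_care", "quality of care", 2.5, better, FALSE,
      "Medicare/Dartmouth Institute", "2011"),
    m("mammography_screening", "Mammography screening (%)",
      "factors", "clinical_care", "quality of care", 2.5, better, FALSE,
      "Medicare/Dartmouth Institute", "2011"),
    # -- social and economic factors (40) ----------------------------------
    m("high_school_graduation", "High school graduation (%)",
      "factors", "social_economic", "education", 5, better, FALSE,
      "data.gov / National Center for Education Statistics", "2010-2011"),
    m("some_college", "Some college (%)",
      "factors", "social_economic", "education", 5, better, FALSE,
      "American Community Survey", "2008-2012"),
    m("unemployment", "Unemployment (%)",
      "factors", "social_economic", "employment", 10, worse, FALSE,
      "Bureau of Labor Statistics", "2012"),
    m("children_in_poverty", "Children in poverty (%)",
      "factors", "social_economic", "income", 10, worse, FALSE,
      "Small Area Income and Poverty Estimates", "2012"),
    m("inadequate_social_support", "Inadequate social support (%)",
      "factors", "social_economic", "family and social support", 2.5, worse, TRUE,
      "Behavioral Risk Factor Surveillance System", "2005-2010"),
    m("children_single_parent", "Children in single-parent households (%)",
      "factors", "social_economic", "family and social support", 2.5, worse, FALSE,
      "American Community Survey", "2008-2012"),
    m("violent_crime", "Violent crime (per 100,000)",
      "factors", "social_economic", "community safety", 2.5, worse, FALSE,
      "Uniform Crime Reporting - FBI", "2009-2011"),
    m("injury_deaths", "Injury deaths (per 100,000)",
      "factors", "social_economic", "community safety", 2.5, worse, FALSE,
      "CDC WONDER", "2006-2010"),
    # -- physical environment (10) -----------------------------------------
    m("air_pollution", "Air pollution - particulate matter (ug/m3)",
      "factors", "physical_environment", "air and water quality", 2.5, worse, FALSE,
      "CDC WONDER", "2011"),
    m("drinking_water_violations", "Drinking water violations (%)",
      "factors", "physical_environment", "air and water quality", 2.5, worse, FALSE,
      "Safe Drinking Water Information System", "FY 2012-2013"),
    m("severe_housing_problems", "Severe housing problems (%)",
      "factors", "physical_environment", "housing and transit", 2, worse, FALSE,
      "HUD Comprehensive Housing Affordability Strategy", "2006-2010"),
    m("driving_alone_to_work", "Driving alone to work (%)",
      "factors", "physical_environment", "housing and transit", 2, worse, FALSE,
      "American Community Survey", "2008-2012"),
    m("long_commute_driving_alone", "Long commute - driving alone (%)",
      "factors", "physical_environment", "housing and transit", 1, worse, FALSE,
      "American Community Survey", "2008-2012")
  )
  new_catalog(df)
}

#' Component weight subtotals of a catalog
#'
#' @param catalog a [chr_catalog] tibble.
#' @return A tibble with one row per (composite_family, component) and its
#'   `weight_pct` subtotal (percent of the family).
#' @export
component_weights <- function(catalog) {
  catalog |>
    dplyr::group_by(.data$composite_family, .data$component) |>
    dplyr::summarise(weight_pct = sum(.data$weight_pct), .groups = "drop")
}

#' Validate a measure catalog
#'
#' Checks the structural invariants a catalog must satisfy before it can
#' drive scoring: required columns, unique measure ids, positive weights,
#' valid family/component/direction values, family-consistent components
#' (mortality/morbidity belong to outcomes, the other four to factors), and
#' family weight totals of 100 (tolerance 1e-9). Validation never raises:
#' every violation becomes a row of the returned report, and an empty report
#' means the catalog is valid.
#'
#' @param catalog a candidate catalog (any data frame with the
#'   [chr_catalog] columns).
#' @return A tibble with columns `check` and `detail`, zero rows if valid.
#' @examples
#' nrow(validate_catalog(default_catalog()))  # 0
#' @export
validate_catalog <- function(catalog) {
  issues <- list()
  add <- function(check, detail) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(check = check, detail = detail)
  }
  required <- c("measure_id", "composite_family", "component", "weight_pct",
                "direction")
  missing_cols <- setdiff(required, names(catalog))
  if (length(missing_cols) > 0) {
    add("missing_columns", paste("missing columns:",
                                 paste(missing_cols, collapse = ", ")))
    return(dplyr::bind_rows(issues))
  }
  dup <- unique(catalog$measure_id[duplicated(catalog$measure_id)])
  if (length(dup) > 0)
    add("duplicate_measure_id",
        paste("duplicated measure_id:", paste(dup, collapse = ", ")))
  bad_w <- catalog$measure_id[!is.finite(catalog$weight_pct) |
                                catalog$weight_pct <= 0 |
                                catalog$weight_pct > 100]
  if (length(bad_w) > 0)
    add("weight_out_of_range",
        paste("weight_pct must be in (0, 100]:", paste(bad_w, collapse = ", ")))
  bad_f <- catalog$measure_id[!catalog$composite_family %in% catalog_families]
  if (length(bad_f) > 0)
    add("unknown_family",
        paste("composite_family must be outcomes/factors:",
              paste(bad_f, collapse = ", ")))
  bad_c <- catalog$measure_id[!catalog$component %in% catalog_components]
  if (length(bad_c) > 0)
    add("unknown_component",
        paste("unknown component:", paste(bad_c, collapse = ", ")))
  bad_d <- catalog$measure_id[!catalog$direction %in%
                                c("higher_is_worse", "higher_is_better")]
  if (length(bad_d) > 0)
    add("unknown_direction",
        paste("unknown direction:", paste(bad_d, collapse = ", ")))
  ok <- catalog$composite_family %in% catalog_families &
    catalog$component %in% catalog_components
  expected_family <- names(catalog_components)[
    match(catalog$component, catalog_components)]
  mism <- catalog$measure_id[ok & catalog$composite_family != expected_family]
  if (length(mism) > 0)
    add("component_family_mismatch",
        paste("component inconsistent with composite_family:",
              paste(mism, collapse = ", ")))
  for (fam in catalog_families) {
    w <- catalog$weight_pct[catalog$composite_family == fam &
                              is.finite(catalog$weight_pct)]
    if (length(w) > 0 && abs(sum(w) - 100) > 1e-9)
      add("family_weight_sum",
          sprintf("%s weights sum to %.10g, expected 100", fam, sum(w)))
  }
  if (length(issues) == 0)
    tibble::tibble(check = character(), detail = character())
  else
    dplyr::bind_rows(issues)
}

stop_if_invalid_catalog <- function(catalog) {
  rep <- validate_catalog(catalog)
  if (nrow(rep) > 0)
    stop("invalid measure catalog:\n  ",
         paste(rep$detail, collapse = "\n  "), call. = FALSE)
  invisible(new_catalog(catalog))
}

#' Read / write a measure catalog
#'
#' Catalogs serialize to JSON or YAML (chosen by file extension) as an array
#' of per-measure records carrying the [chr_catalog] fields, so users can
#' export the default, edit weights or swap measures, and load their own.
#' `read_catalog()` validates after parsing and fails with the full list of
#' violations.
#'
#' @param path file path; `.json` or `.yaml`/`.yml`.
#' @param catalog a [chr_catalog] tibble.
#' @return `read_catalog()` returns a validated [chr_catalog];
#'   `write_catalog()` returns `path` invisibly.
#' @export
read_catalog <- function(path) {
  ext <- tolower(tools::file_ext(path))
  rec <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    yaml = ,
    yml = {
      y <- yaml::read_yaml(path)
      dplyr::bind_rows(lapply(y, tibble::as_tibble))
    },
    stop("unsupported catalog format: ", ext, call. = FALSE)
  )
  stop_if_invalid_catalog(tibble::as_tibble(rec))
}

#' @rdname read_catalog
#' @export
write_catalog <- function(catalog, path) {
  ext <- tolower(tools::file_ext(path))
  df <- as.data.frame(catalog)
  switch(ext,
    json = jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    yaml = ,
    yml = yaml::write_yaml(
      lapply(seq_len(nrow(df)), function(i) as.list(df[i, ])), path),
    stop("unsupported catalog format: ", ext, call. = FALSE)
  )
  invisible(path)
}
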