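#' Published 2014 extremes comparison (reference data)
#'
#' The per-measure group means published in the 2014 County Health
#' Rankings comparison of the five least-healthy (LH) and five healthiest
#' (H) counties of each state with at least ten counties: means over All
#' 3,027 included counties, the 230-county LH and H pools, and the 2,567
#' Others, in each measure's raw units, plus the mean 2011 population
#' estimate. Useful as a worked example for [extremes_ratio()] — e.g.
#' premature death at 10,862 (LH) vs 5,113 (H) years of potential life
#' lost per 100,000 gives the published two-fold ratio — and as a set of
#' realistic measure baselines.
#'
#' @return A tibble `measure_id`, `all`, `least_healthy`, `healthy`,
#'   `others` mirroring [compare_extremes()] output (first row
#'   `n_counties`, last row `population_mean`).
#' @export
extremes_reference_2014 <- function() {
  tibble::tribble(
    ~measure_id,                        ~all,   ~least_healthy, ~healthy, ~others,
    "n_counties",                       3027,   230,     230,    2567,
    "premature_death",                  7746,   10862,   5113,   7785,
    "poor_or_fair_health",              17,     20,      11,     17,
    "poor_physical_health_days",        3.7,    4.4,     2.9,    3.8,
    "poor_mental_health_days",          3.5,    4,       2.9,    3.5,
    "low_birthweight",                  8,      9,       7,      8,
    "adult_smoking",                    21,     24,      16,     21,
    "adult_obesity",                    31,     32,      27,     31,
    "food_environment_index",           2.4,    3.3,     1.8,    2.4,
    "physical_inactivity",              28,     30,      23,     28,
    "access_to_exercise",               54,     47,      69,     53,
    "excessive_drinking",               16,     16,      17,     16,
    "alcohol_impaired_driving_deaths",  31,     31,      30,     32,
    "sexually_transmitted_infections",  271,    312,     214,    277,
    "teen_births",                      42.4,   55.43,   21.61,  43.53,
    "uninsured",                        18,     18,      15,     18,
    "primary_care_physicians",          1980,   2087,    1472,   2003,
    "dentists",                         2730,   2740,    1973,   2841,
    "mental_health_providers",          1640,   1379,    1131,   1728,
    "preventable_hospital_stays",       71,     78,      56,     73,
    "diabetic_screening",               85,     83,      86,     85,
    "mammography_screening",            61,     57,      66,     61,
    "high_school_graduation",           83,     77,      86,     83,
    "some_college",                     55,     49,      68,     54,
    "unemployment",                     8,      9,       6,      8,
    "children_in_poverty",              24,     31,      15,     24,
    "inadequate_social_support",        19,     23,      17,     19,
    "children_single_parent",           31,     38,      24,     31,
    "violent_crime",                    204.55, 258.95,  156.02, 206.97,
    "injury_deaths",                    73,     98.3,    53.7,   73.2,
    "air_pollution",                    11.93,  11.8,    11.5,   11.98,
    "drinking_water_violations",        1,      3,       1,      1,
    "severe_housing_problems",          14,     15,      14,     13,
    "driving_alone_to_work",            80,     78,      78,     80,
    "long_commute_driving_alone",       29,     29,      30,     29,
    "population_mean",                  26837,  18300,   75755,  26310
  )
}
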