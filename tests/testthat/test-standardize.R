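test_that("reliability flag implements the 20% RSE rule", {
  expect_true(flag_unreliable(100, 25))
  expect_false(flag_unreliable(100, 10))
  expect_false(flag_unreliable(100, 20))           # boundary: strictly >
  expect_true(flag_unreliable(0, 1))               # RSE diverges at value 0
  expect_false(flag_unreliable(0, 0))
  expect_true(flag_unreliable(-50, 20))            # magnitude, not sign
  expect_true(is.na(flag_unreliable(NA, 1)))
  expect_error(flag_unreliable(10, -1), "non-negative")
})

test_that("direction flip negates reverse-coded scores only", {
  expect_equal(apply_direction(1.5, "higher_is_better"), -1.5)
  expect_equal(apply_direction(1.5, "higher_is_worse"), 1.5)
  expect_equal(apply_direction(0, "higher_is_better"), 0)
  expect_error(apply_direction(1, "sideways"), "unknown direction")
})

test_that("small-county truncation clamps to +/-3 at the inclusive cutoff", {
  expect_equal(truncate_small_county(3.7, 15000), 3.0)
  expect_equal(truncate_small_county(3.7, 25000), 3.7)
  expect_equal(truncate_small_county(-3.5, 20000), -3.0)   # 20,000 inclusive
  expect_equal(truncate_small_county(-3.5, 20001), -3.5)
  expect_equal(truncate_small_county(2.9, 100), 2.9)
})

test_that("within-state z-scores standardize observed counties", {
  cat1 <- mini_catalog()
  std <- compute_zscores(one_state_table(c(1, 2, 3)), cat1)
  expect_equal(std$z, c(-1, 0, 1))                 # sample SD of 1,2,3 is 1
  expect_false(any(std$imputed | std$truncated | std$unreliable))

  # constant column: no information, z = 0, no crash
  std0 <- compute_zscores(one_state_table(c(4, 4, 4, 4)), cat1)
  expect_equal(std0$z, rep(0, 4))

  # missing value: imputed to the state mean (z = 0), mean/SD from the rest
  stdm <- compute_zscores(one_state_table(c(1, 2, 3, NA)), cat1)
  expect_equal(stdm$z, c(-1, 0, 1, 0))
  expect_equal(stdm$imputed, c(FALSE, FALSE, FALSE, TRUE))

  # population SD option
  stdp <- compute_zscores(one_state_table(c(1, 2, 3)), cat1,
                          sd_method = "population")
  expect_equal(stdp$z, c(-1, 0, 1) * sqrt(3 / 2))
})

test_that("unreliable cells are imputed but remembered", {
  cat1 <- mini_catalog()
  tab <- one_state_table(c(10, 20, 30, 40), se = c(1, 1, 50, 1))
  std <- compute_zscores(tab, cat1)
  expect_equal(std$unreliable, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(std$imputed, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(std$z[3], 0)
  # state mean/SD come from the three reliable counties only
  obs <- c(10, 20, 40)
  expect_equal(std$z[c(1, 2, 4)], (obs - mean(obs)) / sd(obs))
})

test_that("whole-state missing measures are dropped, not crashed on", {
  cat2 <- mini_catalog(factor_ids = "m_fac", factor_weights = 100)
  tab <- dplyr::bind_rows(
    one_state_table(c(1, 2, 3), state = "S1"),
    one_state_table(c(4, 5, 6), state = "S2"))
  tab$m_fac <- c(7, 8, 9, NA, NA, NA)   # m_fac absent in all of S2
  tab$fips <- sprintf("%05d", 1:6)
  std <- compute_zscores(tab, cat2)
  dropped <- std[std$measure_id == "m_fac" & std$state == "S2", ]
  expect_true(all(dropped$state_dropped))
  expect_true(all(is.na(dropped$z)))
  expect_false(any(std$state_dropped[std$measure_id == "m_out"]))
})

test_that("z-scores are invariant to location and positive scale", {
  cat1 <- mini_catalog()
  set.seed(11)
  vals <- rnorm(20, 50, 10)
  base <- compute_zscores(one_state_table(vals), cat1)
  shifted <- compute_zscores(one_state_table(vals * 7.3 + 100), cat1)
  expect_equal(shifted$z, base$z, tolerance = 1e-12)
})

test_that("observed z has mean 0 and SD 1 within each state-measure", {
  set.seed(21)
  sim <- simulate_counties(
    simulation_config(n_states = 5, counties_per_state = c(20, 40),
                      seed = 21,
                      population_log_mean = 12))  # large counties: no truncation
  std <- compute_zscores(sim$table)
  chk <- std |>
    dplyr::filter(!imputed, !state_dropped) |>
    dplyr::group_by(state, measure_id) |>
    dplyr::summarise(m = mean(z), s = sd(z), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(n >= 2)
  expect_lt(max(abs(chk$m)), 1e-9)
  expect_lt(max(abs(chk$s - 1)), 1e-9)
})

test_that("truncation only ever shrinks magnitudes of small counties", {
  cat1 <- mini_catalog()
  set.seed(31)
  n <- 60
  tab <- one_state_table(c(rnorm(n - 1), 50), population = 15000)
  tab$population[seq(1, n, 2)] <- 80000
  std <- compute_zscores(tab, cat1)
  raw <- compute_zscores(dplyr::mutate(tab, population = 1e6), cat1)
  small <- std$population <= 20000
  expect_true(all(abs(std$z[small]) <= 3))
  expect_true(all(abs(std$z) <= abs(raw$z) + 1e-12))
  expect_equal(std$z[!small], raw$z[!small])
  expect_true(all(std$truncated == (std$z != raw$z)))
})

test_that("pipeline standardization matches a naive per-cell oracle", {
  cat34 <- default_catalog()
  for (s in 1:8) {
    sim <- simulate_counties(
      simulation_config(n_states = 3, counties_per_state = c(4, 10),
                        seed = 100 + s, se_scale = 200,
                        whole_state_missing = list()),
      cat34)
    std <- compute_zscores(sim$table, cat34)
    oracle <- naive_zscores(sim$table, cat34)
    joined <- dplyr::inner_join(std, oracle, by = c("fips", "measure_id"))
    expect_equal(nrow(joined), nrow(std))
    expect_equal(joined$z, joined$z_oracle, tolerance = 1e-12)
  }
})
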