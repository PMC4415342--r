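test_that("composites are hand-checkable weighted sums of z-scores", {
  cat34 <- default_catalog()

  # premature death carries 50% of outcomes
  std <- manual_std(cat34, z = c(premature_death = 1.0))
  sc <- compute_composites(std, cat34)
  expect_equal(sc$outcomes, 0.5)
  expect_equal(sc$mortality, 0.5)
  expect_equal(sc$morbidity, 0)
  expect_equal(sc$factors, 0)

  # adult smoking carries 10% of factors
  sc2 <- compute_composites(manual_std(cat34, z = c(adult_smoking = 2.0)),
                            cat34)
  expect_equal(sc2$factors, 0.2)
  expect_equal(sc2$health_behaviors, 0.2)
  expect_equal(sc2$outcomes, 0)

  # all zeros in, all zeros out
  sc0 <- compute_composites(manual_std(cat34), cat34)
  expect_true(all(as.matrix(sc0[composite_names()]) == 0))
})

test_that("component scores partition the family scores", {
  set.seed(5)
  sim <- simulate_counties(
    simulation_config(n_states = 4, counties_per_state = c(10, 30), seed = 5))
  sc <- compute_composites(compute_zscores(sim$table))
  expect_equal(sc$outcomes, sc$mortality + sc$morbidity, tolerance = 1e-12)
  expect_equal(sc$factors,
               sc$health_behaviors + sc$clinical_care + sc$social_economic +
                 sc$physical_environment,
               tolerance = 1e-12)
})

test_that("whole-state missing measures renormalize family weights", {
  cat34 <- default_catalog()
  sim <- simulate_counties(
    simulation_config(n_states = 3, counties_per_state = 15, seed = 77,
                      whole_state_missing = list(air_pollution = "S02")))
  std <- compute_zscores(sim$table, cat34)
  w <- effective_weights(std, cat34)
  # in the affected state, remaining factor weights scale by 100/97.5
  w_s2 <- w[w$state == "S02" & w$composite_family == "factors", ]
  expect_false("air_pollution" %in% w_s2$measure_id)
  expect_equal(sum(w_s2$weight_pct), 100, tolerance = 1e-12)
  expect_equal(w_s2$weight_pct[w_s2$measure_id == "adult_smoking"],
               10 * 100 / 97.5, tolerance = 1e-12)
  # untouched states keep nominal weights
  w_s1 <- w[w$state == "S01" & w$composite_family == "factors", ]
  expect_equal(w_s1$weight_pct[w_s1$measure_id == "adult_smoking"], 10)
  # family partition still holds under renormalization
  sc <- compute_composites(std, cat34)
  expect_equal(sc$factors,
               sc$health_behaviors + sc$clinical_care + sc$social_economic +
                 sc$physical_environment,
               tolerance = 1e-12)
})

test_that("unrankable counties are flagged by the three mortality rules", {
  cat34 <- default_catalog()
  sim <- simulate_counties(
    simulation_config(n_states = 1, counties_per_state = 8, seed = 13,
                      missing_rate = 0, se_scale = 0,
                      whole_state_missing = list()))
  tab <- sim$table
  morb <- c("poor_or_fair_health", "poor_physical_health_days",
            "poor_mental_health_days", "low_birthweight")

  # county 1: premature death missing -> rule 1
  tab$premature_death[1] <- NA
  # county 2: premature death unreliable, poor-or-fair-health observed -> ranked
  tab$premature_death_se[2] <- tab$premature_death[2]
  # county 3: premature death unreliable, all morbidity missing -> rule 2
  tab$premature_death_se[3] <- tab$premature_death[3]
  for (m in morb) tab[[m]][3] <- NA
  # county 4: pd + lbw unreliable, other morbidity missing -> rule 3
  tab$premature_death_se[4] <- tab$premature_death[4]
  tab$low_birthweight_se[4] <- tab$low_birthweight[4]
  for (m in setdiff(morb, "low_birthweight")) tab[[m]][4] <- NA

  std <- compute_zscores(tab, cat34)
  un <- determine_unranked(std, cat34)
  expect_equal(un$unranked, c(TRUE, FALSE, TRUE, TRUE, rep(FALSE, 4)))
  expect_equal(un$unranked_reason[1:4],
               c("missing_premature_death", "none",
                 "unreliable_pd_no_morbidity",
                 "unreliable_pd_lbw_no_morbidity"))
})

test_that("within-state competition ranking follows the tie rule", {
  sc <- manual_composites(c(0.2, -1.0, 0.2, 0.5))
  rk <- rank_within_state(sc)
  expect_equal(rk$rank_outcomes, c(2L, 1L, 2L, 4L))

  # distinct scores: ranks are the ascending permutation
  sc2 <- manual_composites(c(3, 1, 2))
  expect_equal(rank_within_state(sc2)$rank_outcomes, c(3L, 1L, 2L))

  # a single ranked county gets rank 1
  expect_equal(rank_within_state(manual_composites(0.7))$rank_outcomes, 1L)

  # unranked counties get no rank and do not occupy a position
  un <- tibble::tibble(fips = sc$fips, state = sc$state,
                       unranked = c(FALSE, TRUE, FALSE, FALSE),
                       unranked_reason = c("none", "missing_premature_death",
                                           "none", "none"))
  rk2 <- rank_within_state(sc, un)
  expect_equal(rk2$rank_outcomes, c(1L, NA, 1L, 3L))
})

test_that("ranks match a brute-force sort oracle on small states", {
  for (s in 1:25) {
    set.seed(400 + s)
    n_states <- 3
    sizes <- sample(2:6, n_states, replace = TRUE)
    scores <- round(rnorm(sum(sizes)), sample(c(1, 6), 1))  # force some ties
    sc <- manual_composites(scores,
                            state = rep(sprintf("S%d", 1:n_states), sizes))
    rk <- rank_within_state(sc)
    for (st in unique(sc$state)) {
      got <- rk$rank_outcomes[rk$state == st]
      expect_equal(got, naive_rank(sc$outcomes[sc$state == st]))
    }
  }
})

test_that("quartiles follow the ceiling formula on outcome ranks", {
  q8 <- assign_quartiles(rank_within_state(manual_composites(8:1)))
  expect_equal(q8$quartile_outcomes[order(q8$rank_outcomes)],
               c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))

  q72 <- assign_quartiles(rank_within_state(manual_composites(1:72)))
  expect_equal(q72$quartile_outcomes[q72$rank_outcomes == 18], 1L)
  expect_equal(q72$quartile_outcomes[q72$rank_outcomes == 19], 2L)

  # single-county state: rank 1 is quartile 4 by the formula (ceil(4/1))
  q1 <- assign_quartiles(rank_within_state(manual_composites(0.3)))
  expect_equal(q1$quartile_outcomes, 4L)
})

test_that("national benchmarks take the direction-aware best-10% boundary", {
  cat2 <- mini_catalog(factor_ids = "m_good", factor_weights = 100,
                       factor_directions = "higher_is_better")
  tab <- one_state_table(as.numeric(1:100))
  tab$m_good <- as.numeric(1:100)
  bm <- national_benchmark(tab, cat2)
  expect_equal(bm$benchmark[bm$measure_id == "m_out"], 10.9)   # 10th pctile
  expect_equal(bm$benchmark[bm$measure_id == "m_good"], 90.1)  # 90th pctile

  # constant column benchmarks at the constant
  tabc <- one_state_table(rep(5, 30))
  tabc$m_good <- rep(5, 30)
  expect_equal(national_benchmark(tabc, cat2)$benchmark, c(5, 5))

  # too few observed counties: unavailable
  tabf <- one_state_table(c(1:5, rep(NA, 20)))
  tabf$m_good <- as.numeric(1:25)
  bmf <- national_benchmark(tabf, cat2)
  expect_true(is.na(bmf$benchmark[bmf$measure_id == "m_out"]))
  # benchmark always inside the observed range
  expect_true(all(bmf$benchmark >= 1 & bmf$benchmark <= 25, na.rm = TRUE))
})

test_that("extremes comparison pools k best and worst per eligible state", {
  sim <- simulate_counties(
    simulation_config(n_states = 6,
                      counties_per_state = c(12, 15, 4, 20, 11, 30),
                      seed = 55, missing_rate = 0,
                      whole_state_missing = list()))
  res <- run_rankings(sim$table, quiet = TRUE)
  ext <- res$extremes
  n_row <- ext[ext$measure_id == "n_counties", ]
  # the 4-county state is excluded; 5 states contribute 5 + 5 counties
  expect_equal(n_row$least_healthy, 25)
  expect_equal(n_row$healthy, 25)
  expect_equal(n_row$all, 12 + 15 + 20 + 11 + 30)
  expect_equal(n_row$others, n_row$all - 50)

  # LH group genuinely is less healthy on the outcome anchor
  pd <- ext[ext$measure_id == "premature_death", ]
  expect_gt(pd$least_healthy, pd$healthy)
  expect_equal(pd$ratio_lh_h,
               round(pd$least_healthy / pd$healthy, 1))

  # groups are disjoint and sized k even in a state with 11 counties
  ranked <- res$rankings[res$rankings$state == "S05", ]
  expect_equal(sum(!ranked$unranked), 11)
})

test_that("published group means reproduce the published LH/H ratios", {
  ref <- extremes_reference_2014()
  expected <- c(premature_death = 2.1, poor_or_fair_health = 1.8,
                teen_births = 2.6, children_in_poverty = 2.1,
                drinking_water_violations = 3.0, access_to_exercise = 0.7,
                unemployment = 1.5, adult_smoking = 1.5,
                preventable_hospital_stays = 1.4, injury_deaths = 1.8)
  got <- extremes_ratio(
    ref$least_healthy[match(names(expected), ref$measure_id)],
    ref$healthy[match(names(expected), ref$measure_id)])
  expect_equal(unname(got), unname(expected))
  expect_equal(extremes_ratio(7, 7), 1.0)
})

test_that("ranks are invariant to input row order and worsening is monotone", {
  sim <- simulate_counties(
    simulation_config(n_states = 3, counties_per_state = c(8, 25), seed = 99))
  tab <- sim$table

  res <- run_rankings(tab, quiet = TRUE)
  set.seed(123)
  shuf <- tab[sample(nrow(tab)), ]
  res_shuf <- run_rankings(shuf, quiet = TRUE)
  expect_equal(res$rankings, res_shuf$rankings)

  # worsening one county on one reliable measure never improves its rank
  # (a cell that is unreliable, hence state-mean imputed, can legitimately
  # re-enter scoring when worsening pushes its RSE under the cutoff, so
  # monotonicity is asserted for cells whose reliability status is stable)
  cat34 <- default_catalog()
  set.seed(321)
  for (i in 1:40) {
    row <- sample(nrow(tab), 1)
    m <- cat34[sample(nrow(cat34), 1), ]
    old <- tab[[m$measure_id]][row]
    if (is.na(old)) next
    if (res$rankings$unranked[res$rankings$fips == tab$fips[row]]) next
    se_col <- paste0(m$measure_id, "_se")
    if (se_col %in% names(tab)) {
      se <- tab[[se_col]][row]
      if (!is.na(se) && isTRUE(flag_unreliable(old, se))) next
    }
    tab2 <- tab
    delta <- (1 + runif(1)) * sd(tab[[m$measure_id]], na.rm = TRUE)
    tab2[[m$measure_id]][row] <- old +
      ifelse(m$direction == "higher_is_worse", delta, -delta)
    r2 <- run_rankings(tab2, quiet = TRUE)$rankings
    comp <- paste0("rank_", ifelse(m$composite_family == "outcomes",
                                   "outcomes", "factors"))
    before <- res$rankings[[comp]][res$rankings$fips == tab$fips[row]]
    after <- r2[[comp]][r2$fips == tab$fips[row]]
    expect_gte(after, before)
  }
})
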