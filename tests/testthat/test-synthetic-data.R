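test_that("GDU generator is seeded, clamped, and respects degenerate profiles", {
  p <- site_profile(mean_gdu = 9, seasonal_amplitude = 0, noise_sd = 0,
                    n_years = 1)
  s <- gen_gdu_series(p)
  expect_equal(nrow(s), 365L)
  expect_true(all(s$gdu == 9))
  # bit-reproducible per seed, different across seeds
  p1 <- site_profile_site0(n_years = 1, seed = 5)
  expect_identical(gen_gdu_series(p1)$gdu, gen_gdu_series(p1)$gdu)
  p2 <- site_profile_site0(n_years = 1, seed = 6)
  expect_false(identical(gen_gdu_series(p1)$gdu, gen_gdu_series(p2)$gdu))
  # no negative GDUs even with violent noise
  pn <- site_profile(mean_gdu = 2, seasonal_amplitude = 1.5, noise_sd = 5,
                     n_years = 1)
  expect_true(all(gen_gdu_series(pn)$gdu >= 0))
  # amplitude must stay below the mean
  expect_error(site_profile(5, 6, 1), "smaller")
})

test_that("default site profiles reproduce the two-site contrast", {
  s0 <- gen_gdu_series(site_profile_site0())
  s1 <- gen_gdu_series(site_profile_site1(), site = "site1")
  expect_equal(nrow(s0), 3650L)
  # site 0 cool and steady: mostly below 10 degree-days
  expect_gte(mean(s0$gdu < 10), 0.9)
  # site 1 warm: mainly above 10
  expect_gt(mean(s1$gdu > 10), 0.5)
  # site 1 has the higher variance at matched length
  expect_gt(var(s1$gdu), var(s0$gdu))
})

test_that("population generator calibrates maturity into the 95-120 day range", {
  series <- gen_gdu_series(site_profile_site0(n_years = 2))
  prof <- population_profile(n_populations = 25, seed = 8)
  pops <- gen_population_table(prof, series)
  expect_equal(nrow(pops), 25L)
  expect_true(all(pops$window_end_day >= pops$window_start_day))
  expect_true(all(pops$qty_scenario1 >= 50 & pops$qty_scenario1 <= 500))
  # reproducible per seed
  expect_identical(pops, gen_population_table(prof, series))
  # typical days-to-maturity from the earliest window day lands near 95-120
  k <- vapply(seq_len(nrow(pops)), function(i) {
    accumulate_to_threshold(series, pops$window_start_day[i],
                            pops$required_gdu[i], 200L)
  }, integer(1))
  expect_true(all(!is.na(k)))
  expect_true(median(k) >= 80 && median(k) <= 135)
  # construction guarantee: every eligibility row non-empty
  H <- build_harvest_week_matrix(pops, series)
  elig <- build_eligibility_matrix(H)
  expect_equal(unschedulable_populations(elig), character(0))
  # degenerate single-population profile is fully determined
  prof1 <- population_profile(n_populations = 1,
                              window_start_range = c(10L, 10L),
                              window_length_range = c(7L, 7L),
                              quantity_range = c(100L, 100L), seed = 1)
  one <- gen_population_table(prof1, series)
  expect_equal(one$window_start_day, 10L)
  expect_equal(one$window_end_day, 16L)
  expect_equal(one$qty_scenario1, 100)
})

test_that("case fixtures deterministically exercise both solver paths", {
  site <- site_profile_site0(n_years = 2, seed = 21)
  pops <- population_profile(n_populations = 15, seed = 22)
  tight <- gen_case_fixture(site, pops, case = "fixed", flavor = "tight")
  expect_lt(tight$capacity, tight$c_min)
  expect_true(is_infeasible(solve_base_fixed(tight$instance)))

  ample <- gen_case_fixture(site, pops, case = "fixed", flavor = "ample")
  expect_gte(ample$capacity, ample$c_min)
  s <- solve_base_fixed(ample$instance)
  expect_false(is_infeasible(s))
  # ample path yields z = 0
  expect_equal(solve_min_extra_capacity(ample$instance)$z, 0)

  flex <- gen_case_fixture(site, pops, case = "flexible")
  cz <- solve_min_capacity_flexible(flex$instance)$c_z
  expect_gte(cz, max(flex$instance$quantities))
})
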