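toy_instance <- function(capacity = 5) {
  elig <- matrix(1L, 3, 2, dimnames = list(c("a", "b", "c"), NULL))
  scheduling_instance(c(a = 4, b = 4, c = 4), elig, capacity = capacity)
}

test_that("base model solves trivial and enumerable instances", {
  # single population, one eligible week
  e1 <- matrix(0L, 1, 5, dimnames = list("p1", NULL))
  e1[1, 3] <- 1L
  s <- solve_base_fixed(scheduling_instance(c(p1 = 5), e1, capacity = 10))
  expect_false(is_infeasible(s))
  expect_equal(s$assignment$harvest_week, 3L)
  expect_equal(length(s$used_weeks), 1L)

  # three populations fit one week when 12 <= 12
  e2 <- matrix(1L, 3, 2, dimnames = list(c("a", "b", "c"), NULL))
  s2 <- solve_base_fixed(scheduling_instance(c(a = 4, b = 4, c = 4), e2, 12))
  expect_equal(length(s2$used_weeks), 1L)

  # pigeonhole: 3 populations, 2 weeks, any doubled week holds 8 > 5
  expect_true(is_infeasible(solve_base_fixed(toy_instance(5))))
})

test_that("extra-capacity model finds the minimal uniform relaxation", {
  expect_equal(solve_min_extra_capacity(toy_instance(5))$z, 3)
  # feasible base: z = 0
  expect_equal(solve_min_extra_capacity(toy_instance(12))$z, 0)
  # single population forces C + Z >= Q
  e1 <- matrix(1L, 1, 2, dimnames = list("p1", NULL))
  inst <- scheduling_instance(c(p1 = 9), e1, capacity = 5)
  expect_equal(solve_min_extra_capacity(inst)$z, 4)
})

test_that("peak-week model concentrates extra capacity on the peak weeks", {
  pk <- solve_peak_weeks(toy_instance(5), 3)
  expect_equal(pk$total, 3)
  expect_equal(sort(pk$m, decreasing = TRUE)[1], 3)
  expect_equal(length(pk$peak_weeks), 1L)
  # z = 0 on a feasible instance: m identically zero
  pk0 <- solve_peak_weeks(toy_instance(12), 0)
  expect_equal(pk0$total, 0)
  expect_equal(pk0$peak_weeks, integer(0))
  # forced co-assignment in a single shared week
  e <- matrix(0L, 2, 3, dimnames = list(c("a", "b"), NULL))
  e[, 2] <- 1L
  inst <- scheduling_instance(c(a = 6, b = 6), e, capacity = 5)
  z <- solve_min_extra_capacity(inst)$z
  expect_equal(z, 7)
  pk2 <- solve_peak_weeks(inst, z)
  expect_equal(pk2$m[2], 7)
  expect_equal(pk2$peak_weeks, 2L)
})

test_that("allocation with peaks reduces to the base model when m = 0", {
  inst <- toy_instance(12)
  s_base <- solve_base_fixed(inst)
  s_m0 <- solve_allocation_with_peaks(inst, rep(0, inst$n_weeks))
  expect_equal(length(s_m0$used_weeks), length(s_base$used_weeks))
  # toy instance with m = [3, 0]: two used weeks
  inst5 <- toy_instance(5)
  s <- solve_allocation_with_peaks(inst5, c(3, rep(0, inst5$n_weeks - 1L)))
  expect_equal(length(s$used_weeks), 2L)
  expect_true(all(s$weekly$total_quantity <=
                    inst5$capacity + s$weekly$extra_capacity + 1e-9))
})

test_that("flexible capacity model matches enumeration on toys", {
  elig <- matrix(1L, 3, 2, dimnames = list(c("a", "b", "c"), NULL))
  flex <- scheduling_instance(c(a = 4, b = 4, c = 4), elig, "flexible")
  expect_equal(solve_min_capacity_flexible(flex)$c_z, 8)
  s <- solve_allocation_flexible(flex, 8)
  expect_equal(length(s$used_weeks), 2L)
  # single population: c_z equals its quantity
  e1 <- matrix(1L, 1, 3, dimnames = list("p1", NULL))
  f1 <- scheduling_instance(c(p1 = 9), e1, "flexible")
  expect_equal(solve_min_capacity_flexible(f1)$c_z, 9)
  # disjoint singleton weeks: c_z = max quantity
  e3 <- diag(3); rownames(e3) <- c("a", "b", "c")
  f3 <- scheduling_instance(c(a = 2, b = 7, c = 4), e3, "flexible")
  expect_equal(solve_min_capacity_flexible(f3)$c_z, 7)
  # allocation at c_z coincides with the base model run at C = c_z
  fixed <- scheduling_instance(c(a = 4, b = 4, c = 4), elig, capacity = 8)
  expect_equal(length(solve_base_fixed(fixed)$used_weeks),
               length(solve_allocation_flexible(flex, 8)$used_weeks))
})

test_that("orchestration takes the right path and reports peak weeks", {
  plan_ok <- run_fixed_capacity(toy_instance(12))
  expect_equal(plan_ok$path, "single")
  expect_equal(plan_ok$z, 0)
  expect_equal(plan_ok$peak_weeks, integer(0))

  plan_tight <- run_fixed_capacity(toy_instance(5))
  expect_equal(plan_tight$path, "three_step")
  expect_equal(plan_tight$z, 3)
  expect_equal(sum(plan_tight$m), 3)
  expect_equal(plan_tight$peak_weeks, which(plan_tight$m > 0))
  expect_equal(length(plan_tight$schedule$used_weeks), 2L)

  flex <- scheduling_instance(
    c(a = 4, b = 4, c = 4),
    matrix(1L, 3, 2, dimnames = list(c("a", "b", "c"), NULL)), "flexible")
  plan_flex <- run_flexible_capacity(flex)
  expect_equal(plan_flex$proposed_capacity, 8)
  expect_equal(length(plan_flex$schedule$used_weeks), 2L)

  # empty eligibility row is rejected upfront, naming the population
  e <- matrix(0L, 2, 2, dimnames = list(c("good", "stuck"), NULL))
  e[1, 1] <- 1L
  inst <- scheduling_instance(c(good = 1, stuck = 1), e, capacity = 5)
  expect_error(run_fixed_capacity(inst), "stuck")
})

test_that("harvest week inverts to the earliest in-window planting day", {
  H <- tibble::tibble(population = "p1", planting_day = 100:106,
                      harvest_week = 20L)
  expect_equal(harvest_week_to_planting_day(H, "p1", 20), 100L)
  H1 <- tibble::tibble(population = "p2", planting_day = 42L,
                       harvest_week = 9L)
  expect_equal(harvest_week_to_planting_day(H1, "p2", 9), 42L)
  expect_error(harvest_week_to_planting_day(H, "p1", 21), "no planting day")
  # property: returned day always maps to the assigned week, in window
  set.seed(31)
  for (r in 1:10) {
    values <- pmax(rnorm(300, 9, 1), 0)
    pops <- tibble::tibble(population = c("a", "b"),
                           window_start_day = c(1, 30),
                           window_end_day = c(20, 45),
                           required_gdu = runif(2, 300, 700),
                           qty_scenario1 = c(3, 4))
    H2 <- build_harvest_week_matrix(pops, values)
    ok <- H2[!is.na(H2$harvest_week), ]
    for (pop in unique(ok$population)) {
      wks <- unique(ok$harvest_week[ok$population == pop])
      d <- harvest_week_to_planting_day(H2, rep(pop, length(wks)), wks)
      sub <- ok[ok$population == pop, ]
      expect_true(all(d %in% sub$planting_day))
      expect_equal(sub$harvest_week[match(d, sub$planting_day)], wks)
    }
  }
})

test_that("raising capacity never increases weeks; lowering never decreases z", {
  set.seed(77)
  for (r in 1:5) {
    sm <- random_small_instance()
    caps <- sort(sample(3:30, 3))
    prev_weeks <- Inf
    prev_z <- -Inf
    for (cap in caps) {
      inst <- scheduling_instance(sm$Q, sm$A, capacity = cap)
      s <- solve_base_fixed(inst)
      w <- if (is_infeasible(s)) Inf else length(s$used_weeks)
      expect_lte(w, prev_weeks)
      prev_weeks <- w
    }
    for (cap in rev(caps)) {  # decreasing capacity
      inst <- scheduling_instance(sm$Q, sm$A, capacity = cap)
      z <- solve_min_extra_capacity(inst)$z
      expect_gte(z + 1e-9, prev_z)
      prev_z <- z
    }
  }
})
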