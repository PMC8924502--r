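# Independent brute-force oracles for the scheduling models: enumerate every
# eligible assignment of populations to weeks and take the optimum directly
# from the definition. Tractable for <= 6 populations with few eligible
# weeks each; the MILP path never touches this code.

# list of eligible week vectors, one per population
eligible_sets <- function(A) {
  lapply(seq_len(nrow(A)), function(i) which(A[i, ] == 1L))
}

# iterate over all assignments, calling fn(weeks) with the chosen week per
# population; returns the minimum of fn over assignments (Inf if none valid)
enumerate_min <- function(A, fn) {
  sets <- eligible_sets(A)
  grid <- expand.grid(sets, KEEP.OUT.ATTRS = FALSE)
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    v <- fn(as.integer(grid[r, ]))
    if (!is.na(v) && v < best) best <- v
  }
  best
}

weekly_totals_of <- function(weeks, Q, n_weeks) {
  tot <- numeric(n_weeks)
  for (i in seq_along(weeks)) tot[weeks[i]] <- tot[weeks[i]] + Q[i]
  tot
}

# min #distinct weeks s.t. all weekly totals <= C; Inf when infeasible
oracle_base_weeks <- function(Q, A, C) {
  enumerate_min(A, function(w) {
    tot <- weekly_totals_of(w, Q, ncol(A))
    if (any(tot > C + 1e-9)) NA_real_ else length(unique(w))
  })
}

# minimal uniform extra capacity Z
oracle_min_z <- function(Q, A, C) {
  peak <- enumerate_min(A, function(w) max(weekly_totals_of(w, Q, ncol(A))))
  max(0, peak - C)
}

# minimal feasible capacity C_z (min over assignments of max weekly total)
oracle_min_cz <- function(Q, A) {
  enumerate_min(A, function(w) max(weekly_totals_of(w, Q, ncol(A))))
}

# minimal total overflow sum_j max(0, tot_j - C) with per-week overflow <= z
oracle_peak_total <- function(Q, A, C, z) {
  enumerate_min(A, function(w) {
    over <- pmax(weekly_totals_of(w, Q, ncol(A)) - C, 0)
    if (any(over > z + 1e-9)) NA_real_ else sum(over)
  })
}

# random small instance: n populations, wk weeks, 1..3 eligible weeks each
random_small_instance <- function(n = NULL, wk = NULL) {
  if (is.null(n)) n <- sample(2:6, 1)
  if (is.null(wk)) wk <- sample(3:8, 1)
  A <- matrix(0L, n, wk, dimnames = list(paste0("p", seq_len(n)), NULL))
  for (i in seq_len(n)) {
    A[i, sample.int(wk, sample(1:3, 1))] <- 1L
  }
  Q <- setNames(as.numeric(sample(1:12, n, replace = TRUE)), rownames(A))
  list(Q = Q, A = A)
}

# full invariant audit of a solved plan against its instance
expect_schedule_valid <- function(plan, inst, harvest_weeks = NULL,
                                  populations = NULL) {
  sched <- if (inherits(plan, "harvest_plan")) plan$schedule else plan
  asg <- sched$assignment
  Q <- inst$quantities
  # one week per population, eligibility respected
  expect_setequal(asg$population, names(Q))
  expect_equal(anyDuplicated(asg$population), 0L)
  idx <- cbind(match(asg$population, rownames(inst$eligibility)),
               asg$harvest_week)
  expect_true(all(inst$eligibility[idx] == 1L))
  # conservation and capacity
  expect_equal(sum(asg$quantity), sum(Q))
  weekly <- sched$weekly
  expect_equal(sum(weekly$total_quantity), sum(Q))
  if (!inst$flexible) {
    extra <- if (inherits(plan, "harvest_plan") && !is.null(plan$m)) plan$m
             else weekly$extra_capacity
    expect_true(all(weekly$total_quantity <= inst$capacity + extra + 1e-6))
    # lower bound on weeks used
    maxcap <- inst$capacity + max(extra)
    expect_gte(length(sched$used_weeks), ceiling(sum(Q) / maxcap - 1e-9))
  } else {
    cz <- plan$proposed_capacity
    expect_gte(cz, max(Q) - 1e-6)
    expect_true(all(weekly$total_quantity <= cz + 1e-6))
    expect_gte(length(sched$used_weeks), ceiling(sum(Q) / cz - 1e-9))
  }
  # planting days realise the assigned weeks from within the window
  if (!is.null(harvest_weeks) && "planting_day" %in% names(asg)) {
    for (r in seq_len(nrow(asg))) {
      sub <- harvest_weeks[harvest_weeks$population == asg$population[r], ]
      row <- sub[sub$planting_day == asg$planting_day[r], ]
      expect_equal(nrow(row), 1L)
      expect_equal(row$harvest_week, asg$harvest_week[r])
    }
    if (!is.null(populations)) {
      m <- match(asg$population, populations$population)
      expect_true(all(asg$planting_day >= populations$window_start_day[m] &
                        asg$planting_day <= populations$window_end_day[m]))
    }
  }
  invisible(TRUE)
}
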