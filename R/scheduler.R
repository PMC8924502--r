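# Scheduling models. All five are assignment MILPs over binary X[i, j]
# ("population i harvested in week j", allowed only where a[i, j] = 1):
#
#   base (fixed capacity):   min sum_j Y_j   s.t. sum_i Q_i X_ij <= C * Y_j
#   extra capacity:          min Z           s.t. sum_i Q_i X_ij <= C + Z
#   peak weeks:              min sum_j m_j   s.t. sum_i Q_i X_ij <= C + m_j,
#                                                 m_j <= Z
#   allocation with peaks:   min sum_j Y_j   s.t. sum_i Q_i X_ij <= (C+m_j)*Y_j
#   flexible capacity:       min C_z         s.t. sum_i Q_i X_ij <= C_z
#
# plus sum_j X_ij = 1 for every population in each model. X variables are
# only created where the eligibility matrix allows them, which keeps the
# models sparse.

#' Scheduling instance
#'
#' Bundles everything one MILP solve needs: the per-population harvest
#' quantities of the active scenario, the binary week-eligibility matrix,
#' and the weekly storage capacity (a number of ears, or `"flexible"` when
#' the capacity is itself the decision).
#'
#' @param quantities named numeric vector of harvest quantities (ears), one
#'   per population, all `> 0`; or a population tibble, in which case
#'   `scenario` selects the `qty_scenario<c>` column.
#' @param eligibility wide tibble from [build_eligibility_matrix()] or a
#'   binary matrix with population rownames.
#' @param capacity weekly storage capacity in ears, or `"flexible"`.
#' @param scenario scenario index used when `quantities` is a tibble.
#' @return a `scheduling_instance`.
#' @export
scheduling_instance <- function(quantities, eligibility, capacity,
                                scenario = 1L) {
  if (is.data.frame(quantities)) {
    quantities <- population_quantities(quantities, scenario)
  }
  if (is.null(names(quantities))) {
    names(quantities) <- paste0("p", seq_along(quantities))
  }
  if (any(!is.finite(quantities)) || any(quantities <= 0)) {
    abort("all `quantities` must be finite and > 0")
  }
  A <- if (is.data.frame(eligibility)) as_eligibility_matrix(eligibility)
       else {
         storage.mode(eligibility) <- "integer"
         eligibility
       }
  if (is.null(rownames(A))) rownames(A) <- names(quantities)
  if (!setequal(rownames(A), names(quantities))) {
    abort("eligibility rows and quantity names must cover the same populations")
  }
  A <- A[names(quantities), , drop = FALSE]
  if (!all(A %in% c(0L, 1L))) abort("eligibility must be binary")
  flexible <- identical(capacity, "flexible")
  if (!flexible && !(is_number(capacity) && capacity > 0)) {
    abort("`capacity` must be a positive number or \"flexible\"")
  }
  structure(
    list(quantities = quantities, eligibility = A,
         capacity = if (flexible) NA_real_ else as.numeric(capacity),
         flexible = flexible, n_weeks = ncol(A)),
    class = "scheduling_instance"
  )
}

#' @export
print.scheduling_instance <- function(x, ...) {
  cat("<scheduling_instance> ", length(x$quantities), " populations, ",
      x$n_weeks, " weeks, capacity ",
      if (x$flexible) "flexible" else format(x$capacity), "\n", sep = "")
  invisible(x)
}

check_schedulable <- function(inst) {
  zero <- rownames(inst$eligibility)[rowSums(inst$eligibility) == 0L]
  if (length(zero) > 0L) {
    abort(paste0("population(s) with no eligible harvest week: ",
                 paste(zero, collapse = ", "),
                 "; remove them upstream (see unschedulable_populations())"))
  }
  invisible(inst)
}

# Incremental sparse-model builder shared by the five formulations.
# `pairs` enumerates the allowed (population, week) variables.
model_skeleton <- function(inst) {
  idx <- which(inst$eligibility == 1L, arr.ind = TRUE)
  pairs <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  list(
    pairs = pairs,                                  # nx x 2: (i, j)
    nx = nrow(pairs),
    weeks = sort(unique(pairs[, 2L])),              # weeks that can be used
    npop = nrow(inst$eligibility),
    Q = unname(inst$quantities)
  )
}

# Constraint rows: one assignment equality per population, then one capacity
# row per usable week. Returns triplet lists plus row bookkeeping.
assignment_rows <- function(sk) {
  list(i = sk$pairs[, 1L], j = seq_len(sk$nx), v = rep(1, sk$nx),
       nrow = sk$npop)
}

week_load_triplets <- function(sk, row_of_week) {
  list(i = row_of_week[sk$pairs[, 2L]],
       j = seq_len(sk$nx),
       v = sk$Q[sk$pairs[, 1L]])
}

solve_model <- function(obj, trip, cl, cu, lb, ub, integrality, time_limit) {
  hp_milp(obj,
          A = list(i = unlist(lapply(trip, `[[`, "i")),
                   j = unlist(lapply(trip, `[[`, "j")),
                   v = unlist(lapply(trip, `[[`, "v")),
                   nrow = length(cl), ncol = length(obj)),
          cl = cl, cu = cu, lb = lb, ub = ub, integrality = integrality,
          time_limit = time_limit)
}

# Turn a solved x-vector into a schedule object.
schedule_from_solution <- function(inst, sk, xvals, extra_capacity = NULL,
                                   objective = NULL, status = "OPTIMAL") {
  chosen <- sk$pairs[xvals[seq_len(sk$nx)] > 0.5, , drop = FALSE]
  chosen <- chosen[order(chosen[, 1L]), , drop = FALSE]
  pops <- rownames(inst$eligibility)
  assignment <- tibble(
    population = pops[chosen[, 1L]],
    harvest_week = as.integer(chosen[, 2L]),
    quantity = unname(inst$quantities[chosen[, 1L]])
  )
  nw <- inst$n_weeks
  totals <- vapply(seq_len(nw), function(j) {
    sum(assignment$quantity[assignment$harvest_week == j])
  }, numeric(1))
  extra <- if (is.null(extra_capacity)) rep(0, nw) else extra_capacity
  weekly <- tibble(
    week = seq_len(nw),
    total_quantity = totals,
    capacity = if (inst$flexible) NA_real_ else inst$capacity,
    extra_capacity = extra,
    used = totals > 0
  )
  structure(
    list(assignment = assignment, weekly = weekly,
         used_weeks = which(totals > 0), objective = objective,
         status = status, capacity = inst$capacity,
         flexible = inst$flexible, n_weeks = nw),
    class = "harvest_schedule"
  )
}

#' @export
print.harvest_schedule <- function(x, ...) {
  cat("<harvest_schedule> ", nrow(x$assignment), " populations over ",
      length(x$used_weeks), " week(s); status ", x$status, "\n", sep = "")
  if (length(x$used_weeks) > 0L) {
    cat("  weeks: ", paste(x$used_weeks, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Did a solve come back infeasible?
#'
#' @param x result of a scheduling solve.
#' @return `TRUE` when `x` carries status `"INFEASIBLE"`.
#' @export
is_infeasible <- function(x) {
  inherits(x, "hp_infeasible") ||
    (is.list(x) && identical(x$status, "INFEASIBLE"))
}

infeasible_result <- function(message = "") {
  structure(list(status = "INFEASIBLE", message = message),
            class = "hp_infeasible")
}

#' @export
print.hp_infeasible <- function(x, ...) {
  cat("<infeasible> no schedule satisfies the capacity constraints\n")
  invisible(x)
}

solver_failed <- function(res, context) {
  abort(sprintf("MILP solve failed in %s: status %s (%s)",
                context, res$status, res$message))
}

#' Minimum-weeks schedule under a fixed weekly capacity
#'
#' Solves the base fixed-capacity model: assign every population to one
#' eligible harvest week so that each week's total stays within the storage
#' capacity, using as few distinct weeks as possible. Infeasibility (the
#' capacity cannot absorb the quantities under any eligible assignment) is
#' returned as a value, not raised.
#'
#' @param inst a [scheduling_instance()] with fixed capacity.
#' @param time_limit solver time limit in seconds.
#' @return a `harvest_schedule`, or an infeasibility marker
#'   (test with [is_infeasible()]).
#' @export
solve_base_fixed <- function(inst,
                             time_limit = getOption("harvestplan.solver_time_limit", 600)) {
  stopifnot(inherits(inst, "scheduling_instance"))
  if (inst$flexible) abort("solve_base_fixed() needs a fixed capacity")
  check_schedulable(inst)
  solve_allocation(inst, cap_of_week = rep(inst$capacity, inst$n_weeks),
                   time_limit = time_limit, context = "solve_base_fixed",
                   infeasible_ok = TRUE)
}

# Shared allocation solve: min sum Y_j with per-week cap cap_of_week[j]*Y_j.
solve_allocation <- function(inst, cap_of_week, time_limit, context,
                             infeasible_ok = FALSE, extra_capacity = NULL) {
  sk <- model_skeleton(inst)
  nW <- length(sk$weeks)
  nv <- sk$nx + nW                       # x pairs then Y per usable week
  row_of_week <- integer(inst$n_weeks)
  row_of_week[sk$weeks] <- sk$npop + seq_len(nW)
  trip <- list(
    assignment_rows(sk),
    week_load_triplets(sk, row_of_week),
    list(i = sk$npop + seq_len(nW), j = sk$nx + seq_len(nW),
         v = -cap_of_week[sk$weeks])
  )
  obj <- c(rep(0, sk$nx), rep(1, nW))
  cl <- c(rep(1, sk$npop), rep(-Inf, nW))
  cu <- c(rep(1, sk$npop), rep(0, nW))
  res <- solve_model(obj, trip, cl, cu,
                     lb = rep(0, nv), ub = rep(1, nv),
                     integrality = rep(1L, nv), time_limit = time_limit)
  if (res$status == "infeasible") {
    if (infeasible_ok) return(infeasible_result(res$message))
    abort(sprintf("internal consistency error: %s came back infeasible",
                  context))
  }
  if (res$status != "optimal") solver_failed(res, context)
  schedule_from_solution(inst, sk, res$x, extra_capacity = extra_capacity,
                         objective = round(res$objective))
}

#' Minimum additional site capacity (fixed-capacity step 1)
#'
#' When the base model is infeasible, finds the smallest uniform capacity
#' increase `Z >= 0` such that some eligible assignment keeps every week's
#' total within `C + Z`.
#'
#' @inheritParams solve_base_fixed
#' @return list with `z` (ears) and the solver report.
#' @export
solve_min_extra_capacity <- function(inst,
                                     time_limit = getOption("harvestplan.solver_time_limit", 600)) {
  stopifnot(inherits(inst, "scheduling_instance"))
  if (inst$flexible) abort("solve_min_extra_capacity() needs a fixed capacity")
  check_schedulable(inst)
  sk <- model_skeleton(inst)
  nW <- length(sk$weeks)
  nv <- sk$nx + 1L                        # x pairs then Z
  row_of_week <- integer(inst$n_weeks)
  row_of_week[sk$weeks] <- sk$npop + seq_len(nW)
  trip <- list(
    assignment_rows(sk),
    week_load_triplets(sk, row_of_week),
    list(i = sk$npop + seq_len(nW), j = rep(nv, nW), v = rep(-1, nW))
  )
  obj <- c(rep(0, sk$nx), 1)
  cl <- c(rep(1, sk$npop), rep(-Inf, nW))
  cu <- c(rep(1, sk$npop), rep(inst$capacity, nW))
  res <- solve_model(obj, trip, cl, cu,
                     lb = rep(0, nv), ub = c(rep(1, sk$nx), Inf),
                     integrality = c(rep(1L, sk$nx), 0L),
                     time_limit = time_limit)
  if (res$status != "optimal") solver_failed(res, "solve_min_extra_capacity")
  list(z = max(0, res$objective), status = res$status)
}

#' Per-week additional capacity (fixed-capacity step 2)
#'
#' Given the minimal uniform extra capacity `z`, finds per-week additions
#' `m_j` (each at most `z`) of minimal total, so peak weeks — the weeks that
#' genuinely need capacity beyond `C` — are identified.
#'
#' @inheritParams solve_base_fixed
#' @param z minimal additional capacity from [solve_min_extra_capacity()].
#' @return list with `m` (numeric, one entry per week of the season),
#'   `peak_weeks` (weeks where `m > 0`), and the witnessing schedule.
#' @export
solve_peak_weeks <- function(inst, z,
                             time_limit = getOption("harvestplan.solver_time_limit", 600)) {
  stopifnot(inherits(inst, "scheduling_instance"), is_number(z), z >= 0)
  if (inst$flexible) abort("solve_peak_weeks() needs a fixed capacity")
  check_schedulable(inst)
  sk <- model_skeleton(inst)
  nW <- length(sk$weeks)
  nv <- sk$nx + nW                        # x pairs then m per usable week
  row_of_week <- integer(inst$n_weeks)
  row_of_week[sk$weeks] <- sk$npop + seq_len(nW)
  trip <- list(
    assignment_rows(sk),
    week_load_triplets(sk, row_of_week),
    list(i = sk$npop + seq_len(nW), j = sk$nx + seq_len(nW), v = rep(-1, nW))
  )
  obj <- c(rep(0, sk$nx), rep(1, nW))
  cl <- c(rep(1, sk$npop), rep(-Inf, nW))
  cu <- c(rep(1, sk$npop), rep(inst$capacity, nW))
  zcap <- z * (1 + 1e-9) + 1e-9           # guard against solver round-off in z
  res <- solve_model(obj, trip, cl, cu,
                     lb = rep(0, nv),
                     ub = c(rep(1, sk$nx), rep(zcap, nW)),
                     integrality = c(rep(1L, sk$nx), rep(0L, nW)),
                     time_limit = time_limit)
  if (res$status != "optimal") solver_failed(res, "solve_peak_weeks")
  m <- rep(0, inst$n_weeks)
  m[sk$weeks] <- pmax(0, res$x[sk$nx + seq_len(nW)])
  m[m < 1e-9] <- 0
  witness <- schedule_from_solution(inst, sk, res$x, extra_capacity = m,
                                    objective = sum(m))
  list(m = m, peak_weeks = which(m > 0), total = sum(m), witness = witness)
}

#' Minimum-weeks schedule with peak-week capacity (fixed-capacity step 3)
#'
#' Re-runs the minimum-weeks allocation with the per-week capacities
#' `C + m_j` fixed (as constants, keeping the model linear).
#'
#' @inheritParams solve_base_fixed
#' @param m per-week additional capacity from [solve_peak_weeks()].
#' @return a `harvest_schedule` whose `weekly$extra_capacity` records `m`.
#' @export
solve_allocation_with_peaks <- function(inst, m,
                                        time_limit = getOption("harvestplan.solver_time_limit", 600)) {
  stopifnot(inherits(inst, "scheduling_instance"),
            is.numeric(m), length(m) == inst$n_weeks, all(m >= 0))
  if (inst$flexible) abort("solve_allocation_with_peaks() needs a fixed capacity")
  check_schedulable(inst)
  solve_allocation(inst, cap_of_week = inst$capacity + m,
                   time_limit = time_limit,
                   context = "solve_allocation_with_peaks",
                   infeasible_ok = FALSE, extra_capacity = m)
}

#' Minimum storage capacity (flexible-capacity step 1)
#'
#' Finds the smallest capacity `C_z` such that some eligible assignment
#' keeps every weekly total within `C_z`. The number of harvesting weeks is
#' not considered at this step.
#'
#' @param inst a [scheduling_instance()] with `capacity = "flexible"`.
#' @param time_limit solver time limit in seconds.
#' @return list with `c_z` (ears) and the solver report.
#' @export
solve_min_capacity_flexible <- function(inst,
                                        time_limit = getOption("harvestplan.solver_time_limit", 600)) {
  stopifnot(inherits(inst, "scheduling_instance"))
  check_schedulable(inst)
  sk <- model_skeleton(inst)
  nW <- length(sk$weeks)
  nv <- sk$nx + 1L                        # x pairs then C_z
  row_of_week <- integer(inst$n_weeks)
  row_of_week[sk$weeks] <- sk$npop + seq_len(nW)
  trip <- list(
    assignment_rows(sk),
    week_load_triplets(sk, row_of_week),
    list(i = sk$npop + seq_len(nW), j = rep(nv, nW), v = rep(-1, nW))
  )
  obj <- c(rep(0, sk$nx), 1)
  cl <- c(rep(1, sk$npop), rep(-Inf, nW))
  cu <- c(rep(1, sk$npop), rep(0, nW))
  res <- solve_model(obj, trip, cl, cu,
                     lb = rep(0, nv), ub = c(rep(1, sk$nx), Inf),
                     integrality = c(rep(1L, sk$nx), 0L),
                     time_limit = time_limit)
  if (res$status != "optimal") solver_failed(res, "solve_min_capacity_flexible")
  list(c_z = res$objective, status = res$status)
}

#' Minimum-weeks schedule at a proposed capacity (flexible-capacity step 2)
#'
#' Identical in structure to the base fixed-capacity model, with the
#' capacity set to the `C_z` proposed by [solve_min_capacity_flexible()].
#'
#' @inheritParams solve_min_capacity_flexible
#' @param c_z capacity from step 1 (ears).
#' @return a `harvest_schedule`.
#' @export
solve_allocation_flexible <- function(inst, c_z,
                                      time_limit = getOption("harvestplan.solver_time_limit", 600)) {
  stopifnot(inherits(inst, "scheduling_instance"), is_number(c_z), c_z > 0)
  check_schedulable(inst)
  fixed <- inst
  fixed$flexible <- FALSE
  # tiny relative slack absorbs solver round-off in a continuous c_z
  fixed$capacity <- c_z * (1 + 1e-9) + 1e-9
  out <- solve_allocation(fixed, cap_of_week = rep(fixed$capacity, inst$n_weeks),
                          time_limit = time_limit,
                          context = "solve_allocation_flexible",
                          infeasible_ok = FALSE)
  out$capacity <- c_z
  out$weekly$capacity <- c_z
  out
}

#' Planting day realising a chosen harvest week
#'
#' Inverts the harvest-week matrix: the earliest in-window planting day of
#' the population that matures in the assigned week.
#'
#' @param harvest_weeks tibble from [build_harvest_week_matrix()].
#' @param population population id(s).
#' @param week assigned harvest week(s), recycled against `population`.
#' @return integer planting day(s)-of-season.
#' @export
harvest_week_to_planting_day <- function(harvest_weeks, population, week) {
  n <- max(length(population), length(week))
  population <- rep_len(as.character(population), n)
  week <- rep_len(as.integer(week), n)
  vapply(seq_len(n), function(t) {
    days <- harvest_weeks$planting_day[
      harvest_weeks$population == population[t] &
        !is.na(harvest_weeks$harvest_week) &
        harvest_weeks$harvest_week == week[t]]
    if (length(days) == 0L) {
      abort(sprintf(
        "internal consistency error: population '%s' has no planting day maturing in week %d",
        population[t], week[t]))
    }
    min(days)
  }, integer(1))
}

attach_planting_days <- function(schedule, harvest_weeks) {
  if (is.null(harvest_weeks)) return(schedule)
  schedule$assignment$planting_day <- harvest_week_to_planting_day(
    harvest_weeks, schedule$assignment$population,
    schedule$assignment$harvest_week)
  schedule
}

#' Fixed-capacity planting algorithm
#'
#' First attempts the base minimum-weeks model. If the given capacity is
#' infeasible, runs the three-step sequence: (1) minimum uniform extra
#' capacity `Z`; (2) per-week extra capacity `m_j <= Z` of minimal total,
#' identifying the peak weeks; (3) minimum-weeks allocation under the
#' relaxed per-week caps. Planting days are attached when the harvest-week
#' matrix is supplied.
#'
#' @param inst a [scheduling_instance()] with fixed capacity.
#' @param harvest_weeks optional tibble from [build_harvest_week_matrix()],
#'   used to back out planting days.
#' @param time_limit solver time limit in seconds (per solve).
#' @return a `harvest_plan`: list with `schedule`, `path`
#'   (`"single"` or `"three_step"`), `z`, `m`, `peak_weeks`.
#' @export
#' @examples
#' \dontrun{
#' elig <- matrix(1L, 3, 2, dimnames = list(c("a", "b", "c"), NULL))
#' inst <- scheduling_instance(c(a = 4, b = 4, c = 4), elig, capacity = 5)
#' plan <- run_fixed_capacity(inst)
#' plan$peak_weeks
#' }
run_fixed_capacity <- function(inst, harvest_weeks = NULL,
                               time_limit = getOption("harvestplan.solver_time_limit", 600)) {
  stopifnot(inherits(inst, "scheduling_instance"))
  if (inst$flexible) abort("run_fixed_capacity() needs a fixed capacity")
  check_schedulable(inst)
  base <- solve_base_fixed(inst, time_limit = time_limit)
  if (!is_infeasible(base)) {
    plan <- list(schedule = attach_planting_days(base, harvest_weeks),
                 path = "single", z = 0, m = rep(0, inst$n_weeks),
                 peak_weeks = integer(0))
    return(structure(plan, class = "harvest_plan"))
  }
  step1 <- solve_min_extra_capacity(inst, time_limit = time_limit)
  step2 <- solve_peak_weeks(inst, step1$z, time_limit = time_limit)
  sched <- solve_allocation_with_peaks(inst, step2$m, time_limit = time_limit)
  plan <- list(schedule = attach_planting_days(sched, harvest_weeks),
               path = "three_step", z = step1$z, m = step2$m,
               peak_weeks = step2$peak_weeks)
  structure(plan, class = "harvest_plan")
}

#' Flexible-capacity planting algorithm
#'
#' Two steps: propose the minimum storage capacity `C_z`, then schedule for
#' a minimum number of harvesting weeks at that capacity.
#'
#' @inheritParams run_fixed_capacity
#' @return a `harvest_plan` with `schedule`, `path = "two_step"`, and
#'   `proposed_capacity` (`C_z`, ears).
#' @export
run_flexible_capacity <- function(inst, harvest_weeks = NULL,
                                  time_limit = getOption("harvestplan.solver_time_limit", 600)) {
  stopifnot(inherits(inst, "scheduling_instance"))
  if (!inst$flexible) abort("run_flexible_capacity() needs capacity = \"flexible\"")
  check_schedulable(inst)
  step1 <- solve_min_capacity_flexible(inst, time_limit = time_limit)
  sched <- solve_allocation_flexible(inst, step1$c_z, time_limit = time_limit)
  plan <- list(schedule = attach_planting_days(sched, harvest_weeks),
               path = "two_step", proposed_capacity = step1$c_z)
  structure(plan, class = "harvest_plan")
}

#' @export
print.harvest_plan <- function(x, ...) {
  cat("<harvest_plan> path: ", x$path, "\n", sep = "")
  if (!is.null(x$proposed_capacity)) {
    cat("  proposed capacity: ", format(x$proposed_capacity), " ears\n",
        sep = "")
  }
  if (length(x$peak_weeks %||% integer(0)) > 0L) {
    cat("  peak weeks (m_j > 0): ", paste(x$peak_weeks, collapse = ", "),
        "\n", sep = "")
  }
  print(x$schedule)
  invisible(x)
}
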