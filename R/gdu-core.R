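# Agronomic core: cumulative growing degree units (GDUs), the per-population
# harvest-week matrix H[i, d], and the binary week-eligibility matrix a[i, j]
# that bridges planting windows to the scheduling models.

#' Season calendar
#'
#' Weeks are 7-day bins of the day-of-season axis: week `j` covers days
#' `7(j-1)+1 ... 7j`. Days are 1-based.
#'
#' @param n_weeks number of harvest weeks in the season (default 70).
#' @param days_per_week days per week, 7.
#' @return a `season_calendar` object.
#' @export
#' @examples
#' cal <- season_calendar()
#' day_to_week(c(1, 7, 8), cal)
season_calendar <- function(n_weeks = 70L, days_per_week = 7L) {
  stopifnot(is_count(n_weeks), is_count(days_per_week))
  structure(
    list(n_weeks = as.integer(n_weeks),
         days_per_week = as.integer(days_per_week),
         season_days = as.integer(n_weeks) * as.integer(days_per_week)),
    class = "season_calendar"
  )
}

#' @export
print.season_calendar <- function(x, ...) {
  cat("<season_calendar> ", x$n_weeks, " weeks x ", x$days_per_week,
      " days = ", x$season_days, " days\n", sep = "")
  invisible(x)
}

#' Maturity configuration
#'
#' Caps the days a population may take to reach its required GDUs (harvest
#' past the cap is treated as unattainable for that planting day) and
#' optionally reduces the GDU requirement for late plantings, reflecting the
#' lower heat requirement of corn planted into a cooling season.
#'
#' @param max_harvest_days hard cap on days from planting to maturity
#'   (default 120, the agronomic upper bound for corn).
#' @param adjustment `NULL` (default), or [maturity_adjustment()].
#' @return a `maturity_config` object.
#' @export
maturity_config <- function(max_harvest_days = 120L, adjustment = NULL) {
  stopifnot(is_count(max_harvest_days))
  if (!is.null(adjustment) && !inherits(adjustment, "maturity_adjustment")) {
    abort("`adjustment` must be NULL or maturity_adjustment()")
  }
  structure(list(max_harvest_days = as.integer(max_harvest_days),
                 adjustment = adjustment),
            class = "maturity_config")
}

#' Late-planting GDU reduction
#'
#' Populations planted on or after `cutoff_day` have their required GDUs
#' reduced by a flat `gdu_reduction` (clamped at zero). The 110 degree-day
#' default reflects the average reduction in heat requirement reported for
#' corn planted in early June versus early May in the US corn belt.
#'
#' @param cutoff_day first day-of-season the reduction applies to.
#' @param gdu_reduction degree-days subtracted from the requirement.
#' @export
maturity_adjustment <- function(cutoff_day, gdu_reduction = 110) {
  stopifnot(is_count(cutoff_day), is_number(gdu_reduction), gdu_reduction >= 0)
  structure(list(cutoff_day = as.integer(cutoff_day),
                 gdu_reduction = as.numeric(gdu_reduction)),
            class = "maturity_adjustment")
}

#' Daily GDU series
#'
#' One row per consecutive day for one site. `day` is the 1-based day index
#' used throughout scheduling; `date` anchors it to the calendar.
#'
#' @param values numeric vector of daily GDUs (degree-days), finite.
#' @param site site identifier.
#' @param start_date calendar date of day 1.
#' @return tibble with columns `site`, `date`, `day`, `gdu`.
#' @export
#' @examples
#' gdu_series(c(9.5, 10.1, 8.7), site = "site0")
gdu_series <- function(values, site = "site0",
                       start_date = as.Date("2011-01-01")) {
  values <- as.numeric(values)
  if (length(values) < 1L || !all(is.finite(values))) {
    abort("GDU `values` must be a non-empty vector of finite numbers")
  }
  tibble(
    site = as.character(site),
    date = as.Date(start_date) + seq_along(values) - 1L,
    day = seq_along(values),
    gdu = values
  )
}

# Pull the ordered daily GDU vector out of a series tibble (or pass a bare
# numeric vector through), checking contiguity.
gdu_values <- function(series) {
  if (is.numeric(series)) return(as.numeric(series))
  if (!is.data.frame(series) || !all(c("gdu") %in% names(series))) {
    abort("`series` must be a numeric vector or a tibble with a `gdu` column")
  }
  if ("date" %in% names(series) && nrow(series) > 1L) {
    gaps <- diff(as.integer(as.Date(series$date)))
    if (any(gaps != 1L)) {
      abort(sprintf("GDU series has a date gap after row %d",
                    which(gaps != 1L)[1L]))
    }
  }
  as.numeric(series$gdu)
}

#' Map a day-of-season to its harvest week
#'
#' @param day integer day(s) of season, 1-based.
#' @param calendar a [season_calendar()].
#' @return integer week `ceiling(day / days_per_week)`, or `NA` for days
#'   past the end of the season.
#' @export
day_to_week <- function(day, calendar = season_calendar()) {
  if (any(!is.finite(day)) || any(day < 1)) {
    abort("`day` must be >= 1")
  }
  wk <- as.integer(ceiling(day / calendar$days_per_week))
  wk[wk > calendar$n_weeks] <- NA_integer_
  wk
}

#' Days to accumulate a GDU threshold
#'
#' Counts forward from `start_day` (the planting day, whose GDUs count) and
#' returns the smallest number of days `k` such that the GDUs of days
#' `start_day ... start_day + k - 1` sum to at least `threshold`. `k = 1`
#' means the crop matures on the planting day. Returns `NA` if the threshold
#' is not reached within `max_days` days or before the series ends.
#'
#' @param series a [gdu_series()] tibble or numeric GDU vector.
#' @param start_day 1-based planting day within the series.
#' @param threshold required cumulative GDUs (degree-days), `>= 0`.
#' @param max_days cap on the count (default 120).
#' @return integer days-to-maturity, or `NA`.
#' @export
#' @examples
#' accumulate_to_threshold(rep(10, 400), start_day = 1, threshold = 105)
accumulate_to_threshold <- function(series, start_day, threshold,
                                    max_days = 120L) {
  values <- gdu_values(series)
  stopifnot(is_number(threshold), threshold >= 0, is_count(max_days))
  if (!is_count(start_day) || start_day > length(values)) {
    abort(sprintf("`start_day` %s is outside the series (length %d)",
                  format(start_day), length(values)))
  }
  last <- min(start_day + max_days - 1L, length(values))
  acc <- cumsum(values[start_day:last])
  k <- which(acc >= threshold)[1L]
  if (is.na(k)) NA_integer_ else as.integer(k)
}

#' Effective required GDUs for a planting day
#'
#' Applies the optional late-planting reduction of a [maturity_config()]:
#' plantings on or after the cutoff day need `gdu_reduction` fewer
#' degree-days, never going below zero.
#'
#' @param required_gdu base GDU requirement(s).
#' @param planting_day day(s) of season; recycled against `required_gdu`.
#' @param config a [maturity_config()].
#' @return numeric effective requirement(s).
#' @export
effective_required_gdu <- function(required_gdu, planting_day,
                                   config = maturity_config()) {
  n <- max(length(required_gdu), length(planting_day))
  required_gdu <- rep_len(as.numeric(required_gdu), n)
  planting_day <- rep_len(planting_day, n)
  adj <- config$adjustment
  if (is.null(adj)) return(required_gdu)
  out <- ifelse(planting_day >= adj$cutoff_day,
                pmax(required_gdu - adj$gdu_reduction, 0),
                required_gdu)
  as.numeric(out)
}

check_population_table <- function(populations, calendar) {
  req <- c("population", "window_start_day", "window_end_day", "required_gdu")
  missing <- setdiff(req, names(populations))
  if (length(missing) > 0L) {
    abort(paste0("population table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad <- which(populations$window_end_day < populations$window_start_day)
  if (length(bad) > 0L) {
    abort(sprintf(
      "population '%s' (row %d): window_end_day < window_start_day",
      populations$population[bad[1L]], bad[1L]))
  }
  bad <- which(populations$window_start_day < 1 |
                 populations$window_end_day > calendar$season_days)
  if (length(bad) > 0L) {
    abort(sprintf(
      "population '%s' (row %d): planting window outside days 1..%d",
      populations$population[bad[1L]], bad[1L], calendar$season_days))
  }
  bad <- which(!is.finite(populations$required_gdu) |
                 populations$required_gdu <= 0)
  if (length(bad) > 0L) {
    abort(sprintf("population '%s' (row %d): required_gdu must be > 0",
                  populations$population[bad[1L]], bad[1L]))
  }
  qty_cols <- grep("^qty_", names(populations), value = TRUE)
  for (qc in qty_cols) {
    bad <- which(!is.finite(populations[[qc]]) | populations[[qc]] <= 0)
    if (length(bad) > 0L) {
      abort(sprintf("population '%s' (row %d): %s must be > 0",
                    populations$population[bad[1L]], bad[1L], qc))
    }
  }
  invisible(populations)
}

#' Harvest-week matrix H
#'
#' For every population and every day in its planting window, computes the
#' harvest week reached by accumulating the (effective) required GDUs from
#' that planting day. `NA` marks planting days whose crop would not mature
#' within the maturity cap, before the series ends, or within the season.
#'
#' @param populations tibble with columns `population`, `window_start_day`,
#'   `window_end_day`, `required_gdu` (and `qty_*` scenario columns).
#' @param series [gdu_series()] tibble or numeric vector of daily GDUs
#'   (observed or forecast) covering every window day plus the maturity cap.
#' @param calendar a [season_calendar()].
#' @param maturity a [maturity_config()].
#' @return tibble with columns `population`, `planting_day`, `harvest_week`.
#' @export
#' @examples
#' pops <- tibble::tibble(population = "p1", window_start_day = 1,
#'                        window_end_day = 3, required_gdu = 100,
#'                        qty_scenario1 = 10)
#' build_harvest_week_matrix(pops, rep(10, 200))
build_harvest_week_matrix <- function(populations, series,
                                      calendar = season_calendar(),
                                      maturity = maturity_config()) {
  check_population_table(populations, calendar)
  values <- gdu_values(series)
  need <- max(populations$window_end_day) + maturity$max_harvest_days - 1L
  if (length(values) < need) {
    abort(sprintf(
      "GDU series too short: %d days given, %d needed (latest window day %d + maturity cap %d - 1)",
      length(values), need, max(populations$window_end_day),
      maturity$max_harvest_days))
  }
  purrr::pmap_dfr(
    list(populations$population, populations$window_start_day,
         populations$window_end_day, populations$required_gdu),
    function(pop, d0, d1, req) {
      days <- seq.int(d0, d1)
      thr <- effective_required_gdu(req, days, maturity)
      k <- vapply(seq_along(days), function(t) {
        accumulate_to_threshold(values, days[t], thr[t],
                                maturity$max_harvest_days)
      }, integer(1))
      wk <- rep(NA_integer_, length(days))
      ok <- !is.na(k)
      if (any(ok)) wk[ok] <- day_to_week(days[ok] + k[ok] - 1L, calendar)
      tibble(population = as.character(pop), planting_day = as.integer(days),
             harvest_week = wk)
    }
  )
}

#' Week-eligibility matrix a_ij
#'
#' Collapses the harvest-week matrix into the binary matrix used by the
#' scheduling models: `a[i, j] = 1` iff some in-window planting day of
#' population `i` matures in week `j`. Populations with an all-zero row
#' cannot be scheduled; they are reported with a message, not an error, so
#' callers can surface them.
#'
#' @param harvest_weeks output of [build_harvest_week_matrix()].
#' @param calendar a [season_calendar()].
#' @return wide tibble, one row per population: `population`,
#'   `week_1 ... week_<n_weeks>` with 0/1 entries.
#' @export
build_eligibility_matrix <- function(harvest_weeks,
                                     calendar = season_calendar()) {
  pops <- unique(harvest_weeks$population)
  nw <- calendar$n_weeks
  A <- matrix(0L, nrow = length(pops), ncol = nw,
              dimnames = list(pops, paste0("week_", seq_len(nw))))
  seen <- dplyr::distinct(
    dplyr::filter(harvest_weeks, !is.na(.data$harvest_week)),
    .data$population, .data$harvest_week
  )
  A[cbind(match(seen$population, pops), seen$harvest_week)] <- 1L
  zero <- pops[rowSums(A) == 0L]
  if (length(zero) > 0L) {
    message("unschedulable population(s), all-zero eligibility row: ",
            paste(zero, collapse = ", "))
  }
  dplyr::bind_cols(tibble(population = pops), as_tibble(A))
}

#' Eligibility tibble to binary matrix
#'
#' @param eligibility wide tibble from [build_eligibility_matrix()].
#' @return integer matrix, populations in rownames, one column per week.
#' @export
as_eligibility_matrix <- function(eligibility) {
  wk <- grep("^week_", names(eligibility), value = TRUE)
  A <- as.matrix(eligibility[, wk, drop = FALSE])
  storage.mode(A) <- "integer"
  rownames(A) <- as.character(eligibility$population)
  A
}

#' Populations with no eligible harvest week
#'
#' @param eligibility wide tibble from [build_eligibility_matrix()].
#' @return character vector of population ids with all-zero rows.
#' @export
unschedulable_populations <- function(eligibility) {
  A <- as_eligibility_matrix(eligibility)
  rownames(A)[rowSums(A) == 0L]
}

#' Per-population harvest quantities for a scenario
#'
#' @param populations population tibble with `qty_scenario<c>` columns.
#' @param scenario scenario index `c` (selects column `qty_scenario<c>`).
#' @return named numeric vector of quantities (ears), names = population ids.
#' @export
population_quantities <- function(populations, scenario = 1L) {
  col <- paste0("qty_scenario", scenario)
  if (!col %in% names(populations)) {
    abort(sprintf("no column `%s` in the population table", col))
  }
  setNames(as.numeric(populations[[col]]),
           as.character(populations$population))
}
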