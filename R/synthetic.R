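# Seeded synthetic-data generators. They emulate the statistical structure
# of the two-site seed-corn case: daily GDUs as a clamped sinusoid plus
# Gaussian noise in the 4-16 degree-day range (site 0 cooler and steadier,
# mostly below 10; site 1 warmer and noisier, mainly above 10), and
# population tables whose GDU requirements put typical maturity at 95-120
# days.

#' Site GDU profile
#'
#' Parameters of the daily-GDU generator:
#' `gdu(t) = clamp0(mean + amplitude * sin(2*pi*t/period + phase) + N(0, sd))`.
#'
#' @param mean_gdu mean daily GDU (degree-days).
#' @param seasonal_amplitude sinusoid amplitude, `< mean_gdu` so values
#'   stay away from the clamp.
#' @param noise_sd Gaussian noise standard deviation.
#' @param period season period in days (365).
#' @param n_years series length in years (365-day years).
#' @param phase sinusoid phase; the default puts the warm peak mid-season.
#' @param seed integer seed.
#' @return a `site_profile` object.
#' @export
site_profile <- function(mean_gdu, seasonal_amplitude, noise_sd,
                         period = 365L, n_years = 10L,
                         phase = -pi / 2, seed = 1L) {
  stopifnot(is_number(mean_gdu), is_number(seasonal_amplitude),
            is_number(noise_sd), noise_sd >= 0,
            is_count(period), is_count(n_years))
  if (seasonal_amplitude >= mean_gdu) {
    abort("`seasonal_amplitude` must be smaller than `mean_gdu`")
  }
  structure(list(mean_gdu = mean_gdu,
                 seasonal_amplitude = seasonal_amplitude,
                 noise_sd = noise_sd, period = as.integer(period),
                 n_years = as.integer(n_years), phase = phase,
                 seed = as.integer(seed)),
            class = "site_profile")
}

#' Default site profiles
#'
#' Two canned profiles reproducing the qualitative contrast of the
#' case-study sites: site 0 cool and low-variance (daily GDUs mostly below
#' 10 degree-days), site 1 warmer with higher variance (mainly above 10),
#' both within roughly 4-16 degree-days.
#'
#' @param n_years series length in years.
#' @param seed integer seed.
#' @name site_profiles
#' @export
site_profile_site0 <- function(n_years = 10L, seed = 1L) {
  site_profile(mean_gdu = 7.5, seasonal_amplitude = 2.0, noise_sd = 0.6,
               n_years = n_years, seed = seed)
}

#' @rdname site_profiles
#' @export
site_profile_site1 <- function(n_years = 10L, seed = 2L) {
  site_profile(mean_gdu = 11.5, seasonal_amplitude = 2.5, noise_sd = 1.0,
               n_years = n_years, seed = seed)
}

#' Generate a daily GDU series
#'
#' @param profile a [site_profile()].
#' @param site site identifier stored in the series.
#' @param start_date calendar date of day 1.
#' @return a [gdu_series()] tibble of `n_years * 365` days.
#' @export
#' @examples
#' s <- gen_gdu_series(site_profile_site0(n_years = 2))
#' range(s$gdu)
gen_gdu_series <- function(profile, site = "site0",
                           start_date = as.Date("2011-01-01")) {
  stopifnot(inherits(profile, "site_profile"))
  n <- profile$n_years * 365L
  t <- seq_len(n)
  values <- with_seed(profile$seed, {
    raw <- profile$mean_gdu +
      profile$seasonal_amplitude *
        sin(2 * pi * t / profile$period + profile$phase) +
      rnorm(n, sd = profile$noise_sd)
    pmax(raw, 0)
  })
  gdu_series(values, site = site, start_date = start_date)
}

#' Population generation profile
#'
#' Ranges for the uniform draws of the population table. Required GDUs are
#' not drawn directly: a target maturity time of 95-120 days is drawn and
#' converted through the series' mean daily GDU, matching how long corn
#' takes to reach maturity.
#'
#' @param n_populations number of populations.
#' @param window_start_range earliest-planting-day range (day-of-season).
#' @param window_length_range planting-window length range in days.
#' @param maturity_days_range target days-to-maturity range used to
#'   calibrate required GDUs.
#' @param quantity_range harvest quantity range (ears), integer draws.
#' @param seed integer seed.
#' @return a `population_profile` object.
#' @export
population_profile <- function(n_populations = 200L,
                               window_start_range = c(1L, 150L),
                               window_length_range = c(7L, 21L),
                               maturity_days_range = c(95, 118),
                               quantity_range = c(50L, 500L),
                               seed = 1L) {
  stopifnot(is_count(n_populations),
            length(window_start_range) == 2L,
            length(window_length_range) == 2L,
            length(maturity_days_range) == 2L,
            length(quantity_range) == 2L,
            all(window_start_range >= 1),
            all(window_length_range >= 1),
            all(maturity_days_range > 0),
            all(quantity_range > 0))
  structure(list(n_populations = as.integer(n_populations),
                 window_start_range = as.integer(window_start_range),
                 window_length_range = as.integer(window_length_range),
                 maturity_days_range = as.numeric(maturity_days_range),
                 quantity_range = as.integer(quantity_range),
                 seed = as.integer(seed)),
            class = "population_profile")
}

#' Generate a population table
#'
#' Draws planting windows, calibrated GDU requirements, and two scenario
#' quantities. Every generated population is guaranteed at least one
#' eligible harvest week against the supplied series (rows failing the
#' check are redrawn, with bounded retries).
#'
#' @param profile a [population_profile()].
#' @param series [gdu_series()] tibble or numeric daily GDUs the
#'   eligibility guarantee is checked against.
#' @param calendar a [season_calendar()].
#' @param maturity a [maturity_config()].
#' @param max_retries redraw budget per population.
#' @return population tibble: `population`, `window_start_day`,
#'   `window_end_day`, `required_gdu`, `qty_scenario1`, `qty_scenario2`.
#' @export
gen_population_table <- function(profile, series,
                                 calendar = season_calendar(),
                                 maturity = maturity_config(),
                                 max_retries = 50L) {
  stopifnot(inherits(profile, "population_profile"))
  values <- gdu_values(series)
  mean_gdu <- mean(values)
  need <- max(profile$window_start_range) +
    max(profile$window_length_range) + maturity$max_harvest_days
  if (length(values) < need) {
    abort(sprintf("series too short for the profile: %d days given, %d needed",
                  length(values), need))
  }
  # sample(x, 1) on a scalar x would draw from 1:x; guard degenerate ranges
  draw_range <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1L)
  draw_one <- function(id) {
    for (r in seq_len(max_retries)) {
      ws <- draw_range(profile$window_start_range[1], profile$window_start_range[2])
      len <- draw_range(profile$window_length_range[1], profile$window_length_range[2])
      we <- min(ws + len - 1L, calendar$season_days)
      target_days <- runif(1, profile$maturity_days_range[1],
                           profile$maturity_days_range[2])
      req <- target_days * mean_gdu
      row <- tibble(
        population = sprintf("p%03d", id),
        window_start_day = as.integer(ws), window_end_day = as.integer(we),
        required_gdu = req,
        qty_scenario1 = as.numeric(
          draw_range(profile$quantity_range[1], profile$quantity_range[2])),
        qty_scenario2 = as.numeric(
          draw_range(profile$quantity_range[1], profile$quantity_range[2]))
      )
      H <- build_harvest_week_matrix(row, values, calendar, maturity)
      if (any(!is.na(H$harvest_week))) return(row)
    }
    abort(sprintf(
      "could not generate a schedulable population after %d retries; the series cannot support the requested maturity calibration",
      max_retries))
  }
  with_seed(profile$seed,
            purrr::map_dfr(seq_len(profile$n_populations), draw_one))
}

#' Generate an end-to-end scheduling fixture
#'
#' Bundles a synthetic series, population table, harvest-week and
#' eligibility matrices, and a ready-to-solve [scheduling_instance()].
#' Fixed-capacity fixtures come in two flavours: `"ample"` sets the
#' capacity comfortably above the minimum feasible weekly peak (the base
#' model is feasible), `"tight"` sets it below (forcing the three-step
#' path). Both are derived from the instance's own minimum feasible
#' capacity, obtained from the flexible-capacity model.
#'
#' @param site a [site_profile()].
#' @param pops a [population_profile()].
#' @param case `"fixed"` or `"flexible"`.
#' @param flavor `"ample"` or `"tight"`, for `case = "fixed"`.
#' @param scenario scenario index selecting the quantity column.
#' @param calendar a [season_calendar()].
#' @param maturity a [maturity_config()].
#' @return list with `series`, `populations`, `harvest_weeks`,
#'   `eligibility`, `instance`, `case`, `flavor`, `capacity`, and `c_min`
#'   (the minimum feasible weekly capacity used to set fixed capacities).
#' @export
gen_case_fixture <- function(site, pops, case = c("fixed", "flexible"),
                             flavor = c("ample", "tight"), scenario = 1L,
                             calendar = season_calendar(),
                             maturity = maturity_config()) {
  case <- match.arg(case)
  flavor <- match.arg(flavor)
  series <- gen_gdu_series(site)
  populations <- gen_population_table(pops, series, calendar, maturity)
  H <- build_harvest_week_matrix(populations, series, calendar, maturity)
  elig <- build_eligibility_matrix(H, calendar)
  keep <- setdiff(populations$population, unschedulable_populations(elig))
  populations <- populations[populations$population %in% keep, , drop = FALSE]
  elig <- elig[elig$population %in% keep, , drop = FALSE]
  q <- population_quantities(populations, scenario)
  if (case == "flexible") {
    inst <- scheduling_instance(q, elig, capacity = "flexible")
    return(list(series = series, populations = populations,
                harvest_weeks = H, eligibility = elig, instance = inst,
                case = case, flavor = NA_character_,
                capacity = NA_real_, c_min = NA_real_))
  }
  flex <- scheduling_instance(q, elig, capacity = "flexible")
  c_min <- solve_min_capacity_flexible(flex)$c_z
  capacity <- if (flavor == "ample") ceiling(1.25 * c_min)
              else max(floor(0.8 * c_min), 1)
  if (flavor == "tight" && capacity >= c_min) capacity <- c_min - 1
  if (capacity < 1) abort("cannot build a tight fixture: minimum capacity is 1")
  inst <- scheduling_instance(q, elig, capacity = capacity)
  list(series = series, populations = populations, harvest_weeks = H,
       eligibility = elig, instance = inst, case = case, flavor = flavor,
       capacity = capacity, c_min = c_min)
}
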