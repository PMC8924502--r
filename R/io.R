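# CSV/JSON input-output and the end-to-end pipeline: forecast (or bypass)
# -> harvest-week and eligibility matrices -> capacity-aware scheduling ->
# evaluation, with every artifact written to disk.

#' Read a daily GDU CSV
#'
#' Expects columns `site,date,gdu` (ISO dates, one row per day). Dates must
#' be contiguous within the site.
#'
#' @param path CSV file path.
#' @param site optional site id to filter on when the file holds several.
#' @return a [gdu_series()] tibble (`site`, `date`, `day`, `gdu`).
#' @export
read_gdu_csv <- function(path, site = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(
    site = readr::col_character(), date = readr::col_date(),
    gdu = readr::col_double()))
  if (!is.null(site)) df <- df[df$site == site, , drop = FALSE]
  if (nrow(df) == 0L) abort(sprintf("no GDU rows in %s", path))
  if (length(unique(df$site)) > 1L) {
    abort(sprintf("%s holds several sites (%s); pass `site` to choose one",
                  path, paste(unique(df$site), collapse = ", ")))
  }
  df <- df[order(df$date), , drop = FALSE]
  if (nrow(df) > 1L) {
    gaps <- which(diff(as.integer(df$date)) != 1L)
    if (length(gaps) > 0L) {
      abort(sprintf("date gap in %s after line %d (%s)", path,
                    gaps[1L] + 1L, format(df$date[gaps[1L]])))
    }
  }
  if (any(!is.finite(df$gdu))) {
    abort(sprintf("non-finite gdu value in %s at line %d", path,
                  which(!is.finite(df$gdu))[1L] + 1L))
  }
  gdu_series(df$gdu, site = df$site[1L], start_date = df$date[1L])
}

#' Write a daily GDU CSV
#'
#' @param series a [gdu_series()] tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gdu_csv <- function(series, path) {
  readr::write_csv(series[, c("site", "date", "gdu")], path)
  invisible(path)
}

#' Read a population CSV
#'
#' Expects `population,window_start_day,window_end_day,required_gdu,`
#' `qty_scenario1,qty_scenario2`. Row-level validation errors name the
#' offending population and row.
#'
#' @param path CSV file path.
#' @param calendar a [season_calendar()] the windows are checked against.
#' @return validated population tibble.
#' @export
read_population_csv <- function(path, calendar = season_calendar()) {
  df <- readr::read_csv(path, col_types = readr::cols(
    population = readr::col_character(), .default = readr::col_double()))
  check_population_table(df, calendar)
  df
}

#' Write a population CSV
#'
#' @param populations population tibble.
#' @param path output CSV path.
#' @export
write_population_csv <- function(populations, path) {
  readr::write_csv(populations, path)
  invisible(path)
}

#' Write / read the wide eligibility CSV
#'
#' One row per population, columns `population, week_1 ... week_<n>`.
#'
#' @param eligibility wide tibble from [build_eligibility_matrix()].
#' @param path CSV path.
#' @name eligibility_csv
#' @export
write_eligibility_csv <- function(eligibility, path) {
  readr::write_csv(eligibility, path)
  invisible(path)
}

#' @rdname eligibility_csv
#' @export
read_eligibility_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    population = readr::col_character(), .default = readr::col_integer()))
}

#' Write / read the schedule CSV
#'
#' Columns `population,harvest_week,planting_day,quantity`.
#'
#' @param schedule a `harvest_schedule` (or `harvest_plan`).
#' @param path CSV path.
#' @name schedule_csv
#' @export
write_schedule_csv <- function(schedule, path) {
  if (inherits(schedule, "harvest_plan")) schedule <- schedule$schedule
  out <- schedule$assignment
  if (!"planting_day" %in% names(out)) out$planting_day <- NA_integer_
  readr::write_csv(
    out[, c("population", "harvest_week", "planting_day", "quantity")], path)
  invisible(path)
}

#' @rdname schedule_csv
#' @export
read_schedule_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    population = readr::col_character(),
    harvest_week = readr::col_integer(),
    planting_day = readr::col_integer(),
    quantity = readr::col_double()))
}

#' Write / read the weekly report CSV
#'
#' Columns `week,total_quantity,capacity,extra_capacity,used`.
#'
#' @param schedule a `harvest_schedule` (or `harvest_plan`).
#' @param path CSV path.
#' @name weekly_report_csv
#' @export
write_weekly_report_csv <- function(schedule, path) {
  if (inherits(schedule, "harvest_plan")) schedule <- schedule$schedule
  readr::write_csv(schedule$weekly, path)
  invisible(path)
}

#' @rdname weekly_report_csv
#' @export
read_weekly_report_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    week = readr::col_integer(), total_quantity = readr::col_double(),
    capacity = readr::col_double(), extra_capacity = readr::col_double(),
    used = readr::col_logical()))
}

#' Pipeline run configuration
#'
#' @param gdu_file historical daily GDU CSV (`site,date,gdu`).
#' @param population_file population CSV.
#' @param out_dir output directory for artifacts.
#' @param site optional site filter for `gdu_file`.
#' @param case `"fixed"` or `"flexible"`.
#' @param capacity weekly storage capacity in ears (fixed case).
#' @param scenario scenario index selecting the quantity column.
#' @param n_weeks season length in weeks.
#' @param max_harvest_days maturity cap in days.
#' @param adjustment_cutoff_day,adjustment_gdu_reduction optional
#'   late-planting GDU reduction; both `NULL` disables it.
#' @param forecast_model `"seasonal_naive"`, `"cnn"`, or `"none"` (bypass:
#'   `future_gdu_file` supplies the season's GDUs directly).
#' @param future_gdu_file daily GDU CSV used as the season series when
#'   `forecast_model = "none"`.
#' @param lookback,horizon forecasting window sizes in days.
#' @param epochs,batch_size CNN training schedule.
#' @param seed integer seed for forecasting.
#' @param solver_time_limit seconds per MILP solve.
#' @return a `run_config` object.
#' @export
run_config <- function(gdu_file, population_file, out_dir,
                       site = NULL, case = c("fixed", "flexible"),
                       capacity = NULL, scenario = 1L, n_weeks = 70L,
                       max_harvest_days = 120L,
                       adjustment_cutoff_day = NULL,
                       adjustment_gdu_reduction = 110,
                       forecast_model = c("seasonal_naive", "cnn", "none"),
                       future_gdu_file = NULL,
                       lookback = 730L, horizon = 547L,
                       epochs = 20L, batch_size = 32L, seed = 42L,
                       solver_time_limit = 600) {
  case <- match.arg(case)
  forecast_model <- match.arg(forecast_model)
  if (case == "fixed" && !(is_number(capacity) && capacity > 0)) {
    abort("fixed case needs a positive `capacity`")
  }
  if (forecast_model == "none" && is.null(future_gdu_file)) {
    abort("forecast_model = \"none\" needs `future_gdu_file`")
  }
  for (f in c(gdu_file, population_file, future_gdu_file)) {
    if (!file.exists(f)) abort(sprintf("input file does not exist: %s", f))
  }
  structure(
    list(gdu_file = gdu_file, population_file = population_file,
         out_dir = out_dir, site = site, case = case,
         capacity = capacity, scenario = as.integer(scenario),
         n_weeks = as.integer(n_weeks),
         max_harvest_days = as.integer(max_harvest_days),
         adjustment_cutoff_day = adjustment_cutoff_day,
         adjustment_gdu_reduction = adjustment_gdu_reduction,
         forecast_model = forecast_model,
         future_gdu_file = future_gdu_file,
         lookback = as.integer(lookback), horizon = as.integer(horizon),
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         seed = as.integer(seed), solver_time_limit = solver_time_limit),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @return a `run_config` object.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Read and validate the pipeline inputs
#'
#' @param config a [run_config()].
#' @return list with `series` (historical GDUs) and `populations`.
#' @export
read_inputs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cal <- season_calendar(config$n_weeks)
  list(series = read_gdu_csv(config$gdu_file, site = config$site),
       populations = read_population_csv(config$population_file, cal))
}

pipeline_forecaster <- function(config, train) {
  switch(config$forecast_model,
    seasonal_naive = seasonal_naive(365L, horizon = config$horizon),
    cnn = fit_cnn(
      cnn_spec(input_length = config$lookback,
               output_units = config$horizon, epochs = config$epochs,
               batch_size = config$batch_size, seed = config$seed),
      train),
    abort("no forecaster for forecast_model = \"none\"")
  )
}

#' Run the end-to-end planting pipeline
#'
#' Forecast the season's daily GDUs (or consume a supplied future series),
#' build the harvest-week and eligibility matrices, schedule under the
#' configured capacity case, evaluate, and write all artifacts to
#' `out_dir`: `forecast.csv`, `eligibility.csv`, `schedule.csv`,
#' `weekly_report.csv`, `evaluation.json`, `diagnostics.json`,
#' `run_log.json`.
#'
#' @param config a [run_config()] or path to a YAML config file.
#' @return invisibly, a list with the `plan`, the `evaluation` tibble, and
#'   the artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  cal <- season_calendar(config$n_weeks)
  adjustment <- if (!is.null(config$adjustment_cutoff_day)) {
    maturity_adjustment(config$adjustment_cutoff_day,
                        config$adjustment_gdu_reduction)
  }
  maturity <- maturity_config(config$max_harvest_days, adjustment)
  stage <- "read_inputs"
  out <- tryCatch({
    inputs <- read_inputs(config)
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(config$out_dir,
                       c(forecast = "forecast.csv",
                         eligibility = "eligibility.csv",
                         schedule = "schedule.csv",
                         weekly = "weekly_report.csv",
                         evaluation = "evaluation.json",
                         diagnostics = "diagnostics.json",
                         log = "run_log.json"))
    names(paths) <- c("forecast", "eligibility", "schedule", "weekly",
                      "evaluation", "diagnostics", "log")

    stage <- "forecast"
    if (config$forecast_model == "none") {
      season <- read_gdu_csv(config$future_gdu_file, site = config$site)
    } else {
      hist <- gdu_values(inputs$series)
      windows <- if (config$forecast_model == "cnn") {
        make_sliding_windows(inputs$series, config$lookback, config$horizon)
      }
      model <- pipeline_forecaster(config, windows)
      pred <- predict_horizon(model, tail(hist, config$lookback))
      season <- gdu_series(pred, site = inputs$series$site[1L],
                           start_date = max(inputs$series$date) + 1L)
    }
    readr::write_csv(
      tibble(site = season$site, day_index = season$day, date = season$date,
             gdu_pred = season$gdu),
      paths[["forecast"]])

    stage <- "harvest_maps"
    H <- build_harvest_week_matrix(inputs$populations, season, cal, maturity)
    elig <- build_eligibility_matrix(H, cal)
    write_eligibility_csv(elig, paths[["eligibility"]])
    dropped <- unschedulable_populations(elig)
    keep <- setdiff(inputs$populations$population, dropped)
    pops <- inputs$populations[inputs$populations$population %in% keep, ]
    elig_keep <- elig[elig$population %in% keep, , drop = FALSE]

    stage <- "schedule"
    q <- population_quantities(pops, config$scenario)
    cap <- if (config$case == "flexible") "flexible" else config$capacity
    inst <- scheduling_instance(q, elig_keep, capacity = cap)
    plan <- if (config$case == "flexible") {
      run_flexible_capacity(inst, H, time_limit = config$solver_time_limit)
    } else {
      run_fixed_capacity(inst, H, time_limit = config$solver_time_limit)
    }
    write_schedule_csv(plan, paths[["schedule"]])
    write_weekly_report_csv(plan, paths[["weekly"]])

    stage <- "evaluate"
    eval_cap <- if (config$case == "flexible") plan$proposed_capacity
                else config$capacity
    report <- evaluate_schedule(plan, eval_cap)
    jsonlite::write_json(as.list(report), paths[["evaluation"]],
                         auto_unbox = TRUE, digits = NA)
    diag <- list(status = plan$schedule$status,
                 objective = plan$schedule$objective,
                 path = plan$path,
                 peak_weeks = as.list(plan$peak_weeks %||% integer(0)),
                 proposed_capacity = plan$proposed_capacity %||% NA)
    jsonlite::write_json(diag, paths[["diagnostics"]],
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
    log <- list(timestamp = format(Sys.time(), tz = "UTC"),
                seed = config$seed, case = config$case,
                scenario = config$scenario,
                forecast_model = config$forecast_model,
                solver = "highs (scipy.optimize.milp)",
                solver_status = plan$schedule$status,
                dropped_populations = as.list(dropped))
    jsonlite::write_json(log, paths[["log"]], auto_unbox = TRUE, digits = NA)
    list(plan = plan, evaluation = report, paths = as.list(paths))
  }, error = function(e) {
    abort(sprintf("pipeline failed at stage `%s`: %s", stage,
                  conditionMessage(e)))
  })
  invisible(out)
}
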