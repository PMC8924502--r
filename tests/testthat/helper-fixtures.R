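# Seeded end-to-end fixtures, cached so several test files can share them
# without regenerating series and re-solving capacity models.

.fixture_cache <- new.env(parent = emptyenv())

# the 20-fixture panel: mixed flavours and sizes up to 200 populations
fixture_panel <- function() {
  tibble::tribble(
    ~id, ~case, ~flavor, ~n_pops, ~site, ~seed,
    1L, "fixed", "ample", 30L, 0L, 101L,
    2L, "fixed", "ample", 60L, 1L, 102L,
    3L, "fixed", "ample", 100L, 0L, 103L,
    4L, "fixed", "ample", 150L, 1L, 104L,
    5L, "fixed", "ample", 200L, 0L, 105L,
    6L, "fixed", "ample", 80L, 1L, 106L,
    7L, "fixed", "ample", 40L, 0L, 107L,
    8L, "fixed", "tight", 30L, 1L, 108L,
    9L, "fixed", "tight", 60L, 0L, 109L,
    10L, "fixed", "tight", 100L, 1L, 110L,
    11L, "fixed", "tight", 150L, 0L, 111L,
    12L, "fixed", "tight", 200L, 1L, 112L,
    13L, "fixed", "tight", 80L, 0L, 113L,
    14L, "fixed", "tight", 40L, 1L, 114L,
    15L, "flexible", NA, 30L, 0L, 115L,
    16L, "flexible", NA, 60L, 1L, 116L,
    17L, "flexible", NA, 100L, 0L, 117L,
    18L, "flexible", NA, 150L, 1L, 118L,
    19L, "flexible", NA, 200L, 0L, 119L,
    20L, "flexible", NA, 120L, 1L, 120L
  )
}

get_fixture <- function(id) {
  key <- paste0("fx", id)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  row <- fixture_panel()[id, ]
  site <- if (row$site == 0L) site_profile_site0(n_years = 2, seed = row$seed)
          else site_profile_site1(n_years = 2, seed = row$seed)
  pops <- population_profile(n_populations = row$n_pops, seed = row$seed + 500L)
  fx <- if (row$case == "flexible") {
    gen_case_fixture(site, pops, case = "flexible")
  } else {
    gen_case_fixture(site, pops, case = "fixed", flavor = row$flavor)
  }
  fx$id <- id
  .fixture_cache[[key]] <- fx
  fx
}

get_plan <- function(id) {
  key <- paste0("plan", id)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  fx <- get_fixture(id)
  plan <- if (fx$case == "flexible") {
    run_flexible_capacity(fx$instance, fx$harvest_weeks)
  } else {
    run_fixed_capacity(fx$instance, fx$harvest_weeks)
  }
  .fixture_cache[[key]] <- plan
  plan
}

# the scaled-down noisy forecasting benchmark shared by tests
benchmark_series <- function(seed = 11, n = 800, period = 30,
                             mean = 8, amp = 3, sd = 0.4) {
  set.seed(seed)
  pmax(mean + amp * sin(2 * pi * (1:n) / period) + rnorm(n, sd = sd), 0)
}

benchmark_cnn_spec <- function() {
  cnn_spec(input_length = 60L, conv_filters = 8L, kernel_size = 2L,
           pool_size = 2L, dense_units = 32L, output_units = 30L,
           epochs = 120L, batch_size = 32L, learning_rate = 0.005,
           seed = 1L)
}
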