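# Schedule evaluation: how well the weekly allocation uses the storage
# capacity. Deviations |capacity - weekly total| are computed over used
# weeks only; counting idle weeks would swamp the median with
# full-capacity deviations and say nothing about the harvest plan.

#' Evaluate a harvest schedule against a storage capacity
#'
#' @param schedule a `harvest_schedule` (or a `harvest_plan`, whose
#'   schedule and proposed capacity are unwrapped).
#' @param capacity weekly storage capacity in ears; defaults to the
#'   capacity recorded in the schedule.
#' @return one-row tibble: `max_abs_deviation` and `median_abs_deviation`
#'   (ears, over used weeks), `weeks_used` (count of harvesting weeks),
#'   `last_week` (index of the final harvesting week), and
#'   `proposed_capacity` (ears for flexible-capacity runs, `NA` otherwise).
#' @export
#' @examples
#' \dontrun{
#' evaluate_schedule(plan)  # plan from run_fixed_capacity()
#' }
evaluate_schedule <- function(schedule, capacity = NULL) {
  proposed <- NA_real_
  if (inherits(schedule, "harvest_plan")) {
    proposed <- schedule$proposed_capacity %||% NA_real_
    schedule <- schedule$schedule
  }
  stopifnot(inherits(schedule, "harvest_schedule"))
  if (is.null(capacity)) capacity <- schedule$capacity
  if (isTRUE(schedule$flexible) && is.na(proposed)) proposed <- capacity
  if (!is_number(capacity)) abort("`capacity` must be a single number")
  weekly <- schedule$weekly[schedule$weekly$used, , drop = FALSE]
  if (nrow(weekly) == 0L) {
    warn("empty schedule: no used weeks")
    return(tibble(max_abs_deviation = 0, median_abs_deviation = 0,
                  weeks_used = 0L, last_week = 0L,
                  proposed_capacity = proposed))
  }
  dev <- abs(capacity - weekly$total_quantity)
  tibble(
    max_abs_deviation = max(dev),
    median_abs_deviation = median(dev),
    weeks_used = nrow(weekly),
    last_week = max(weekly$week),
    proposed_capacity = proposed
  )
}
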