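#' Simulate daily developmental event counts
#'
#' Generates vial-format pupation/eclosion count tables with the structure
#' the validation assays assume: each individual survives to the event with
#' probability `survival`, and surviving individuals' event days follow a
#' discretised normal centred at `median_day + delay` (rounded to the day
#' grid and clamped to it). Delay therefore shifts the whole event-day
#' distribution; lethality scales the surviving fraction.
#'
#' @param n_individuals Individuals at the start (per group).
#' @param days Integer day grid on which events are recorded.
#' @param median_day Median event day of the reference condition.
#' @param delay Shift in days added to `median_day`.
#' @param survival Probability of surviving to the event, in [0, 1].
#' @param spread SD (days) of the event-day distribution.
#' @param label Group label stored in the output.
#' @param seed Optional seed; when given the draw is reproducible.
#' @return A `dev_events` data frame: `label`, `day`, `count`, with
#'   attributes `n_total` (starting individuals) and `n_survivors`.
#' @export
simulate_dev_events <- function(n_individuals, days = 9:14, median_day = 10,
                                delay = 0, survival = 1, spread = 0.8,
                                label = "group", seed = NULL) {
  stopifnot(n_individuals >= 0, survival >= 0, survival <= 1, spread > 0)
  draw <- function() {
    n_surv <- stats::rbinom(1, n_individuals, survival)
    d <- round(stats::rnorm(n_surv, median_day + delay, spread))
    d <- pmin(pmax(d, min(days)), max(days))
    counts <- tabulate(match(d, days), nbins = length(days))
    out <- data.frame(label = label, day = days, count = counts,
                      stringsAsFactors = FALSE)
    attr(out, "n_total") <- n_individuals
    attr(out, "n_survivors") <- n_surv
    class(out) <- c("dev_events", "data.frame")
    out
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
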