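#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an outcome tally
#'
#' @param x An `outcome_tally` from [run_microsim()].
#' @param ... Unused.
#' @return One row per tallied metric with totals and per-100,000 rates,
#'   plus the strategy label.
#' @export
tidy.outcome_tally <- function(x, ...) {
  dplyr::mutate(x$counts, label = x$label, .before = 1)
}

#' @rdname tidy.outcome_tally
#' @export
glance.outcome_tally <- function(x, ...) {
  tibble::tibble(
    label = x$label, n = x$n, seed = x$seed,
    mean_cost = x$mean_cost, mean_qaly = x$mean_qaly,
    sd_cost = x$sd_cost, sd_qaly = x$sd_qaly,
    mean_life_years = x$mean_life_years,
    cancers_per_100k = tally_metric(x, "cancers"),
    crc_deaths_per_100k = tally_metric(x, "crc_deaths")
  )
}

#' Tidy a cohort-expectation result
#'
#' @param x A `cohort_result` from [run_cohort_expectation()].
#' @param ... Unused.
#' @return One row per expected count.
#' @export
tidy.cohort_result <- function(x, ...) {
  dplyr::mutate(x$counts, label = x$label, .before = 1)
}

#' @rdname tidy.cohort_result
#' @export
glance.cohort_result <- function(x, ...) {
  cc <- x$counts
  g <- function(m) cc$per_100k[cc$metric == m]
  tibble::tibble(
    label = x$label, mean_cost = x$mean_cost, mean_qaly = x$mean_qaly,
    mean_life_years = x$mean_life_years,
    cancers_per_100k = g("cancers"), crc_deaths_per_100k = g("crc_deaths")
  )
}

#' Tidy an incremental cost-effectiveness analysis
#'
#' @param x A `cea_result` from [incremental_analysis()].
#' @param ... Unused.
#' @return The cost-ordered strategy table with dominance flags and ICERs.
#' @export
tidy.cea_result <- function(x, ...) {
  x$table
}

#' @rdname tidy.cea_result
#' @export
glance.cea_result <- function(x, ...) {
  tibble::tibble(
    n_strategies = nrow(x$table),
    n_frontier = sum(x$table$on_frontier),
    n_strongly_dominated = sum(x$table$strongly_dominated),
    n_extendedly_dominated = sum(x$table$extendedly_dominated)
  )
}

#' Tidy a probabilistic sensitivity analysis
#'
#' @param x A `psa_result` from [run_psa()].
#' @param ... Unused.
#' @return Per-strategy means with 2.5th/97.5th percentile intervals.
#' @export
tidy.psa_result <- function(x, ...) {
  x$intervals
}

#' @rdname tidy.psa_result
#' @export
glance.psa_result <- function(x, ...) {
  cheaper_better <- x$quadrants$fraction[
    x$quadrants$quadrant == "more effective, less costly"]
  tibble::tibble(
    n_draws = x$n_draws, seed = x$seed,
    comparison = paste(x$comparison, collapse = " vs "),
    frac_more_effective_less_costly = cheaper_better
  )
}

#' Tidy a calibration result
#'
#' @param x A `calibration_result` from [calibrate_natural_history()].
#' @param ... Unused.
#' @return The adjusted-parameter table.
#' @export
tidy.calibration_result <- function(x, ...) {
  x$adjusted
}

#' @rdname tidy.calibration_result
#' @export
glance.calibration_result <- function(x, ...) {
  a <- x$achieved
  tibble::tibble(
    converged = x$converged, objective = x$objective,
    cancers_per_100k = a$achieved[a$metric == "cancers_per_100k"],
    deaths_per_100k = a$achieved[a$metric == "deaths_per_100k"]
  )
}
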