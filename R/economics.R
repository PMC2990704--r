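#' Discount a future amount to present value
#'
#' Year 0 (age 50, cohort entry) is undiscounted; year `t` amounts are
#' divided by `(1 + rate)^t`. The base-case rate is 5% per year for both
#' costs and health benefits.
#'
#' @param amount Numeric amount(s).
#' @param year Nonnegative cycle index (0 = entry year).
#' @param rate Annual discount rate (>= 0).
#' @return Discounted amount(s).
#' @export
#' @examples
#' discount(100, 1, 0.05)
discount <- function(amount, year, rate) {
  if (any(year < 0)) stop("discounting year must be nonnegative", call. = FALSE)
  if (any(rate < 0)) stop("discount rate must be nonnegative", call. = FALSE)
  amount / (1 + rate)^year
}

#' Annual utility weight for a health state
#'
#' All alive, undiagnosed states (including undiagnosed CRC and
#' post-polypectomy) carry the no-CRC utility. Diagnosed CRC carries the
#' early-CRC weight (stages I-II) or advanced-CRC weight (stages III-IV)
#' during the five-year survival window; survivors beyond the window revert
#' to the no-CRC weight, mirroring the mortality cure rule.
#'
#' @param state Character health state (see [health_states()]).
#' @param stage Stage at diagnosis (1-4), for diagnosed CRC.
#' @param years_since_dx Completed years since diagnosis.
#' @param params A `crc_parameters` object.
#' @return Utility weight(s) in \[0, 1\].
#' @export
annual_utility <- function(state, stage = NA_integer_,
                           years_since_dx = NA_integer_,
                           params = base_case_parameters()) {
  if (any(state == "dead")) {
    stop("the dead state carries no utility and must not be queried", call. = FALSE)
  }
  u <- params$utilities
  window <- params$settings$crc_survival_window
  dx <- state == "crc_diagnosed"
  in_window <- dx & !is.na(years_since_dx) & years_since_dx < window
  out <- rep(u$no_crc, length(state))
  out[in_window & stage <= 2] <- u$early_crc
  out[in_window & stage >= 3] <- u$advanced_crc
  out
}

# utility vector for internal integer states
utility_int <- function(state, stage, ydx, params) {
  u <- params$utilities
  window <- params$settings$crc_survival_window
  out <- rep(u$no_crc, length(state))
  in_window <- state == 5L & ydx < window
  early <- in_window & stage <= 2L
  adv <- in_window & stage >= 3L
  out[early] <- u$early_crc
  out[adv] <- u$advanced_crc
  out[state == 6L] <- 0
  out
}

#' Cost ledger for a sequence of screening events
#'
#' Converts an event log into ledger entries: primary stool tests cost the
#' kit/processing fee plus the stool nonmedical cost plus any administrative
#' cost per test; CT colonography and flexible sigmoidoscopy their direct
#' plus nonmedical costs; colonoscopies the diagnostic or therapeutic
#' procedure cost plus the colonoscopy nonmedical cost; bleeding and
#' perforation complications their event costs; and a CRC diagnosis the full
#' stage-based management cost as a lump sum in the diagnosis year.
#'
#' @param events Tibble with columns `year`, `kind` (one of `primary_test`,
#'   `followup_colonoscopy`, `surveillance_colonoscopy`,
#'   `complication_bleed`, `complication_perforation`, `crc_diagnosis`),
#'   `modality` (for tests), `therapeutic` (logical, colonoscopies),
#'   `stage` (for diagnoses).
#' @param costs The `costs` component of a `crc_parameters` object.
#' @return A tibble ledger with columns `year`, `category`, `amount`.
#' @export
cost_of_events <- function(events, costs) {
  if (nrow(events) == 0) {
    return(tibble::tibble(year = integer(), category = character(),
                          amount = numeric()))
  }
  rows <- purrr::pmap(events, function(year, kind, modality = NA_character_,
                                       therapeutic = FALSE, stage = NA_integer_, ...) {
    if (kind == "primary_test") {
      if (modality == "colonoscopy") {
        direct <- if (isTRUE(therapeutic)) costs$direct$colonoscopy_tx else costs$direct$colonoscopy_dx
        tibble::tibble(
          year = year,
          category = c("test_direct", "test_nonmedical", "admin"),
          amount = c(direct, costs$nonmedical$colonoscopy, costs$admin_per_test)
        )
      } else {
        tibble::tibble(
          year = year,
          category = c("test_direct", "test_nonmedical", "admin"),
          amount = c(direct_test_cost(modality, costs),
                     nonmedical_test_cost(modality, costs),
                     costs$admin_per_test)
        )
      }
    } else if (kind %in% c("followup_colonoscopy", "surveillance_colonoscopy")) {
      direct <- if (isTRUE(therapeutic)) costs$direct$colonoscopy_tx else costs$direct$colonoscopy_dx
      tibble::tibble(year = year,
                     category = c("test_direct", "test_nonmedical"),
                     amount = c(direct, costs$nonmedical$colonoscopy))
    } else if (kind == "complication_bleed") {
      tibble::tibble(year = year, category = "complication",
                     amount = costs$complication$bleed)
    } else if (kind == "complication_perforation") {
      tibble::tibble(year = year, category = "complication",
                     amount = costs$complication$perforation)
    } else if (kind == "crc_diagnosis") {
      tibble::tibble(year = year, category = "crc_management",
                     amount = unlist(costs$crc_management)[[stage]])
    } else {
      stop("unknown event kind '", kind, "'", call. = FALSE)
    }
  })
  out <- dplyr::bind_rows(rows)
  out[out$amount > 0 | out$category != "admin", , drop = FALSE]
}

#' Summarise one person's discounted outcomes
#'
#' @param ledger Tibble of cost entries (`year`, `amount`).
#' @param utility_stream Numeric vector of annual utility weights, one per
#'   lived year starting at year 0.
#' @param settings The `settings` component of a `crc_parameters` object.
#' @return A one-row tibble with `discounted_cost`, `discounted_qaly`, and
#'   undiscounted `life_years`.
#' @export
summarize_person <- function(ledger, utility_stream, settings) {
  rate <- settings$discount_rate
  cost <- if (nrow(ledger)) sum(discount(ledger$amount, ledger$year, rate)) else 0
  years <- seq_along(utility_stream) - 1
  qaly <- sum(discount(utility_stream, years, rate))
  tibble::tibble(discounted_cost = cost, discounted_qaly = qaly,
                 life_years = length(utility_stream))
}
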