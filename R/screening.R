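#' Define a screening strategy
#'
#' @param modality Screening modality label: one of `"FOBT-low"`,
#'   `"FOBT-high"`, `"FIT-low"`, `"FIT-mid"`, `"FIT-high"`, `"FDNA-SDT1"`,
#'   `"FDNA-SDT2"`, `"colonoscopy"`, `"flex_sig"`, `"CTC"`, or `"none"`.
#' @param interval_years Years between screening offers (default per
#'   modality: annual stool tests, fecal DNA every 3 years, flexible
#'   sigmoidoscopy and CT colonography every 5, colonoscopy every 10).
#' @param start_age,stop_age Screening window (default 50 to 75).
#' @param label Display label (defaults to the modality).
#' @param first_adherence,subsequent_adherence Optional per-strategy
#'   adherence overrides; `NA` uses the parameter set's shared rates.
#' @return A one-row strategy tibble.
#' @export
strategy <- function(modality,
                     interval_years = default_interval(modality),
                     start_age = 50, stop_age = 75, label = modality,
                     first_adherence = NA_real_,
                     subsequent_adherence = NA_real_) {
  known <- c(.stool_modalities, .structural_modalities, "none")
  if (!modality %in% known) {
    stop("unknown modality '", modality, "'", call. = FALSE)
  }
  if (modality != "none") {
    if (interval_years < 1) stop("screening interval must be >= 1 year", call. = FALSE)
    if (start_age >= stop_age) stop("start_age must be below stop_age", call. = FALSE)
  }
  tibble::tibble(label = label, modality = modality,
                 interval_years = as.integer(interval_years),
                 start_age = start_age, stop_age = stop_age,
                 first_adherence = first_adherence,
                 subsequent_adherence = subsequent_adherence)
}

default_interval <- function(modality) {
  switch(modality,
    "FOBT-low" = 1L, "FOBT-high" = 1L,
    "FIT-low" = 1L, "FIT-mid" = 1L, "FIT-high" = 1L,
    "FDNA-SDT1" = 3L, "FDNA-SDT2" = 3L,
    "colonoscopy" = 10L, "flex_sig" = 5L, "CTC" = 5L,
    "none" = NA_integer_,
    stop("unknown modality '", modality, "'", call. = FALSE)
  )
}

#' All base-case comparator strategies
#'
#' The seven modalities at their guideline intervals plus the no-screening
#' natural-history arm.
#'
#' @return A strategy tibble, one row per comparator.
#' @export
default_strategies <- function() {
  dplyr::bind_rows(
    strategy("none"),
    strategy("FOBT-low"), strategy("FOBT-high"),
    strategy("FIT-low"), strategy("FIT-mid"), strategy("FIT-high"),
    strategy("FDNA-SDT1"), strategy("FDNA-SDT2"),
    strategy("colonoscopy"), strategy("flex_sig"), strategy("CTC")
  )
}

#' Surveillance interval after a colonoscopic finding
#'
#' Advanced adenomas and resected cancers trigger 3-year surveillance
#' colonoscopy; nonadvanced adenomas 5-year surveillance, consistent with
#' post-polypectomy guidelines.
#'
#' @param finding `"nonadvanced_adenoma"`, `"advanced_adenoma"`, or
#'   `"crc_resected"`.
#' @return Interval in years (3 or 5).
#' @export
surveillance_interval <- function(finding) {
  out <- c(nonadvanced_adenoma = 5L, advanced_adenoma = 3L, crc_resected = 3L)[finding]
  if (any(is.na(out))) {
    stop("unknown finding '", finding[is.na(out)][1], "'", call. = FALSE)
  }
  unname(out)
}

#' Is screening due this year?
#'
#' Scheduled surveillance takes precedence over primary screening. Primary
#' screening is due when the person is inside the screening age window, the
#' interval since the last offer has elapsed, no surveillance is pending,
#' no post-colonoscopy exemption is active, and the person is not a
#' diagnosed CRC patient.
#'
#' @param persons Tibble with columns `age`, `state`,
#'   `surveillance_due_year`, `screening_exempt_until`, `last_offer_year`
#'   (use `NA` for "never"/"none").
#' @param strat A one-row strategy tibble.
#' @param current_year Cycle index (0 = entry).
#' @return Character vector: `"surveillance"`, `"primary"`, or `"none"`.
#' @export
is_screening_due <- function(persons, strat, current_year) {
  state <- persons$state
  alive <- state != "dead"
  surv <- alive & !is.na(persons$surveillance_due_year) &
    persons$surveillance_due_year <= current_year
  if (strat$modality == "none") {
    return(ifelse(surv, "surveillance", "none"))
  }
  age <- persons$age
  since <- current_year - ifelse(is.na(persons$last_offer_year), -Inf,
                                 persons$last_offer_year)
  exempt <- !is.na(persons$screening_exempt_until) &
    persons$screening_exempt_until > current_year
  primary <- alive & !surv & is.na(persons$surveillance_due_year) &
    state != "crc_diagnosed" &
    age >= strat$start_age & age <= strat$stop_age &
    since >= strat$interval_years & !exempt
  dplyr::case_when(surv ~ "surveillance", primary ~ "primary", TRUE ~ "none")
}

#' Probability that a screening test returns positive
#'
#' Per-person test performance: sensitivity against the true worst lesion
#' (nonadvanced adenoma, advanced adenoma, or cancer), and one minus the
#' per-person specificity when no lesion is present.
#'
#' @param state Character health state(s).
#' @param perf A test-performance list (e.g. one entry of
#'   `base_case_parameters()$tests`).
#' @return Probability of a positive result.
#' @export
test_positive_prob <- function(state, perf) {
  if (any(state == "dead")) stop("cannot test a dead person", call. = FALSE)
  code <- state_code(state)
  p <- c(1 - perf$specificity, perf$sens_nonadvanced, perf$sens_advanced,
         perf$sens_cancer, NA_real_)
  p[code]
}

#' Apply a screening test
#'
#' @inheritParams test_positive_prob
#' @param u Optional uniform deviates.
#' @return Logical: positive result?
#' @export
apply_test <- function(state, perf, u = NULL) {
  p <- test_positive_prob(state, perf)
  if (is.null(u)) u <- stats::runif(length(p))
  u < p
}

# per-state positive probabilities as a length-5 lookup vector
# (index = internal state code; diagnosed CRC is never screened)
positive_prob_lookup <- function(perf) {
  c(1 - perf$specificity, perf$sens_nonadvanced, perf$sens_advanced,
    perf$sens_cancer, 0)
}
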