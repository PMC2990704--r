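# Report writers. Display values mirror the published precision (costs to
# the nearest dollar with thousands separators, QALYs to three decimals);
# every writer also emits an unrounded raw CSV alongside so downstream
# comparisons never run on rounded numbers.

fmt_int <- function(x) ifelse(is.na(x), "n/a", formatC(round(x), format = "d", big.mark = ","))
fmt_qaly <- function(x) formatC(x, format = "f", digits = 3)

raw_path <- function(path) {
  sub("(\\.[A-Za-z0-9]+)?$", "_raw.csv", path)
}

#' Write the incremental cost-effectiveness table
#'
#' One row per strategy, cost-ascending: mean cost (with PSA percentile
#' interval when supplied), mean QALYs, and the dominance status or ICER
#' versus the next cheaper non-dominated strategy.
#'
#' @param cea A `cea_result` from [incremental_analysis()].
#' @param path Output CSV path (a `*_raw.csv` file with unrounded values is
#'   written alongside).
#' @param psa Optional `psa_result` supplying 95% intervals.
#' @return `path`, invisibly.
#' @export
write_table4 <- function(cea, path, psa = NULL) {
  df <- cea$table
  out <- tibble::tibble(
    strategy = df$label,
    average_cost_cad = fmt_int(df$cost),
    average_qalys = fmt_qaly(df$qaly),
    status = dplyr::case_when(
      df$strongly_dominated ~ "Dominated",
      df$extendedly_dominated ~ "Dominated (extended)",
      TRUE ~ ""
    ),
    incremental_cost_per_qaly = ifelse(is.na(df$icer), "",
                                       ifelse(is.infinite(df$icer), "Inf",
                                              fmt_int(df$icer))),
    comparator = ifelse(is.na(df$comparator), "", df$comparator)
  )
  if (!is.null(psa)) {
    iv <- psa$intervals
    i <- match(df$label, iv$label)
    out$cost_95ci <- ifelse(is.na(i), "",
      paste0("(", fmt_int(iv$cost_lo[i]), "-", fmt_int(iv$cost_hi[i]), ")"))
    out$qaly_95ci <- ifelse(is.na(i), "",
      paste0("(", fmt_qaly(iv$qaly_lo[i]), "-", fmt_qaly(iv$qaly_hi[i]), ")"))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  utils::write.csv(df, raw_path(path), row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write the cancer-outcome and resource-use table
#'
#' One row per strategy: lifetime cancers, cancer deaths, primary screening
#' tests and colonoscopies per 100,000 persons, and mean discounted cost
#' per person. For a primary-colonoscopy strategy the colonoscopy column
#' reads `n/a` (its colonoscopies are the primary tests).
#'
#' @param results Tibble from [simulate_strategies()] (microsim engine for
#'   count outcomes).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table5 <- function(results, path) {
  df <- results[order(results$crc_deaths), , drop = FALSE]
  out <- tibble::tibble(
    strategy = df$label,
    n_cancers_overall = fmt_int(df$cancers),
    n_cancer_deaths = fmt_int(df$crc_deaths),
    n_primary_screening_tests = ifelse(df$modality == "none", "n/a",
                                       fmt_int(df$primary_tests)),
    n_colonoscopies = ifelse(df$modality %in% c("none", "colonoscopy"), "n/a",
                             fmt_int(df$colonoscopies)),
    cost_of_screening_and_managing_crc_cad = fmt_int(df$cost)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  utils::write.csv(df, raw_path(path), row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write the PSA incremental scatter
#'
#' Two columns (incremental QALYs, incremental cost), one row per PSA draw.
#'
#' @param psa A `psa_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scatter <- function(psa, path) {
  utils::write.csv(
    psa$scatter[, c("delta_qaly", "delta_cost")], path, row.names = FALSE)
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' Records the master seed, parameter digest, strategy set, engine and
#' cohort size of a run; re-running a manifest reproduces expectation-mode
#' outputs bit for bit and microsimulation tallies exactly.
#'
#' @param params `crc_parameters` used.
#' @param strategies Strategy tibble.
#' @param engine `"expectation"` or `"microsim"`.
#' @param n,seed Cohort size and master seed (microsim).
#' @param scenario Scenario name, if any.
#' @return A one-row tibble.
#' @export
run_manifest <- function(params, strategies, engine, n = NA_integer_,
                         seed = NA_integer_, scenario = NA_character_) {
  digest <- sum(utf8ToInt(yaml::as.yaml(unclass(params), precision = 12)) *
                  (seq_len(nchar(yaml::as.yaml(unclass(params), precision = 12))) %% 9973))
  tibble::tibble(
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    parameter_digest = sprintf("%.0f", digest),
    strategies = paste(strategies$label, collapse = ";"),
    scenario = scenario,
    engine = engine,
    n = n,
    version = as.character(utils::packageVersion("crcscreen"))
  )
}
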