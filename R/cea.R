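#' Evaluate strategies into a cost/QALY results table
#'
#' Runs every strategy through the chosen engine under one parameter set
#' and collects mean discounted cost and QALYs per person (plus event
#' counts per 100,000).
#'
#' @param params A `crc_parameters` object.
#' @param strategies Strategy tibble (default [default_strategies()]).
#' @param engine `"expectation"` (deterministic cohort engine) or
#'   `"microsim"`.
#' @param n_persons,seed Microsimulation size and master seed (microsim
#'   engine only).
#' @return A tibble with one row per strategy: `label`, `modality`, `cost`,
#'   `qaly`, and per-100,000 `cancers`, `crc_deaths`, `primary_tests`,
#'   `colonoscopies`.
#' @export
simulate_strategies <- function(params = base_case_parameters(),
                                strategies = default_strategies(),
                                engine = c("expectation", "microsim"),
                                n_persons = 100000, seed = 1) {
  engine <- match.arg(engine)
  rows <- purrr::map(seq_len(nrow(strategies)), function(i) {
    strat <- strategies[i, ]
    if (engine == "expectation") {
      res <- run_cohort_expectation(strat, params)
      cc <- res$counts
      per100k <- function(m) cc$per_100k[cc$metric == m]
    } else {
      res <- run_microsim(strat, params, n_persons = n_persons, seed = seed)
      cc <- res$counts
      per100k <- function(m) cc$per_100k[cc$metric == m]
    }
    tibble::tibble(
      label = strat$label, modality = strat$modality,
      cost = res$mean_cost, qaly = res$mean_qaly,
      cancers = per100k("cancers"), crc_deaths = per100k("crc_deaths"),
      primary_tests = per100k("primary_tests"),
      colonoscopies = per100k("colonoscopies")
    )
  })
  dplyr::bind_rows(rows)
}

#' Incremental cost-effectiveness analysis with dominance elimination
#'
#' Rank-orders strategies by increasing cost, flags strategies that are
#' strongly dominated (another strategy costs no more and yields no fewer
#' QALYs, with at least one strict inequality) and extendedly dominated (a
#' blend of two other strategies dominates them, detected as a
#' non-increasing ICER along the cost-ordered chain), and reports the ICER
#' of each efficient-frontier member against the next cheaper frontier
#' member.
#'
#' @param results Data frame with columns `label`, `cost`, `qaly` (e.g.
#'   from [simulate_strategies()]).
#' @return A `cea_result` object wrapping a tibble sorted by ascending
#'   cost with dominance flags, `icer`, `comparator`, and `on_frontier`.
#' @export
incremental_analysis <- function(results) {
  df <- tibble::as_tibble(results)[, c("label", "cost", "qaly")]
  if (nrow(df) < 2) stop("need at least two strategies", call. = FALSE)
  if (anyDuplicated(df$label)) {
    stop("duplicate strategy labels: ",
         paste(unique(df$label[duplicated(df$label)]), collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(df)
  strong <- vapply(seq_len(n), function(i) {
    any(df$cost <= df$cost[i] & df$qaly >= df$qaly[i] &
          (df$cost < df$cost[i] | df$qaly > df$qaly[i]))
  }, logical(1))

  # candidates for the frontier, cost-ascending; ties broken by label order
  cand <- df[!strong, , drop = FALSE]
  cand <- cand[order(cand$cost, -cand$qaly, cand$label), , drop = FALSE]
  # exact cost/QALY ties: keep the first as the chain representative
  tie_key <- paste(signif(cand$cost, 15), signif(cand$qaly, 15))
  tied <- duplicated(tie_key)
  chain <- cand[!tied, , drop = FALSE]

  extended <- character(0)
  repeat {
    if (nrow(chain) < 3) break
    dc <- diff(chain$cost)
    dq <- diff(chain$qaly)
    icer <- dc / dq
    drop_k <- NA_integer_
    for (k in seq_len(length(icer) - 1)) {
      if (icer[k + 1] <= icer[k]) { drop_k <- k + 1L; break }
    }
    if (is.na(drop_k)) break
    extended <- c(extended, chain$label[drop_k])
    chain <- chain[-drop_k, , drop = FALSE]
  }

  # tie members share frontier status with their chain representative
  chain_keys <- tie_key[!tied][match(chain$label, cand$label[!tied])]
  tie_on_frontier <- cand$label[tied][tie_key[tied] %in% chain_keys]

  out <- df[order(df$cost, -df$qaly, df$label), , drop = FALSE]
  out$strongly_dominated <- strong[match(out$label, df$label)]
  out$extendedly_dominated <- out$label %in% extended
  out$on_frontier <- out$label %in% c(chain$label, tie_on_frontier)

  out$icer <- NA_real_
  out$comparator <- NA_character_
  out$note <- NA_character_
  if (nrow(chain) >= 2) {
    for (k in 2:nrow(chain)) {
      dq <- chain$qaly[k] - chain$qaly[k - 1]
      dc <- chain$cost[k] - chain$cost[k - 1]
      i <- match(chain$label[k], out$label)
      out$comparator[i] <- chain$label[k - 1]
      if (dq <= 0) {
        out$icer[i] <- Inf
        out$note[i] <- "zero QALY gain over comparator"
      } else {
        out$icer[i] <- dc / dq
      }
    }
  }
  tie_members <- cand$label[tied]
  if (length(tie_members)) {
    i <- match(tie_members, out$label)
    out$note[i] <- "exact cost/QALY tie; ICER undefined"
  }
  structure(list(table = out), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>\n")
  df <- x$table
  df$status <- ifelse(df$strongly_dominated, "dominated",
               ifelse(df$extendedly_dominated, "ext. dominated",
               ifelse(df$on_frontier, "frontier", "")))
  print(as.data.frame(df[, c("label", "cost", "qaly", "status", "icer")]),
        row.names = FALSE, digits = 6)
  invisible(x)
}

#' Second-order probabilistic sensitivity analysis
#'
#' For each draw, samples one parameter set from the supplied distribution
#' specs and evaluates every strategy on it with the deterministic
#' expectation engine (common sampled parameters across strategies, so
#' incremental quantities are paired). Reports empirical 2.5th/97.5th
#' percentile intervals (linear interpolation between closest ranks) for
#' cost and QALYs per strategy, and the incremental cost/QALY scatter for a
#' designated comparison.
#'
#' @param strategies Strategy tibble; must include both comparison arms.
#' @param base_params Base-case `crc_parameters`.
#' @param specs Distribution specs ([default_distribution_specs()]).
#' @param n_draws Number of parameter draws (>= 2).
#' @param seed Master seed; identical seeds give identical output.
#' @param comparison Character pair `c(strategy, comparator)` for the
#'   scatter (default FIT-mid versus no screening).
#' @return A `psa_result` with elements `draws`, `intervals`, `scatter`,
#'   `quadrants`.
#' @export
run_psa <- function(strategies, base_params = base_case_parameters(),
                    specs = default_distribution_specs(),
                    n_draws = 1000, seed = 1,
                    comparison = c("FIT-mid", "none")) {
  stopifnot(n_draws >= 2)
  if (!all(comparison %in% strategies$label)) {
    stop("comparison strategies must be present in `strategies`", call. = FALSE)
  }
  seeds <- derive_seeds(seed, n_draws)
  draws <- purrr::map(seq_len(n_draws), function(d) {
    p <- sample_psa_parameters(base_params, specs, seed = seeds[d])
    res <- simulate_strategies(p, strategies, engine = "expectation")
    res$draw <- d
    res[, c("draw", "label", "cost", "qaly")]
  })
  draws <- dplyr::bind_rows(draws)

  intervals <- draws |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      mean_cost = mean(.data$cost),
      cost_lo = stats::quantile(.data$cost, 0.025, type = 7, names = FALSE),
      cost_hi = stats::quantile(.data$cost, 0.975, type = 7, names = FALSE),
      mean_qaly = mean(.data$qaly),
      qaly_lo = stats::quantile(.data$qaly, 0.025, type = 7, names = FALSE),
      qaly_hi = stats::quantile(.data$qaly, 0.975, type = 7, names = FALSE),
      .groups = "drop"
    )

  wide <- draws |>
    tidyr::pivot_wider(names_from = "label",
                       values_from = c("cost", "qaly"))
  dcost <- wide[[paste0("cost_", comparison[1])]] -
    wide[[paste0("cost_", comparison[2])]]
  dqaly <- wide[[paste0("qaly_", comparison[1])]] -
    wide[[paste0("qaly_", comparison[2])]]
  scatter <- tibble::tibble(draw = wide$draw,
                            delta_cost = dcost, delta_qaly = dqaly)
  quadrants <- tibble::tibble(
    quadrant = c("more effective, less costly", "more effective, more costly",
                 "less effective, less costly", "less effective, more costly"),
    fraction = c(mean(dqaly >= 0 & dcost < 0), mean(dqaly >= 0 & dcost >= 0),
                 mean(dqaly < 0 & dcost < 0), mean(dqaly < 0 & dcost >= 0))
  )
  structure(list(draws = draws, intervals = intervals, scatter = scatter,
                 quadrants = quadrants, comparison = comparison,
                 n_draws = n_draws, seed = seed),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result> ", x$n_draws, " draws, ", x$comparison[1], " vs ",
      x$comparison[2], "\n", sep = "")
  print(as.data.frame(x$intervals), row.names = FALSE, digits = 6)
  print(as.data.frame(x$quadrants), row.names = FALSE, digits = 4)
  invisible(x)
}

# ---- scenarios -------------------------------------------------------------

#' Comparators retained for scenario analysis
#'
#' No screening, FIT-mid, FIT-high, and colonoscopy: the strategies that
#' remain decision-relevant in sensitivity analysis.
#'
#' @return A strategy tibble.
#' @export
core_scenario_strategies <- function() {
  dplyr::bind_rows(strategy("none"), strategy("FIT-mid"),
                   strategy("FIT-high"), strategy("colonoscopy"))
}

#' Registered sensitivity-analysis scenarios
#'
#' Each scenario is a named modification of the base-case parameters and/or
#' strategy definitions: biennial FIT, differential first-screen adherence
#' by modality, reduced subsequent adherence for annual stool tests,
#' administrative cost per screening test, chemotherapy costs without
#' biologic agents, a 50% higher FIT kit cost, and exclusion of nonmedical
#' (time and travel) costs.
#'
#' @return Named list of scenario definitions (`title`, `apply`).
#' @export
scenario_definitions <- function() {
  set_subsequent <- function(strategies, modalities, value) {
    i <- strategies$modality %in% modalities
    strategies$subsequent_adherence[i] <- value
    strategies
  }
  stool_annual <- c("FOBT-low", "FOBT-high", "FIT-low", "FIT-mid", "FIT-high")
  list(
    base_case = list(
      title = "Base case",
      apply = function(params, strategies) list(params = params, strategies = strategies)
    ),
    biennial_fit = list(
      title = "Biennial FIT screening (versus annual)",
      apply = function(params, strategies) {
        i <- grepl("^FIT", strategies$modality)
        strategies$interval_years[i] <- 2L
        list(params = params, strategies = strategies)
      }
    ),
    differential_first_adherence = list(
      title = "Differential initial adherence (FIT/FDNA 60%, FOBT 50%, CTC 40%, colonoscopy and flex sig 30%)",
      apply = function(params, strategies) {
        map <- c("FIT-low" = 0.60, "FIT-mid" = 0.60, "FIT-high" = 0.60,
                 "FDNA-SDT1" = 0.60, "FDNA-SDT2" = 0.60,
                 "FOBT-low" = 0.50, "FOBT-high" = 0.50,
                 "CTC" = 0.40, "colonoscopy" = 0.30, "flex_sig" = 0.30)
        i <- strategies$modality %in% names(map)
        strategies$first_adherence[i] <- map[strategies$modality[i]]
        list(params = params, strategies = strategies)
      }
    ),
    reduced_subsequent_adherence_40 = list(
      title = "Subsequent adherence for FITs and FOBTs reduced from 63% to 40%",
      apply = function(params, strategies) {
        list(params = params,
             strategies = set_subsequent(strategies, stool_annual, 0.40))
      }
    ),
    reduced_subsequent_adherence_20 = list(
      title = "Subsequent adherence for FITs and FOBTs reduced from 63% to 20%",
      apply = function(params, strategies) {
        list(params = params,
             strategies = set_subsequent(strategies, stool_annual, 0.20))
      }
    ),
    admin_cost_10 = list(
      title = "CAN$10 administrative cost per screening test",
      apply = function(params, strategies) {
        list(params = param_set(params, "costs.admin_per_test", 10),
             strategies = strategies)
      }
    ),
    admin_cost_30 = list(
      title = "CAN$30 administrative cost per screening test",
      apply = function(params, strategies) {
        list(params = param_set(params, "costs.admin_per_test", 30),
             strategies = strategies)
      }
    ),
    admin_cost_50 = list(
      title = "CAN$50 administrative cost per screening test",
      apply = function(params, strategies) {
        list(params = param_set(params, "costs.admin_per_test", 50),
             strategies = strategies)
      }
    ),
    chemo_without_biologics = list(
      title = "CRC management costs without biologic chemotherapy (stages II-IV CAN$35,844 / 80,345 / 99,574)",
      apply = function(params, strategies) {
        p <- param_set(params, "costs.crc_management.stage_ii", 35844)
        p <- param_set(p, "costs.crc_management.stage_iii", 80345)
        p <- param_set(p, "costs.crc_management.stage_iv", 99574)
        list(params = p, strategies = strategies)
      }
    ),
    fit_cost_plus_50 = list(
      title = "FIT direct cost increased by 50%",
      apply = function(params, strategies) {
        list(params = param_set(params, "costs.direct.FIT",
                                param_get(params, "costs.direct.FIT") * 1.5),
             strategies = strategies)
      }
    ),
    exclude_nonmedical_costs = list(
      title = "Nonmedical (time and travel) costs excluded",
      apply = function(params, strategies) {
        p <- params
        for (nm in names(p$costs$nonmedical)) {
          p <- param_set(p, paste0("costs.nonmedical.", nm), 0)
        }
        list(params = p, strategies = strategies)
      }
    )
  )
}

#' Run one registered scenario
#'
#' Applies the scenario's overrides to the base case and re-runs the
#' strategy evaluation and incremental analysis.
#'
#' @param scenario_name Name from [scenario_definitions()].
#' @param base_params Base `crc_parameters`.
#' @param strategies Strategy tibble (default: no screening, FIT-mid,
#'   FIT-high, colonoscopy — the comparators that remain relevant in
#'   sensitivity analysis).
#' @param engine Evaluation engine (see [simulate_strategies()]).
#' @return A `cea_result`; the evaluated results table is in
#'   `$table`, the scenario name in `attr(, "scenario")`.
#' @export
scenario_run <- function(scenario_name, base_params = base_case_parameters(),
                         strategies = core_scenario_strategies(),
                         engine = "expectation") {
  defs <- scenario_definitions()
  if (!scenario_name %in% names(defs)) {
    stop("unknown scenario '", scenario_name, "'; registered scenarios: ",
         paste(names(defs), collapse = ", "), call. = FALSE)
  }
  mod <- defs[[scenario_name]]$apply(base_params, strategies)
  res <- simulate_strategies(mod$params, mod$strategies, engine = engine)
  out <- incremental_analysis(res)
  attr(out, "scenario") <- scenario_name
  attr(out, "results") <- res
  out
}
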