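test_that("published strategy means reproduce the known dominance pattern", {
  cea <- incremental_analysis(published_table4)
  df <- tidy(cea)
  frontier <- df$label[df$on_frontier]
  expect_setequal(frontier, c("FIT-mid", "FIT-high"))
  expect_true(all(df$strongly_dominated[!df$label %in% frontier]))
  # no screening is more costly and less effective than FIT-mid
  expect_true(df$strongly_dominated[df$label == "none"])
  # the ICER of FIT-high vs FIT-mid from the rounded entries
  icer <- df$icer[df$label == "FIT-high"]
  expect_equal(icer, (2004 - 1833) / (11.302 - 11.300))
  expect_equal(icer, 85500)
  expect_equal(df$comparator[df$label == "FIT-high"], "FIT-mid")
})

test_that("the frontier matches a brute-force blend oracle on random instances", {
  set.seed(8675309)
  for (rep in 1:400) {
    n <- sample(2:8, 1)
    df <- tibble::tibble(
      label = paste0("s", seq_len(n)),
      cost = stats::runif(n, 1000, 3000),
      qaly = 11 + stats::runif(n, 0, 0.1))
    got <- tidy(incremental_analysis(df))
    want_frontier <- df$label[oracle_frontier(df)]
    expect_setequal(got$label[got$on_frontier], want_frontier)
    # strong dominance agrees with the direct pairwise definition
    strong <- vapply(seq_len(n), function(i) {
      any(df$cost <= df$cost[i] & df$qaly >= df$qaly[i] &
            (df$cost < df$cost[i] | df$qaly > df$qaly[i]))
    }, logical(1))
    expect_setequal(got$label[got$strongly_dominated], df$label[strong])
  }
})

test_that("frontier ICERs increase strictly and survive permutation", {
  set.seed(99)
  df <- tibble::tibble(label = paste0("s", 1:8),
                       cost = stats::runif(8, 1000, 3000),
                       qaly = 11 + stats::runif(8, 0, 0.1))
  t1 <- tidy(incremental_analysis(df))
  icers <- t1$icer[t1$on_frontier & !is.na(t1$icer)]
  expect_true(all(diff(icers) > 0) || length(icers) < 2)
  # permuting the input rows changes nothing per label
  t2 <- tidy(incremental_analysis(df[sample(8), ]))
  expect_identical(t1, t2)
})

test_that("degenerate inputs are flagged, not mangled", {
  expect_error(incremental_analysis(published_table4[1, ]), "at least two")
  dup <- published_table4[c(1, 1), ]
  expect_error(incremental_analysis(dup), "duplicate")

  # identical cost/QALY under distinct labels: neither dominated, no ICER
  tie <- tibble::tibble(label = c("a", "b", "c"),
                        cost = c(1000, 1500, 1500),
                        qaly = c(11.0, 11.2, 11.2))
  df <- tidy(incremental_analysis(tie))
  expect_false(any(df$strongly_dominated[df$label %in% c("b", "c")]))
  expect_true(all(df$on_frontier[df$label %in% c("b", "c")]))
  expect_match(df$note[df$label == "c"], "tie")
  expect_true(is.na(df$icer[df$label == "c"]))
  expect_false(is.na(df$icer[df$label == "b"]))
})

psa_strats <- dplyr::bind_rows(strategy("none"), strategy("FIT-mid"))

test_that("PSA is seed-deterministic with sound intervals and quadrants", {
  psa <- run_psa(psa_strats, base_params, n_draws = 6, seed = 123)
  psa2 <- run_psa(psa_strats, base_params, n_draws = 6, seed = 123)
  expect_identical(psa$draws, psa2$draws)

  # quadrant fractions partition the draws
  expect_equal(sum(psa$quadrants$fraction), 1)
  expect_equal(nrow(psa$scatter), 6)

  # intervals are the empirical type-7 percentiles of the draws
  fit <- psa$draws[psa$draws$label == "FIT-mid", ]
  expect_equal(psa$intervals$cost_lo[psa$intervals$label == "FIT-mid"],
               stats::quantile(fit$cost, 0.025, type = 7, names = FALSE))
  expect_equal(psa$intervals$qaly_hi[psa$intervals$label == "FIT-mid"],
               stats::quantile(fit$qaly, 0.975, type = 7, names = FALSE))
  # the interval brackets the mean
  expect_true(with(psa$intervals, all(cost_lo <= mean_cost & mean_cost <= cost_hi)))

  # screening always adds QALYs over no screening across parameter draws
  expect_true(all(psa$scatter$delta_qaly > 0))
})

test_that("zero-variance distributions collapse the PSA to the base case", {
  degenerate <- list(list(parameter_path = "transitions.adv_to_crc",
                          family = "triangular",
                          args = list(min = 0.048, mode = 0.048, max = 0.048)))
  psa <- run_psa(psa_strats, base_params, specs = degenerate,
                 n_draws = 3, seed = 5)
  expect_equal(psa$intervals$cost_lo, psa$intervals$cost_hi)
  expect_equal(psa$intervals$cost_lo, psa$intervals$mean_cost)
  base <- run_cohort_expectation(strategy("FIT-mid"), base_params)
  expect_equal(psa$intervals$mean_cost[psa$intervals$label == "FIT-mid"],
               base$mean_cost)
})

test_that("PSA rejects invalid comparisons and specs", {
  expect_error(run_psa(psa_strats, base_params, n_draws = 2,
                       comparison = c("CTC", "none")),
               "comparison")
  bad <- list(list(parameter_path = "tests.colonoscopy.specificity",
                   family = "beta", args = list(shape1 = 1, shape2 = 1)))
  expect_error(run_psa(psa_strats, base_params, specs = bad, n_draws = 2),
               "excluded from the PSA")
})

test_that("scenario overrides modify exactly what they claim", {
  strategies <- core_scenario_strategies()
  base_res <- simulate_strategies(base_params, strategies)

  # the scenario registry lists every sensitivity block
  expect_setequal(
    names(scenario_definitions()),
    c("base_case", "biennial_fit", "differential_first_adherence",
      "reduced_subsequent_adherence_40", "reduced_subsequent_adherence_20",
      "admin_cost_10", "admin_cost_30", "admin_cost_50",
      "chemo_without_biologics", "fit_cost_plus_50",
      "exclude_nonmedical_costs"))

  # base-case scenario is the identity
  same <- attr(scenario_run("base_case", base_params, strategies), "results")
  expect_equal(same$cost, base_res$cost)
  expect_equal(same$qaly, base_res$qaly)

  # biennial FIT: roughly half the testing volume, less disease prevented
  bi <- attr(scenario_run("biennial_fit", base_params, strategies), "results")
  for (l in c("FIT-mid", "FIT-high")) {
    expect_lt(bi$primary_tests[bi$label == l],
              0.7 * base_res$primary_tests[base_res$label == l])
    expect_lt(bi$qaly[bi$label == l], base_res$qaly[base_res$label == l])
    expect_gt(bi$cancers[bi$label == l], base_res$cancers[base_res$label == l])
  }
  expect_equal(bi$cost[bi$label == "none"],
               base_res$cost[base_res$label == "none"])

  # administrative costs scale with testing frequency: an annual stool
  # programme absorbs a far larger increase than ten-yearly colonoscopy
  ad <- attr(scenario_run("admin_cost_50", base_params, strategies), "results")
  rise <- ad$cost - base_res$cost[match(ad$label, base_res$label)]
  expect_equal(rise[ad$label == "none"], 0)
  expect_gt(rise[ad$label == "FIT-mid"], 3 * rise[ad$label == "colonoscopy"])
  expect_gt(rise[ad$label == "colonoscopy"], 0)

  # removing biologic chemotherapy costs lowers every arm's cost,
  # no-screening (all cancer management) most of all
  nb <- attr(scenario_run("chemo_without_biologics", base_params, strategies),
             "results")
  drop <- base_res$cost[match(nb$label, base_res$label)] - nb$cost
  expect_true(all(drop > 0))
  expect_equal(which.max(drop), which(nb$label == "none"))

  # differential adherence leaves the no-screening arm untouched and
  # reduces colonoscopy uptake hardest
  da <- attr(scenario_run("differential_first_adherence", base_params,
                          strategies), "results")
  expect_equal(da$qaly[da$label == "none"],
               base_res$qaly[base_res$label == "none"])
  expect_lt(da$qaly[da$label == "colonoscopy"],
            base_res$qaly[base_res$label == "colonoscopy"])

  # lower subsequent stool adherence cuts FIT testing volume and benefit
  r40 <- attr(scenario_run("reduced_subsequent_adherence_40", base_params,
                           strategies), "results")
  expect_lt(r40$primary_tests[r40$label == "FIT-mid"],
            base_res$primary_tests[base_res$label == "FIT-mid"])
  expect_lt(r40$qaly[r40$label == "FIT-mid"],
            base_res$qaly[base_res$label == "FIT-mid"])
  expect_equal(r40$qaly[r40$label == "colonoscopy"],
               base_res$qaly[base_res$label == "colonoscopy"])

  expect_error(scenario_run("warp_drive", base_params), "registered scenarios")
})
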