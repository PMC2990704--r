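test_that("base case reproduces the published model inputs", {
  p <- base_params

  # age-stratified epidemiology
  expect_equal(p$strata$young$prev_nonadvanced, 0.171)
  expect_equal(p$strata$young$prev_advanced, 0.038)
  expect_equal(p$strata$young$prev_crc, 0.001)
  expect_equal(p$strata$young$annual_background_death, 0.005)
  expect_equal(p$strata$old$prev_nonadvanced, 0.173)
  expect_equal(p$strata$old$prev_advanced, 0.082)
  expect_equal(p$strata$old$prev_crc, 0.007)
  expect_equal(p$strata$old$annual_background_death, 0.018)

  # adenoma-carcinoma transitions
  expect_equal(p$transitions$normal_to_nonadv_no_history, 0.02)
  expect_equal(p$transitions$normal_to_nonadv_history, 0.038)
  expect_equal(p$transitions$nonadv_to_adv, 0.019)
  expect_equal(p$transitions$adv_to_crc, 0.048)

  # stage distributions by detection context (each sums to one)
  expect_equal(unname(unlist(p$stage_distributions$unscreened)),
               c(0.145, 0.356, 0.280, 0.219))
  expect_equal(unname(unlist(p$stage_distributions$stool)),
               c(0.305, 0.318, 0.243, 0.134))
  expect_equal(unname(unlist(p$stage_distributions$structural)),
               c(0.425, 0.226, 0.267, 0.082))
  for (d in p$stage_distributions) expect_equal(sum(unlist(d)), 1)

  # five-year stage mortality
  expect_equal(unname(unlist(p$stage_mortality$five_year)),
               c(0.068, 0.175, 0.405, 0.919))

  # test performance
  expect_equal(p$tests[["FIT-mid"]]$sens_advanced, 0.540)
  expect_equal(p$tests[["FIT-mid"]]$sens_cancer, 0.810)
  expect_equal(p$tests[["FIT-mid"]]$specificity, 0.960)
  expect_equal(p$tests[["FIT-high"]],
               list(sens_nonadvanced = 0.180, sens_advanced = 0.610,
                    sens_cancer = 0.940, specificity = 0.910))
  expect_equal(p$tests$colonoscopy$sens_cancer, 0.966)
  expect_equal(p$tests$colonoscopy_after_ctc$sens_advanced, 0.970)
  expect_equal(p$tests[["FDNA-SDT1"]]$sens_cancer, 0.516)
  expect_equal(p$tests[["FOBT-low"]]$specificity, 0.952)
  expect_equal(p$tests$flex_sig$sens_advanced, 0.750)
  expect_equal(p$tests$CTC$specificity, 0.890)

  # adherence, complications, utilities, histology
  expect_equal(unname(unlist(p$adherence)), c(0.68, 0.63, 0.81))
  expect_equal(p$complications$perf_tx_colo, 0.0024)
  expect_equal(p$complications$death_after_perforation, 0.049)
  expect_equal(unname(unlist(p$utilities)), c(0.91, 0.74, 0.46))
  expect_equal(p$histology$adenomatous_lt10mm, 0.41)
  expect_equal(p$histology$adenomatous_ge10mm, 0.82)

  # costs (2008 CAN$)
  expect_equal(p$costs$direct$FIT, 19)
  expect_equal(p$costs$direct$FOBT, 12)
  expect_equal(p$costs$direct$FDNA, 336)
  expect_equal(p$costs$direct$colonoscopy_dx, 857)
  expect_equal(p$costs$direct$colonoscopy_tx, 999)
  expect_equal(p$costs$nonmedical$colonoscopy, 308)
  expect_equal(p$costs$complication$perforation, 31223)
  expect_equal(unname(unlist(p$costs$crc_management)),
               c(25049, 36143, 96768, 134014))

  # structural settings
  expect_equal(p$settings$discount_rate, 0.05)
  expect_equal(p$settings$screen_start_age, 50)
  expect_equal(p$settings$screen_stop_age, 75)
  expect_identical(validate_parameters(p)$transitions, p$transitions)
})

test_that("validation rejects out-of-range and inconsistent inputs", {
  p <- base_params
  p$strata$young$prev_crc <- 1.5
  expect_error(validate_parameters(p), "strata.young.prev_crc")

  p <- base_params
  p$transitions$normal_to_nonadv_history <- 0.01 # below the no-history rate
  expect_error(validate_parameters(p), "normal_to_nonadv_history")

  p <- base_params
  p$stage_distributions$unscreened$stage_iv <- 0.5 # no longer sums to 1
  expect_error(validate_parameters(p), "stage_distributions.unscreened")

  p <- base_params
  p$utilities$early_crc <- 0.95 # above no-CRC utility
  expect_error(validate_parameters(p), "utilities")

  p <- base_params
  p$costs$crc_management$stage_ii <- 20000 # below stage I
  expect_error(validate_parameters(p), "crc_management")
})

test_that("fixture round trip is exact and the loader validates", {
  f <- withr::local_tempfile(fileext = ".yaml")
  emit_parameter_fixture(f)
  p2 <- load_parameters(f)
  expect_identical(unclass(p2), unclass(base_case_parameters()))

  # out-of-range override is rejected with its path
  txt <- paste(readLines(f), collapse = "\n")
  bad <- sub("prev_crc: 0.001", "prev_crc: 1.5", txt)
  expect_error(load_parameters(bad), "prev_crc")

  # unknown keys are rejected
  expect_error(load_parameters("inherit_base_case: true\nbogus_section: 1\n"),
               "bogus_section")

  # missing keys are an error unless inheritance is requested
  expect_error(load_parameters("transitions:\n  adv_to_crc: 0.05\n"),
               "inherit_base_case")
  p3 <- load_parameters(
    "inherit_base_case: true\ntransitions:\n  adv_to_crc: 0.05\n")
  expect_equal(p3$transitions$adv_to_crc, 0.05)
  expect_equal(p3$transitions$nonadv_to_adv, 0.019)
  expect_equal(p3$costs$direct$FIT, 19)
})

test_that("loader renormalises near-miss stage distributions with a note", {
  cfg <- paste(
    "inherit_base_case: true",
    "stage_distributions:",
    "  unscreened:",
    "    stage_i: 0.144",
    "    stage_ii: 0.356",
    "    stage_iii: 0.280",
    "    stage_iv: 0.219",
    sep = "\n")
  p <- load_parameters(cfg)
  expect_equal(sum(unlist(p$stage_distributions$unscreened)), 1)
  expect_match(attr(p, "renormalisation"), "unscreened")
})

test_that("parameter paths address every level of the bundle", {
  expect_equal(param_get(base_params, "transitions.adv_to_crc"), 0.048)
  expect_equal(param_get(base_params, "costs.crc_management.stage_iv"), 134014)
  p <- param_set(base_params, "adherence.first_screen", 0.5)
  expect_equal(p$adherence$first_screen, 0.5)
  expect_equal(base_params$adherence$first_screen, 0.68) # original untouched
  expect_error(param_get(base_params, "transitions.unknown_rate"), "unknown")
  expect_error(param_set(base_params, "no.such.path", 1), "unknown")
})

test_that("PSA sampling honours supports, determinism, and exclusions", {
  # empty specs: identity
  expect_identical(unclass(sample_psa_parameters(base_params, list(), seed = 1)),
                   unclass(base_params))

  # identical seeds give identical draws
  s1 <- sample_psa_parameters(base_params, seed = 99)
  s2 <- sample_psa_parameters(base_params, seed = 99)
  expect_identical(unclass(s1), unclass(s2))

  # triangular draws on the advanced-adenoma-to-CRC rate stay in range
  tri <- list(list(parameter_path = "transitions.adv_to_crc",
                   family = "triangular",
                   args = list(min = 0.03, mode = 0.048, max = 0.07)))
  set.seed(42)
  draws <- replicate(500, {
    sample_psa_parameters(base_params, tri)$transitions$adv_to_crc
  })
  expect_true(all(draws >= 0.03 & draws <= 0.07))
  expect_gt(stats::sd(draws), 0)

  # test-performance paths are refused
  bad <- list(list(parameter_path = "tests.FIT-mid.sens_cancer",
                   family = "beta", args = list(shape1 = 2, shape2 = 2)))
  expect_error(sample_psa_parameters(base_params, bad), "excluded from the PSA")

  # stage distributions remain proper after sampling everything
  s <- sample_psa_parameters(base_params, seed = 7)
  for (d in s$stage_distributions) expect_equal(sum(unlist(d)), 1)
  expect_s3_class(validate_parameters(s), "crc_parameters")
})

test_that("an untruncated beta spec reproduces its analytic mean", {
  # mean 0.68 with dispersion nu = 20: shape 13.6 / 6.4
  spec <- list(parameter_path = "adherence.first_screen", family = "beta",
               args = list(shape1 = 13.6, shape2 = 6.4))
  set.seed(1234)
  draws <- replicate(10000, {
    crcscreen:::sample_spec_value(spec)
  })
  analytic_mean <- 13.6 / 20
  analytic_sd <- sqrt(13.6 * 6.4 / (20^2 * 21))
  se <- analytic_sd / sqrt(length(draws))
  expect_lt(abs(mean(draws) - analytic_mean), 3 * se)
})

test_that("the fixture's distribution block covers the ranged inputs only", {
  specs <- default_distribution_specs()
  paths <- vapply(specs, `[[`, character(1), "parameter_path")

  # no test-performance entries
  expect_false(any(grepl("^tests\\.", paths)))
  # no specs for inputs printed without a range (mortality, utilities,
  # management costs)
  expect_false(any(grepl("^stage_mortality|^utilities|crc_management", paths)))

  # the perforation cost range is present and spans the printed interval
  perf <- specs[[which(paths == "costs.complication.perforation")]]
  expect_equal(perf$args$min, 23500)
  expect_equal(perf$args$max, 39000)

  # families follow the stated rules: triangular for transitions/adherence,
  # beta for proportions, log-normal for costs
  fam <- vapply(specs, `[[`, character(1), "family")
  expect_true(all(fam[grepl("^transitions|^adherence", paths)] == "triangular"))
  expect_true(all(fam[grepl("^strata|^stage_distributions|^complications", paths)] == "beta"))
  expect_true(all(fam[grepl("^costs", paths)] == "log-normal"))

  # file round trip of the block
  f <- withr::local_tempfile(fileext = ".yaml")
  emit_parameter_fixture(f)
  reread <- load_distribution_specs(f)
  expect_length(reread, length(specs))
  expect_setequal(vapply(reread, `[[`, character(1), "parameter_path"), paths)
})
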