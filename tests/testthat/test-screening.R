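test_that("strategy constructors enforce the schedule invariants", {
  s <- strategy("FIT-mid")
  expect_equal(s$interval_years, 1L)
  expect_equal(strategy("FDNA-SDT2")$interval_years, 3L)
  expect_equal(strategy("colonoscopy")$interval_years, 10L)
  expect_equal(strategy("flex_sig")$interval_years, 5L)
  expect_equal(strategy("CTC")$interval_years, 5L)
  expect_equal(c(s$start_age, s$stop_age), c(50, 75))
  expect_error(strategy("FIT-mid", interval_years = 0), "interval")
  expect_error(strategy("FIT-mid", start_age = 80, stop_age = 75), "start_age")
  expect_error(strategy("barium_enema"), "unknown modality")
  expect_equal(nrow(default_strategies()), 11)
})

test_that("surveillance intervals follow the findings", {
  expect_equal(surveillance_interval("advanced_adenoma"), 3L)
  expect_equal(surveillance_interval("nonadvanced_adenoma"), 5L)
  expect_equal(surveillance_interval("crc_resected"), 3L)
  expect_error(surveillance_interval("hyperplastic"), "unknown finding")
})

test_that("screening eligibility applies age, interval, precedence and exemption", {
  strat <- strategy("FIT-mid")
  mk <- function(age = 60, state = "no_lesion", surv = NA_integer_,
                 exempt = NA_integer_, last = NA_integer_) {
    tibble::tibble(age = age, state = state, surveillance_due_year = surv,
                   screening_exempt_until = exempt, last_offer_year = last)
  }
  # beyond the stop age: nothing is offered
  expect_equal(is_screening_due(mk(age = 76), strat, 26), "none")
  # surveillance due takes precedence over a due primary screen
  expect_equal(is_screening_due(mk(surv = 10), strat, 10), "surveillance")
  # annual FIT due one year after the last offer
  expect_equal(is_screening_due(mk(last = 9), strat, 10), "primary")
  expect_equal(is_screening_due(mk(last = 10), strat, 10), "none")
  # post-colonoscopy exemption suppresses primary screening
  expect_equal(is_screening_due(mk(exempt = 15), strat, 10), "none")
  expect_equal(is_screening_due(mk(exempt = 10), strat, 10), "primary")
  # pending (future) surveillance replaces routine screening
  expect_equal(is_screening_due(mk(surv = 12), strat, 10), "none")
  # diagnosed patients and the dead are not screened
  expect_equal(is_screening_due(mk(state = "crc_diagnosed"), strat, 10), "none")
  expect_equal(is_screening_due(mk(state = "dead"), strat, 10), "none")
  # a ten-yearly colonoscopy offered at year 0 is not due again until year 10
  colo <- strategy("colonoscopy")
  expect_equal(is_screening_due(mk(age = 59, last = 0), colo, 9), "none")
  expect_equal(is_screening_due(mk(age = 60, last = 0), colo, 10), "primary")
})

test_that("test positivity follows sensitivity by lesion class and specificity", {
  tests <- base_params$tests
  expect_equal(test_positive_prob("crc_undiagnosed", tests$colonoscopy), 0.966)
  expect_equal(test_positive_prob("advanced_adenoma", tests$colonoscopy_after_ctc), 0.970)
  expect_equal(test_positive_prob("no_lesion", tests[["FIT-mid"]]), 1 - 0.960)
  expect_equal(test_positive_prob("nonadvanced_adenoma", tests[["FIT-mid"]]), 0.180)

  perfect <- list(sens_nonadvanced = 1, sens_advanced = 1, sens_cancer = 1,
                  specificity = 1)
  states <- c("no_lesion", "nonadvanced_adenoma", "advanced_adenoma",
              "crc_undiagnosed")
  expect_equal(test_positive_prob(states, perfect), c(0, 1, 1, 1))
  expect_equal(apply_test(states, perfect), c(FALSE, TRUE, TRUE, TRUE))
  expect_error(test_positive_prob("dead", tests$colonoscopy), "dead")
})

test_that("zero adherence reproduces the no-screening arm exactly", {
  # common random numbers: the natural-history stream is independent of the
  # screening stream, so never-adherent screening leaves every outcome
  # untouched
  p <- base_params
  p$adherence$colonoscopy_after_positive <- 0
  null_fit <- strategy("FIT-mid", first_adherence = 0, subsequent_adherence = 0)
  a <- run_microsim(null_fit, p, n_persons = 4000, seed = 31)
  b <- run_microsim(strategy("none"), p, n_persons = 4000, seed = 31)
  expect_equal(get_total(a, "cancers"), get_total(b, "cancers"))
  expect_equal(get_total(a, "crc_deaths"), get_total(b, "crc_deaths"))
  expect_equal(get_total(a, "primary_tests"), 0)
  expect_equal(a$mean_cost, b$mean_cost)
  expect_equal(a$mean_qaly, b$mean_qaly)
})

test_that("a perfect annual test clears prevalent disease at the first offer", {
  p <- base_params
  p$tests[["FIT-mid"]] <- list(sens_nonadvanced = 1, sens_advanced = 1,
                               sens_cancer = 1, specificity = 1)
  p$tests$colonoscopy <- list(sens_nonadvanced = 1, sens_advanced = 1,
                              sens_cancer = 1, specificity = 1)
  p$adherence$colonoscopy_after_positive <- 1
  p$settings$surveillance_adherence <- 1
  # disable the post-colonoscopy decade pause so annual screening resumes
  # immediately after a clean examination: this isolates the
  # disease-clearing property from scheduling gaps
  p$settings$clean_colonoscopy_exempt_years <- 0
  perfect <- strategy("FIT-mid", first_adherence = 1, subsequent_adherence = 1)
  tal <- run_microsim(perfect, p, n_persons = 4000, seed = 77)

  # every prevalent cancer is screen-detected in the offer year: no
  # symptomatic diagnosis occurs at the first offer
  sympt_all <- get_total(tal, "symptomatic_diagnoses")
  sympt_late <- get_total(tal, "symptomatic_diagnoses_after_year0")
  expect_equal(sympt_all - sympt_late, 0)

  # while screening is offered (through age 75), symptomatic cancer can only
  # arise through the narrow surveillance-gap chain (new adenoma -> advanced
  # -> cancer -> symptoms between surveillance colonoscopies); its expected
  # count at this cohort size is well under one, so observing five or more
  # would indicate a leak in the screening cascade, not chance
  expect_lt(get_total(tal, "symptomatic_diagnoses_in_screening_era"), 5)

  # after screening stops, disease arises and presents unchecked
  expect_gt(sympt_late, 0)
})

test_that("follow-up colonoscopy occurs for the stated share of positives", {
  tal <- run_microsim(strategy("FIT-mid"), base_params,
                      n_persons = 30000, seed = 13)
  pos <- get_total(tal, "positive_tests")
  fu <- get_total(tal, "colonoscopies_followup")
  expect_gt(pos, 1000)
  expect_lt(abs(fu / pos - 0.81), 3 * sqrt(0.81 * 0.19 / pos))
})

test_that("colonoscopy tallies decompose by origin", {
  for (s in list(strategy("FIT-mid"), strategy("colonoscopy"))) {
    tal <- run_microsim(s, base_params, n_persons = 8000, seed = 3)
    expect_equal(get_total(tal, "colonoscopies"),
                 get_total(tal, "colonoscopies_primary") +
                   get_total(tal, "colonoscopies_followup") +
                   get_total(tal, "colonoscopies_surveillance"))
  }
  # a primary-colonoscopy programme has no follow-up colonoscopies
  tal <- run_microsim(strategy("colonoscopy"), base_params,
                      n_persons = 8000, seed = 3)
  expect_equal(get_total(tal, "colonoscopies_followup"), 0)
  expect_gt(get_total(tal, "colonoscopies_primary"), 0)
})
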