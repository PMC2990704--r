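#' Base-case model parameters
#'
#' Returns the complete base-case input bundle for the screening model:
#' age-stratified adenoma/CRC prevalence and background mortality,
#' annual transition probabilities of the adenoma-carcinoma sequence,
#' stage distributions at diagnosis by detection context, stage-specific
#' five-year CRC mortality, per-person test performance for every screening
#' modality, adherence, endoscopic complication risks, direct and nonmedical
#' costs (2008 CAN$), stage-based CRC management costs, health-state
#' utilities, polyp histology fractions, and structural settings
#' (discount rate, screening ages, horizon).
#'
#' @return A `crc_parameters` object (a validated nested list).
#' @export
#' @examples
#' p <- base_case_parameters()
#' p$transitions$adv_to_crc
base_case_parameters <- function() {
  p <- list(
    strata = list(
      young = list(
        label = "50-64",
        prev_nonadvanced = 0.171,
        prev_advanced = 0.038,
        prev_crc = 0.001,
        annual_background_death = 0.005
      ),
      old = list(
        label = "65-75",
        prev_nonadvanced = 0.173,
        prev_advanced = 0.082,
        prev_crc = 0.007,
        annual_background_death = 0.018
      )
    ),
    transitions = list(
      normal_to_nonadv_no_history = 0.02,
      normal_to_nonadv_history = 0.038,
      nonadv_to_adv = 0.019,
      adv_to_crc = 0.048
    ),
    stage_distributions = list(
      unscreened = list(stage_i = 0.145, stage_ii = 0.356, stage_iii = 0.280, stage_iv = 0.219),
      stool      = list(stage_i = 0.305, stage_ii = 0.318, stage_iii = 0.243, stage_iv = 0.134),
      structural = list(stage_i = 0.425, stage_ii = 0.226, stage_iii = 0.267, stage_iv = 0.082)
    ),
    stage_mortality = list(
      five_year = list(stage_i = 0.068, stage_ii = 0.175, stage_iii = 0.405, stage_iv = 0.919)
    ),
    tests = list(
      "FOBT-low"  = list(sens_nonadvanced = 0.052, sens_advanced = 0.107, sens_cancer = 0.129, specificity = 0.952),
      "FOBT-high" = list(sens_nonadvanced = 0.030, sens_advanced = 0.074, sens_cancer = 0.500, specificity = 0.980),
      "FIT-low"   = list(sens_nonadvanced = 0.070, sens_advanced = 0.224, sens_cancer = 0.660, specificity = 0.950),
      "FIT-mid"   = list(sens_nonadvanced = 0.180, sens_advanced = 0.540, sens_cancer = 0.810, specificity = 0.960),
      "FIT-high"  = list(sens_nonadvanced = 0.180, sens_advanced = 0.610, sens_cancer = 0.940, specificity = 0.910),
      "colonoscopy" = list(sens_nonadvanced = 0.850, sens_advanced = 0.875, sens_cancer = 0.966, specificity = 1.000),
      "colonoscopy_after_ctc" = list(sens_nonadvanced = 0.900, sens_advanced = 0.970, sens_cancer = 0.990, specificity = 1.000),
      "CTC" = list(sens_nonadvanced = 0.760, sens_advanced = 0.900, sens_cancer = 0.966, specificity = 0.890),
      "flex_sig" = list(sens_nonadvanced = 0.650, sens_advanced = 0.750, sens_cancer = 0.750, specificity = 1.000),
      "FDNA-SDT2" = list(sens_nonadvanced = 0.040, sens_advanced = 0.447, sens_cancer = 0.580, specificity = 0.840),
      "FDNA-SDT1" = list(sens_nonadvanced = 0.076, sens_advanced = 0.151, sens_cancer = 0.516, specificity = 0.944)
    ),
    adherence = list(
      first_screen = 0.68,
      subsequent_screen = 0.63,
      colonoscopy_after_positive = 0.81
    ),
    complications = list(
      bleed_dx_colo = 0.0003,
      bleed_tx_colo = 0.005,
      perf_dx_colo = 0.0009,
      perf_tx_colo = 0.0024,
      perf_flexsig = 0.0002,
      perf_ctc = 0,
      death_after_perforation = 0.049
    ),
    costs = list(
      direct = list(
        FOBT = 12, FIT = 19, FDNA = 336, flex_sig = 650, CTC = 582,
        colonoscopy_dx = 857, colonoscopy_tx = 999
      ),
      nonmedical = list(
        FOBT = 36, FIT = 36, FDNA = 36, colonoscopy = 308, CTC = 105, flex_sig = 105
      ),
      complication = list(bleed = 3194, perforation = 31223),
      crc_management = list(
        stage_i = 25049, stage_ii = 36143, stage_iii = 96768, stage_iv = 134014
      ),
      admin_per_test = 0
    ),
    utilities = list(no_crc = 0.91, early_crc = 0.74, advanced_crc = 0.46),
    histology = list(adenomatous_lt10mm = 0.41, adenomatous_ge10mm = 0.82),
    settings = list(
      discount_rate = 0.05,
      cycle_length = 1,
      screen_start_age = 50,
      screen_stop_age = 75,
      max_age = 100,
      crc_survival_window = 5,
      symptomatic_presentation_annual_prob = 0.4,
      clean_colonoscopy_exempt_years = 10,
      surveillance_adherence = 0.81
    )
  )
  structure(p, class = "crc_parameters")
}

# stool-based modalities share the kit-cost, nonmedical-cost and
# stage-at-diagnosis machinery
.stool_modalities <- c("FOBT-low", "FOBT-high", "FIT-low", "FIT-mid", "FIT-high",
                       "FDNA-SDT1", "FDNA-SDT2")
.structural_modalities <- c("colonoscopy", "flex_sig", "CTC")

#' @keywords internal
is_stool_modality <- function(modality) modality %in% .stool_modalities

# direct (kit/procedure) cost of a primary test, excluding follow-up
# colonoscopies which are costed inside the procedure itself
direct_test_cost <- function(modality, costs) {
  d <- costs$direct
  switch_cost <- c(
    "FOBT-low" = d$FOBT, "FOBT-high" = d$FOBT,
    "FIT-low" = d$FIT, "FIT-mid" = d$FIT, "FIT-high" = d$FIT,
    "FDNA-SDT1" = d$FDNA, "FDNA-SDT2" = d$FDNA,
    "flex_sig" = d$flex_sig, "CTC" = d$CTC
  )
  if (!modality %in% names(switch_cost)) {
    stop("no direct test cost defined for modality '", modality, "'", call. = FALSE)
  }
  unname(switch_cost[modality])
}

nonmedical_test_cost <- function(modality, costs) {
  nm <- costs$nonmedical
  switch_cost <- c(
    "FOBT-low" = nm$FOBT, "FOBT-high" = nm$FOBT,
    "FIT-low" = nm$FIT, "FIT-mid" = nm$FIT, "FIT-high" = nm$FIT,
    "FDNA-SDT1" = nm$FDNA, "FDNA-SDT2" = nm$FDNA,
    "flex_sig" = nm$flex_sig, "CTC" = nm$CTC,
    "colonoscopy" = nm$colonoscopy
  )
  if (!modality %in% names(switch_cost)) {
    stop("no nonmedical cost defined for modality '", modality, "'", call. = FALSE)
  }
  unname(switch_cost[modality])
}

#' Validate a parameter set
#'
#' Checks every structural and range invariant of the model inputs:
#' probabilities in \[0, 1\], prevalence totals below 1, stage distributions
#' summing to one (renormalised within tolerance, see [load_parameters()]),
#' nondecreasing stage mortality and management costs, ordered utilities,
#' and strictly increasing age settings. Errors name the offending path.
#'
#' @param params A `crc_parameters` object or plain nested list.
#' @return The validated (possibly renormalised) `crc_parameters` object,
#'   invisibly usable in pipelines.
#' @export
validate_parameters <- function(params) {
  fail <- function(path, msg) {
    stop("invalid parameter at '", path, "': ", msg, call. = FALSE)
  }
  chk_prob <- function(x, path) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      fail(path, "must be a probability in [0, 1]")
    }
  }
  chk_pos <- function(x, path) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
      fail(path, "must be a nonnegative number")
    }
  }

  for (s in c("young", "old")) {
    st <- params$strata[[s]]
    for (f in c("prev_nonadvanced", "prev_advanced", "prev_crc", "annual_background_death")) {
      chk_prob(st[[f]], paste("strata", s, f, sep = "."))
    }
    if (st$prev_nonadvanced + st$prev_advanced + st$prev_crc >= 1) {
      fail(paste0("strata.", s), "prevalence probabilities must sum to less than 1")
    }
  }

  tr <- params$transitions
  for (f in names(tr)) chk_prob(tr[[f]], paste0("transitions.", f))
  if (tr$normal_to_nonadv_history < tr$normal_to_nonadv_no_history) {
    fail("transitions.normal_to_nonadv_history",
         "history rate must be at least the no-history rate")
  }

  for (ctx in names(params$stage_distributions)) {
    d <- unlist(params$stage_distributions[[ctx]])
    for (i in seq_along(d)) {
      chk_prob(d[[i]], paste("stage_distributions", ctx, names(d)[i], sep = "."))
    }
    if (abs(sum(d) - 1) > 1e-9) {
      fail(paste0("stage_distributions.", ctx),
           sprintf("stage probabilities must sum to 1 (got %.6f)", sum(d)))
    }
  }

  m5 <- unlist(params$stage_mortality$five_year)
  for (i in seq_along(m5)) chk_prob(m5[[i]], paste0("stage_mortality.five_year.", names(m5)[i]))
  if (any(diff(m5) < 0)) {
    fail("stage_mortality.five_year", "five-year mortality must be nondecreasing across stages")
  }

  for (tn in names(params$tests)) {
    perf <- params$tests[[tn]]
    for (f in c("sens_nonadvanced", "sens_advanced", "sens_cancer", "specificity")) {
      chk_prob(perf[[f]], paste("tests", tn, f, sep = "."))
    }
  }

  for (f in names(params$adherence)) chk_prob(params$adherence[[f]], paste0("adherence.", f))

  cp <- params$complications
  for (f in names(cp)) chk_prob(cp[[f]], paste0("complications.", f))
  if (cp$bleed_tx_colo < cp$bleed_dx_colo) {
    fail("complications.bleed_tx_colo", "therapeutic bleed risk below diagnostic risk")
  }
  if (cp$perf_tx_colo < cp$perf_dx_colo) {
    fail("complications.perf_tx_colo", "therapeutic perforation risk below diagnostic risk")
  }

  for (grp in c("direct", "nonmedical", "complication", "crc_management")) {
    g <- params$costs[[grp]]
    for (f in names(g)) chk_pos(g[[f]], paste("costs", grp, f, sep = "."))
  }
  chk_pos(params$costs$admin_per_test, "costs.admin_per_test")
  mg <- unlist(params$costs$crc_management)
  if (any(diff(mg) < 0)) {
    fail("costs.crc_management", "management cost must be nondecreasing across stages")
  }

  ut <- params$utilities
  for (f in names(ut)) chk_prob(ut[[f]], paste0("utilities.", f))
  if (!(ut$no_crc >= ut$early_crc && ut$early_crc >= ut$advanced_crc)) {
    fail("utilities", "must satisfy no_crc >= early_crc >= advanced_crc")
  }

  for (f in names(params$histology)) chk_prob(params$histology[[f]], paste0("histology.", f))

  se <- params$settings
  chk_pos(se$discount_rate, "settings.discount_rate")
  ages <- c(se$screen_start_age, se$screen_stop_age, se$max_age)
  if (any(diff(ages) <= 0)) {
    fail("settings", "screen_start_age < screen_stop_age < max_age required")
  }
  chk_prob(se$symptomatic_presentation_annual_prob,
           "settings.symptomatic_presentation_annual_prob")
  chk_prob(se$surveillance_adherence, "settings.surveillance_adherence")

  structure(params, class = "crc_parameters")
}

#' @export
print.crc_parameters <- function(x, ...) {
  cat("<crc_parameters>\n")
  cat("  strata:     ", x$strata$young$label, "and", x$strata$old$label, "\n")
  cat("  modalities: ", paste(setdiff(names(x$tests), "colonoscopy_after_ctc"),
                              collapse = ", "), "\n")
  cat("  discount:   ", x$settings$discount_rate, " screening ages ",
      x$settings$screen_start_age, "-", x$settings$screen_stop_age,
      ", horizon ", x$settings$max_age, "\n", sep = "")
  invisible(x)
}

# ---- path access -----------------------------------------------------------

param_path_split <- function(path) strsplit(path, ".", fixed = TRUE)[[1]]

#' Get or set one parameter by dotted path
#'
#' Paths address the nested parameter list, e.g.
#' `"transitions.adv_to_crc"` or `"costs.direct.FIT"`.
#'
#' @param params A `crc_parameters` object.
#' @param path Dotted path string.
#' @param value Replacement value (for `param_set()`).
#' @return `param_get()` the value; `param_set()` the modified parameter set.
#' @export
param_get <- function(params, path) {
  out <- params
  for (key in param_path_split(path)) {
    if (!is.list(out) || is.null(out[[key]])) {
      stop("unknown parameter path '", path, "'", call. = FALSE)
    }
    out <- out[[key]]
  }
  out
}

#' @rdname param_get
#' @export
param_set <- function(params, path, value) {
  param_get(params, path) # errors on unknown path
  assign_in <- function(x, keys, value) {
    if (length(keys) == 1) {
      x[[keys]] <- value
    } else {
      x[[keys[1]]] <- assign_in(x[[keys[1]]], keys[-1], value)
    }
    x
  }
  out <- assign_in(unclass(params), param_path_split(path), value)
  structure(out, class = "crc_parameters")
}

# ---- serialisation ---------------------------------------------------------

#' Read a parameter configuration file
#'
#' The configuration is YAML mirroring the structure of
#' [base_case_parameters()]. Unknown keys are rejected. When the file sets
#' `inherit_base_case: true`, keys that are absent fall back to the base
#' case; otherwise the file must be complete. An optional
#' `psa_distributions` block (see [load_distribution_specs()]) is ignored
#' here. Stage distributions are renormalised to sum to exactly one; any
#' adjustment larger than numerical noise is recorded in the
#' `renormalisation` attribute.
#'
#' @param path Path to a YAML file, or a YAML string.
#' @return A validated `crc_parameters` object.
#' @export
load_parameters <- function(path) {
  raw <- if (length(path) == 1 && !grepl("\n", path) && file.exists(path)) {
    yaml::read_yaml(path)
  } else {
    yaml::yaml.load(paste(path, collapse = "\n"))
  }
  inherit <- isTRUE(raw$inherit_base_case)
  raw$inherit_base_case <- NULL
  raw$psa_distributions <- NULL

  base <- unclass(base_case_parameters())
  check_unknown <- function(tmpl, cfg, prefix) {
    if (!is.list(cfg) || !is.list(tmpl)) return(invisible(NULL))
    extra <- setdiff(names(cfg), names(tmpl))
    if (length(extra)) {
      stop("unknown configuration key '",
           paste0(prefix, extra[1]), "'", call. = FALSE)
    }
    for (nm in names(cfg)) {
      check_unknown(tmpl[[nm]], cfg[[nm]], paste0(prefix, nm, "."))
    }
    invisible(NULL)
  }
  check_unknown(base, raw, "")

  merge_into <- function(tmpl, cfg, prefix) {
    for (nm in names(tmpl)) {
      if (is.null(cfg[[nm]])) {
        if (!inherit) {
          stop("missing configuration key '", paste0(prefix, nm),
               "' (set inherit_base_case: true to fall back to defaults)",
               call. = FALSE)
        }
      } else if (is.list(tmpl[[nm]])) {
        tmpl[[nm]] <- merge_into(tmpl[[nm]], cfg[[nm]], paste0(prefix, nm, "."))
      } else {
        tmpl[[nm]] <- cfg[[nm]]
      }
    }
    tmpl
  }
  merged <- merge_into(base, raw, "")

  notes <- character(0)
  for (ctx in names(merged$stage_distributions)) {
    d <- unlist(merged$stage_distributions[[ctx]])
    s <- sum(d)
    if (abs(s - 1) > 1e-9) {
      if (abs(s - 1) > 0.02) {
        stop("invalid parameter at 'stage_distributions.", ctx,
             "': probabilities sum to ", format(s), call. = FALSE)
      }
      d <- d / s
      merged$stage_distributions[[ctx]] <- as.list(d)
      notes <- c(notes, sprintf("stage_distributions.%s renormalised from sum %.6f", ctx, s))
    }
  }

  out <- validate_parameters(merged)
  if (length(notes)) attr(out, "renormalisation") <- notes
  out
}

#' Write a parameter set (plus PSA distributions) to a YAML fixture
#'
#' Writes the full configuration so that [load_parameters()] on the result
#' reproduces the input exactly, and appends a `psa_distributions` block
#' holding one second-order distribution per ranged input (see
#' [default_distribution_specs()]). Test sensitivities and specificities are
#' deliberately excluded from the distribution block: sensitivity and
#' specificity are linked through an unavailable ROC curve and are explored
#' through alternative test-performance rows instead of the PSA.
#'
#' @param path Output file path.
#' @param params Parameter set to write (default the base case).
#' @param specs Distribution specs to embed (default
#'   [default_distribution_specs()]).
#' @return `path`, invisibly.
#' @export
emit_parameter_fixture <- function(path, params = base_case_parameters(),
                                   specs = default_distribution_specs()) {
  obj <- unclass(params)
  obj$psa_distributions <- purrr::map(specs, function(s) {
    c(list(parameter_path = s$parameter_path, family = s$family), s$args)
  })
  txt <- yaml::as.yaml(obj, precision = 12)
  ok <- tryCatch({
    writeLines(txt, path)
    TRUE
  }, error = function(e) {
    stop("failed to write parameter fixture to '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}

#' Read the second-order distribution block of a fixture
#'
#' @param path YAML file written by [emit_parameter_fixture()].
#' @return A list of distribution specs (`parameter_path`, `family`, `args`).
#' @export
load_distribution_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  purrr::map(raw$psa_distributions, function(s) {
    list(parameter_path = s$parameter_path, family = s$family,
         args = s[setdiff(names(s), c("parameter_path", "family"))])
  })
}

# ---- second-order distributions -------------------------------------------

spec_beta_from_range <- function(path, mean, lo, hi) {
  sd <- (hi - lo) / (2 * stats::qnorm(0.975))
  v <- mean * (1 - mean) / sd^2 - 1
  if (!is.finite(v) || v <= 0) v <- 10
  list(parameter_path = path, family = "beta",
       args = list(shape1 = mean * v, shape2 = (1 - mean) * v, min = lo, max = hi))
}

spec_triangular <- function(path, lo, mode, hi) {
  list(parameter_path = path, family = "triangular",
       args = list(min = lo, mode = mode, max = hi))
}

spec_lognormal_from_range <- function(path, base, lo, hi) {
  # median anchored at the base case; the printed range read as a central
  # 95% interval on the log scale
  sdlog <- (log(hi) - log(lo)) / (2 * stats::qnorm(0.975))
  list(parameter_path = path, family = "log-normal",
       args = list(meanlog = log(base), sdlog = sdlog, min = lo, max = hi))
}

#' Default second-order distribution specifications
#'
#' One spec per ranged input: beta for proportions (prevalence, stage
#' distributions, complication risks), triangular for transition rates and
#' adherence (ranged variables without a stated distribution), log-normal for
#' costs (skewed). Inputs printed without a range, and all test sensitivities
#' and specificities, carry no spec.
#'
#' @return A list of distribution specs.
#' @export
default_distribution_specs <- function() {
  c(
    list(
      spec_beta_from_range("strata.young.prev_nonadvanced", 0.171, 0.10, 0.25),
      spec_beta_from_range("strata.young.prev_advanced", 0.038, 0.02, 0.05),
      spec_beta_from_range("strata.young.prev_crc", 0.001, 0.0005, 0.002),
      spec_beta_from_range("strata.old.prev_nonadvanced", 0.173, 0.10, 0.25),
      spec_beta_from_range("strata.old.prev_advanced", 0.082, 0.05, 0.10),
      spec_beta_from_range("strata.old.prev_crc", 0.007, 0.002, 0.01),
      spec_triangular("transitions.normal_to_nonadv_no_history", 0.01, 0.02, 0.03),
      spec_triangular("transitions.normal_to_nonadv_history", 0.03, 0.038, 0.05),
      spec_triangular("transitions.nonadv_to_adv", 0.01, 0.019, 0.03),
      spec_triangular("transitions.adv_to_crc", 0.03, 0.048, 0.07),
      spec_beta_from_range("stage_distributions.unscreened.stage_i", 0.145, 0.12, 0.25),
      spec_beta_from_range("stage_distributions.unscreened.stage_ii", 0.356, 0.34, 0.39),
      spec_beta_from_range("stage_distributions.unscreened.stage_iii", 0.280, 0.23, 0.32),
      spec_beta_from_range("stage_distributions.unscreened.stage_iv", 0.219, 0.18, 0.25),
      spec_beta_from_range("stage_distributions.stool.stage_i", 0.305, 0.29, 0.33),
      spec_beta_from_range("stage_distributions.stool.stage_ii", 0.318, 0.30, 0.35),
      spec_beta_from_range("stage_distributions.stool.stage_iii", 0.243, 0.20, 0.26),
      spec_beta_from_range("stage_distributions.stool.stage_iv", 0.134, 0.10, 0.15),
      spec_beta_from_range("stage_distributions.structural.stage_i", 0.425, 0.41, 0.50),
      spec_beta_from_range("stage_distributions.structural.stage_ii", 0.226, 0.22, 0.26),
      spec_beta_from_range("stage_distributions.structural.stage_iii", 0.267, 0.20, 0.27),
      spec_beta_from_range("stage_distributions.structural.stage_iv", 0.082, 0.001, 0.09),
      spec_triangular("adherence.first_screen", 0.30, 0.68, 0.80),
      spec_triangular("adherence.subsequent_screen", 0.10, 0.63, 0.80),
      spec_triangular("adherence.colonoscopy_after_positive", 0.60, 0.81, 0.90),
      spec_beta_from_range("complications.bleed_dx_colo", 0.0003, 0.00001, 0.009),
      spec_beta_from_range("complications.bleed_tx_colo", 0.005, 0.003, 0.015),
      spec_beta_from_range("complications.perf_dx_colo", 0.0009, 0.0005, 0.002),
      spec_beta_from_range("complications.perf_tx_colo", 0.0024, 0.001, 0.005),
      spec_beta_from_range("complications.perf_flexsig", 0.0002, 0.0001, 0.0004),
      spec_beta_from_range("complications.death_after_perforation", 0.049, 0.01, 0.15),
      spec_lognormal_from_range("costs.direct.FOBT", 12, 6, 18),
      spec_lognormal_from_range("costs.direct.FIT", 19, 10, 30),
      spec_lognormal_from_range("costs.direct.colonoscopy_dx", 857, 500, 1200),
      spec_lognormal_from_range("costs.direct.colonoscopy_tx", 999, 700, 1700),
      spec_lognormal_from_range("costs.direct.CTC", 582, 440, 730),
      spec_lognormal_from_range("costs.direct.FDNA", 336, 200, 500),
      spec_lognormal_from_range("costs.direct.flex_sig", 650, 400, 900),
      spec_lognormal_from_range("costs.complication.bleed", 3194, 2400, 4000),
      spec_lognormal_from_range("costs.complication.perforation", 31223, 23500, 39000),
      spec_lognormal_from_range("costs.nonmedical.FOBT", 36, 25, 50),
      spec_lognormal_from_range("costs.nonmedical.FIT", 36, 25, 50),
      spec_lognormal_from_range("costs.nonmedical.FDNA", 36, 25, 50),
      spec_lognormal_from_range("costs.nonmedical.colonoscopy", 308, 200, 450),
      spec_lognormal_from_range("costs.nonmedical.CTC", 105, 100, 200),
      spec_lognormal_from_range("costs.nonmedical.flex_sig", 105, 100, 200)
    )
  )
}

r_triangular <- function(n, min, mode, max) {
  if (max == min) return(rep(mode, n)) # degenerate (point-mass) range
  u <- stats::runif(n)
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

sample_spec_value <- function(spec) {
  a <- spec$args
  x <- switch(spec$family,
    beta = stats::rbeta(1, a$shape1, a$shape2),
    normal = stats::rnorm(1, a$mean, a$sd),
    "log-normal" = stats::rlnorm(1, a$meanlog, a$sdlog),
    triangular = r_triangular(1, a$min, a$mode, a$max),
    stop("unknown distribution family '", spec$family, "'", call. = FALSE)
  )
  if (!is.null(a$min)) x <- max(x, a$min)
  if (!is.null(a$max)) x <- min(x, a$max)
  x
}

#' Sample a parameter set from second-order distributions
#'
#' Replaces each spec'd field with a random draw from its distribution,
#' truncating to the spec's support so field invariants hold. Stage
#' distributions are renormalised to sum to one after sampling. Specs
#' targeting test sensitivity or specificity paths are rejected: those are
#' linked variables excluded from probabilistic analysis.
#'
#' @param base Base `crc_parameters`.
#' @param specs List of distribution specs (see
#'   [default_distribution_specs()]).
#' @param seed Optional integer seed; identical seeds give identical draws.
#' @return A new validated `crc_parameters` object.
#' @export
sample_psa_parameters <- function(base, specs = default_distribution_specs(),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (spec in specs) {
    if (grepl("^tests\\.", spec$parameter_path)) {
      stop("distribution specs must not target test performance ('",
           spec$parameter_path,
           "'): sensitivity and specificity are excluded from the PSA",
           call. = FALSE)
    }
  }
  draw_once <- function() {
    p <- base
    for (spec in specs) {
      p <- param_set(p, spec$parameter_path, sample_spec_value(spec))
    }
    for (ctx in names(p$stage_distributions)) {
      d <- unlist(p$stage_distributions[[ctx]])
      p$stage_distributions[[ctx]] <- as.list(d / sum(d))
    }
    p
  }
  # independently sampled fields can violate joint orderings (for example a
  # therapeutic complication risk drawn below its diagnostic counterpart);
  # such draws are rejected and redrawn
  for (attempt in 1:100) {
    p <- draw_once()
    ok <- tryCatch({
      validate_parameters(p)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(validate_parameters(p))
  }
  stop("could not draw a jointly valid parameter set in 100 attempts; ",
       "check the distribution specifications", call. = FALSE)
}
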