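# Cohort-expectation engine.
#
# Propagates the full joint occupancy distribution over (health state,
# stage, years since diagnosis, history flag, surveillance clock,
# post-colonoscopy exemption clock, offer clock, ever-offered flag) year by
# year, treating every screening-cascade branch (adherence x test result x
# follow-up x detection x complications) analytically by probability mass
# instead of sampling. Output is deterministic; microsimulation means
# converge to it as the cohort grows. The event order per cycle is
# identical to run_microsim().

atoms_init <- function(params, icap) {
  st <- params$strata$young
  p0 <- c(1 - st$prev_nonadvanced - st$prev_advanced - st$prev_crc,
          st$prev_nonadvanced, st$prev_advanced, st$prev_crc)
  data.frame(
    st = 1:4,
    stage = 0L, ydx = 0L, hist = 0L,
    surv = -1L, exmpt = 0L, sinc = icap, evoff = 0L,
    p = p0
  )
}

atoms_aggregate <- function(a, icap) {
  key <- (((((((a$st - 1L) * 5L + a$stage) * 7L + a$ydx) * 2L + a$hist) * 8L +
              (a$surv + 1L)) * 11L + a$exmpt) * (icap + 1L) + a$sinc) * 2L + a$evoff
  if (!anyDuplicated(key)) return(a)
  p <- rowsum(a$p, key)  # rows sorted by key
  keep <- !duplicated(key)
  out <- a[keep, , drop = FALSE]
  out <- out[order(key[keep]), , drop = FALSE]
  out$p <- p[, 1]
  out[out$p > 0, , drop = FALSE]
}

# override some columns of an atom subset, keeping the rest
atoms_with <- function(a, p, ...) {
  over <- list(...)
  out <- a
  out$p <- p
  for (nm in names(over)) out[[nm]] <- over[[nm]]
  out
}

#' Expectation-mode (Markov cohort) run of one strategy
#'
#' Deterministic counterpart of [run_microsim()]: identical model structure
#' and event ordering, but every stochastic branch is propagated by its
#' probability mass. Used for base-case cost/QALY estimates, calibration,
#' and the probabilistic sensitivity analysis, where first-order Monte
#' Carlo noise would obscure small between-strategy differences.
#'
#' @param strat A one-row strategy tibble (see [strategy()]).
#' @param params A `crc_parameters` object.
#' @return A `cohort_result` object: mean discounted cost and QALYs per
#'   person, expected event counts per person and per 100,000, and a
#'   per-year total-mass trace for conservation checks.
#' @export
run_cohort_expectation <- function(strat, params = base_case_parameters()) {
  strat <- as_strategy_row(strat)
  st_set <- params$settings
  start_age <- st_set$screen_start_age
  horizon <- st_set$max_age - start_age
  disc <- (1 + st_set$discount_rate)^-(0:horizon)
  hz <- annual_crc_hazards(params)
  window <- st_set$crc_survival_window
  mgmt <- unname(unlist(params$costs$crc_management))
  cmp <- params$complications
  ccost <- params$costs$complication
  adh <- params$adherence
  screening <- strat$modality != "none"
  icap <- if (screening) strat$interval_years else 0L
  q_sympt <- st_set$symptomatic_presentation_annual_prob
  exempt_len <- st_set$clean_colonoscopy_exempt_years
  stage_dists <- lapply(params$stage_distributions, function(d) unname(unlist(d)))

  if (screening) {
    perf_primary <- params$tests[[strat$modality]]
    if (is.null(perf_primary)) {
      stop("no test performance defined for modality '", strat$modality, "'",
           call. = FALSE)
    }
    pos_lookup <- positive_prob_lookup(perf_primary)
    fu_row <- if (strat$modality == "CTC") params$tests$colonoscopy_after_ctc
              else params$tests$colonoscopy
    std_row <- params$tests$colonoscopy
    dx_context <- if (is_stool_modality(strat$modality)) "stool" else "structural"
    first_adh <- if (is.na(strat$first_adherence)) adh$first_screen else strat$first_adherence
    subs_adh <- if (is.na(strat$subsequent_adherence)) adh$subsequent_screen else strat$subsequent_adherence
    test_cost <- if (strat$modality == "colonoscopy") 0 else
      direct_test_cost(strat$modality, params$costs) +
      nonmedical_test_cost(strat$modality, params$costs)
    admin <- params$costs$admin_per_test
  }

  acc <- new.env(parent = emptyenv())
  acc$cost <- 0; acc$qaly <- 0; acc$ly <- 0
  acc$cancers <- 0; acc$crc_deaths <- 0; acc$tests <- 0; acc$colos <- 0
  acc$bleeds <- 0; acc$perfs <- 0; acc$pdeaths <- 0
  acc$dead <- 0
  mass_by_year <- numeric(horizon)

  surv_nonadv <- surveillance_interval("nonadvanced_adenoma")
  surv_adv <- surveillance_interval("advanced_adenoma")
  surv_crc <- surveillance_interval("crc_resected")

  # expand a colonoscopy applied to atom subset `a` with entry mass a$p
  colonoscopy_branches <- function(a, perf, context, referral, t) {
    if (nrow(a) == 0 || sum(a$p) == 0) return(a[0, , drop = FALSE])
    acc$colos <- acc$colos + sum(a$p)
    tx_direct <- params$costs$direct$colonoscopy_tx + params$costs$nonmedical$colonoscopy
    dx_direct <- params$costs$direct$colonoscopy_dx + params$costs$nonmedical$colonoscopy
    # expected complication cost and fatal-perforation fraction by flag
    comp_cost_tx <- cmp$bleed_tx_colo * ccost$bleed + cmp$perf_tx_colo * ccost$perforation
    comp_cost_dx <- cmp$bleed_dx_colo * ccost$bleed + cmp$perf_dx_colo * ccost$perforation
    die_tx <- cmp$perf_tx_colo * cmp$death_after_perforation
    die_dx <- cmp$perf_dx_colo * cmp$death_after_perforation

    det_p <- numeric(nrow(a))
    det_p[a$st == 2L] <- perf$sens_nonadvanced
    det_p[a$st == 3L] <- perf$sens_advanced
    det_p[a$st == 4L] <- perf$sens_cancer
    is_ctc_fp <- a$st == 1L & referral == "CTC"

    out <- list()
    push <- function(sub, mass, therapeutic, extra_cost = 0, count_cancer = FALSE, ...) {
      keep <- mass > 0
      if (!any(keep)) return(invisible(NULL))
      sub <- sub[keep, , drop = FALSE]
      mass <- mass[keep]
      proc <- if (therapeutic) tx_direct + comp_cost_tx else dx_direct + comp_cost_dx
      die <- if (therapeutic) die_tx else die_dx
      acc$cost <- acc$cost + sum(mass) * (proc) * disc[t + 1] +
        sum(mass * extra_cost) * disc[t + 1]
      acc$bleeds <- acc$bleeds +
        sum(mass) * (if (therapeutic) cmp$bleed_tx_colo else cmp$bleed_dx_colo)
      acc$perfs <- acc$perfs +
        sum(mass) * (if (therapeutic) cmp$perf_tx_colo else cmp$perf_dx_colo)
      if (count_cancer) acc$cancers <- acc$cancers + sum(mass)
      acc$pdeaths <- acc$pdeaths + sum(mass) * die
      acc$dead <- acc$dead + sum(mass) * die
      over <- list(...)
      b <- sub
      b$p <- mass * (1 - die)
      for (nm in names(over)) {
        v <- over[[nm]]
        b[[nm]] <- if (length(v) == 1) v else v[keep]
      }
      out[[length(out) + 1]] <<- b
      invisible(NULL)
    }

    # nonadvanced adenoma removed -> post-polypectomy, 5-year surveillance
    m <- a$p * det_p * (a$st == 2L)
    push(a, m, therapeutic = TRUE,
         st = 1L, hist = 1L, surv = surv_nonadv, exmpt = 0L)
    # advanced adenoma removed -> 3-year surveillance
    m <- a$p * det_p * (a$st == 3L)
    push(a, m, therapeutic = TRUE,
         st = 1L, hist = 1L, surv = surv_adv, exmpt = 0L)
    # cancer detected -> diagnosis, staged by detection context
    dist <- stage_dists[[context]]
    for (k in 1:4) {
      m <- a$p * det_p * (a$st == 4L) * dist[k]
      push(a, m, therapeutic = TRUE, extra_cost = mgmt[k], count_cancer = TRUE,
           st = 5L, stage = k, ydx = 0L, hist = 1L, surv = surv_crc, exmpt = 0L)
    }
    # CTC false positive: non-adenomatous polyp removed; histology decides
    # whether surveillance starts
    m <- a$p * is_ctc_fp * params$histology$adenomatous_lt10mm
    push(a, m, therapeutic = TRUE,
         hist = 1L, surv = surv_nonadv, exmpt = 0L)
    m <- a$p * is_ctc_fp * (1 - params$histology$adenomatous_lt10mm)
    push(a, m, therapeutic = TRUE, surv = -1L, exmpt = exempt_len)
    # clean examination -> decade exemption, surveillance cleared
    clean_p <- ifelse(is_ctc_fp, 0, ifelse(a$st %in% c(2L, 3L, 4L), 1 - det_p, 1))
    m <- a$p * clean_p
    push(a, m, therapeutic = FALSE, surv = -1L, exmpt = exempt_len)

    do.call(rbind, out)
  }

  a <- atoms_init(params, icap)

  for (t in 0:(horizon - 1)) {
    age <- start_age + t

    # years since diagnosis advance at cycle start
    sel <- a$st == 5L
    a$ydx[sel] <- pmin(a$ydx[sel] + 1L, window + 1L)

    # (1) background mortality
    d_bg <- background_death_prob(age, params)
    acc$dead <- acc$dead + sum(a$p) * d_bg
    a$p <- a$p * (1 - d_bg)

    # (2) CRC mortality inside the survival window
    sel <- a$st == 5L & a$ydx >= 1L & a$ydx <= window
    if (any(sel)) {
      m <- a$p[sel] * hz[a$stage[sel]]
      acc$crc_deaths <- acc$crc_deaths + sum(m)
      acc$dead <- acc$dead + sum(m)
      a$p[sel] <- a$p[sel] - m
    }

    # (3) screening / surveillance contact
    if (screening) {
      # screening and surveillance both stop at the upper screening age
      sdue <- a$surv == 0L & age <= strat$stop_age
      pdue <- a$st != 5L & a$surv == -1L & a$exmpt == 0L &
        age >= strat$start_age & age <= strat$stop_age &
        a$sinc >= strat$interval_years
      rest <- a[!(sdue | pdue), , drop = FALSE]
      pieces <- list(rest)

      if (any(sdue)) {
        s <- a[sdue, , drop = FALSE]
        pieces[[length(pieces) + 1]] <-
          atoms_with(s, s$p * (1 - st_set$surveillance_adherence), surv = 1L)
        go <- atoms_with(s, s$p * st_set$surveillance_adherence)
        pieces[[length(pieces) + 1]] <-
          colonoscopy_branches(go, std_row, "structural", "none", t)
      }

      if (any(pdue)) {
        s <- a[pdue, , drop = FALSE]
        a_prob <- ifelse(s$evoff == 1L, subs_adh, first_adh)
        s$evoff <- 1L
        s$sinc <- 0L
        pieces[[length(pieces) + 1]] <- atoms_with(s, s$p * (1 - a_prob))
        taker <- atoms_with(s, s$p * a_prob)
        acc$tests <- acc$tests + sum(taker$p)
        acc$cost <- acc$cost + sum(taker$p) * (test_cost + admin) * disc[t + 1]

        if (strat$modality == "colonoscopy") {
          pieces[[length(pieces) + 1]] <-
            colonoscopy_branches(taker, std_row, "structural", "none", t)
        } else {
          if (strat$modality == "flex_sig" && cmp$perf_flexsig > 0) {
            pf <- cmp$perf_flexsig
            acc$perfs <- acc$perfs + sum(taker$p) * pf
            acc$cost <- acc$cost + sum(taker$p) * pf * ccost$perforation * disc[t + 1]
            dm <- pf * cmp$death_after_perforation
            acc$pdeaths <- acc$pdeaths + sum(taker$p) * dm
            acc$dead <- acc$dead + sum(taker$p) * dm
            taker$p <- taker$p * (1 - dm)
          }
          if (strat$modality == "CTC" && cmp$perf_ctc > 0) {
            # CTC perforations are costed but assumed never fatal
            acc$perfs <- acc$perfs + sum(taker$p) * cmp$perf_ctc
            acc$cost <- acc$cost + sum(taker$p) * cmp$perf_ctc *
              ccost$perforation * disc[t + 1]
          }
          ppos <- pos_lookup[taker$st]
          pieces[[length(pieces) + 1]] <- atoms_with(taker, taker$p * (1 - ppos))
          pieces[[length(pieces) + 1]] <-
            atoms_with(taker, taker$p * ppos * (1 - adh$colonoscopy_after_positive))
          fu <- atoms_with(taker, taker$p * ppos * adh$colonoscopy_after_positive)
          pieces[[length(pieces) + 1]] <-
            colonoscopy_branches(fu, fu_row, dx_context, strat$modality, t)
        }
      }
      a <- do.call(rbind, pieces)
      a <- a[a$p > 0, , drop = FALSE]
    }

    # (4) lesion progression
    tr <- params$transitions
    rate1 <- ifelse(a$hist == 1L, tr$normal_to_nonadv_history,
                    tr$normal_to_nonadv_no_history)
    move_p <- numeric(nrow(a))
    move_p[a$st == 1L] <- rate1[a$st == 1L]
    move_p[a$st == 2L] <- tr$nonadv_to_adv
    move_p[a$st == 3L] <- tr$adv_to_crc
    moving <- move_p > 0
    if (any(moving)) {
      mv <- a[moving, , drop = FALSE]
      mv$p <- mv$p * move_p[moving]
      mv$st <- mv$st + 1L
      a$p[moving] <- a$p[moving] * (1 - move_p[moving])
      a <- rbind(a, mv)
    }

    # (5) symptomatic presentation
    sel <- a$st == 4L
    if (any(sel) && q_sympt > 0) {
      s <- a[sel, , drop = FALSE]
      dx_mass <- s$p * q_sympt
      a$p[sel] <- s$p - dx_mass
      dist <- stage_dists$unscreened
      for (k in 1:4) {
        m <- dx_mass * dist[k]
        acc$cancers <- acc$cancers + sum(m)
        acc$cost <- acc$cost + sum(m) * mgmt[k] * disc[t + 1]
        a <- rbind(a, atoms_with(s, m, st = 5L, stage = k, ydx = 0L, hist = 1L))
      }
    }

    # (6) utility accrual
    u_w <- utility_int(a$st, pmax(a$stage, 1L), a$ydx, params)
    acc$qaly <- acc$qaly + sum(a$p * u_w) * disc[t + 1]
    acc$ly <- acc$ly + sum(a$p)
    mass_by_year[t + 1] <- sum(a$p) + acc$dead

    # (7) clock updates and aggregation
    a$sinc <- pmin(a$sinc + 1L, icap)
    a$exmpt <- pmax(a$exmpt - 1L, 0L)
    a$surv <- ifelse(a$surv > 0L, a$surv - 1L, a$surv)
    a <- atoms_aggregate(a, icap)
  }

  counts <- c(cancers = acc$cancers, crc_deaths = acc$crc_deaths,
              primary_tests = acc$tests, colonoscopies = acc$colos,
              bleeds = acc$bleeds, perforations = acc$perfs,
              perforation_deaths = acc$pdeaths)
  structure(list(
    label = strat$label,
    modality = strat$modality,
    mean_cost = unname(acc$cost),
    mean_qaly = unname(acc$qaly),
    mean_life_years = unname(acc$ly),
    counts = tibble::tibble(metric = names(counts),
                            per_person = as.numeric(counts),
                            per_100k = as.numeric(counts) * 1e5),
    mass_by_year = mass_by_year
  ), class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result> ", x$label, "\n", sep = "")
  cat(sprintf("  mean discounted cost   CAN$%.2f\n", x$mean_cost))
  cat(sprintf("  mean discounted QALYs  %.4f\n", x$mean_qaly))
  cc <- x$counts
  for (m in c("cancers", "crc_deaths", "primary_tests", "colonoscopies")) {
    cat(sprintf("  %-22s %12s per 100,000\n", m,
                format(round(cc$per_100k[cc$metric == m]), big.mark = ",")))
  }
  invisible(x)
}
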