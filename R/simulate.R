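#' First-order Monte Carlo microsimulation of one screening strategy
#'
#' Simulates `n_persons` independent average-risk individuals from age 50
#' until death or the model horizon under one screening strategy, tallying
#' CRC diagnoses (screen-detected and symptomatic), CRC deaths, primary
#' screening tests, colonoscopies, complications, and mean discounted cost
#' and QALYs per person.
#'
#' Within each one-year cycle events occur in a fixed order: background
#' mortality, then stage-specific CRC mortality (years 1-5 after
#' diagnosis), then any screening or surveillance contact, then lesion
#' progression, then symptomatic presentation of undiagnosed CRC, then
#' utility accrual for survivors and the age increment. Natural-history and
#' screening random numbers come from two independent streams derived from
#' the master seed, so strategies run with the same seed share disease
#' trajectories (common random numbers).
#'
#' @param strat A one-row strategy tibble (see [strategy()]).
#' @param params A `crc_parameters` object.
#' @param n_persons Cohort size (the reference reporting scale is 100,000).
#' @param seed Master integer seed.
#' @return An `outcome_tally` object; see [tidy.outcome_tally()].
#' @export
run_microsim <- function(strat, params = base_case_parameters(),
                         n_persons = 100000, seed = 1) {
  strat <- as_strategy_row(strat)
  stopifnot(n_persons >= 1)
  seeds <- derive_seeds(seed, 2)
  nh <- make_stream(seeds[1])
  sc <- make_stream(seeds[2])

  n <- as.integer(n_persons)
  st_set <- params$settings
  start_age <- st_set$screen_start_age
  horizon <- st_set$max_age - start_age
  disc <- (1 + st_set$discount_rate)^-(0:horizon)
  hz <- annual_crc_hazards(params)
  window <- st_set$crc_survival_window
  mgmt <- unname(unlist(params$costs$crc_management))
  comp_cost <- params$costs$complication
  cmp <- params$complications
  adh <- params$adherence
  screening <- strat$modality != "none"
  surv_adh <- st_set$surveillance_adherence
  exempt_len <- st_set$clean_colonoscopy_exempt_years
  q_sympt <- st_set$symptomatic_presentation_annual_prob

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

  # person state vectors
  u0 <- stream_runif(nh, n)
  state <- init_states_int(n, params$strata$young, u0)
  hist <- logical(n)
  stage <- rep(1L, n)          # meaningful only once diagnosed
  ydx <- integer(n)
  surv_due <- rep(NA_integer_, n)
  exempt_until <- rep(-1L, n)
  last_offer <- rep(-1000L, n)
  ever_off <- logical(n)

  cost <- numeric(n)
  qaly <- numeric(n)
  ly <- integer(n)
  cancer <- logical(n)
  crc_death <- logical(n)
  n_tests <- integer(n)
  n_positive <- integer(n)
  n_colo <- integer(n)
  n_colo_primary <- integer(n)
  n_colo_followup <- integer(n)
  n_colo_surv <- integer(n)
  n_bleed <- integer(n)
  n_perf <- integer(n)
  n_pdeath <- integer(n)
  sympt_dx_total <- 0L
  sympt_dx_late <- 0L
  sympt_dx_era <- 0L  # symptomatic diagnoses in years 1..(stop_age - start)
  alive_plus_dead_ok <- TRUE

  stage_cum <- lapply(params$stage_distributions, function(d) cumsum(unlist(d)))

  # colonoscopy procedure applied to persons `idx`; uses closure state via <<-
  do_colonoscopy <- function(idx, perf, context, referral, t, origin,
                             u_det, u_stg, u_hist, u_bleed, u_perf, u_pd) {
    if (!length(idx)) return(invisible(NULL))
    n_colo[idx] <<- n_colo[idx] + 1L
    switch(origin,
      primary = n_colo_primary[idx] <<- n_colo_primary[idx] + 1L,
      followup = n_colo_followup[idx] <<- n_colo_followup[idx] + 1L,
      surveillance = n_colo_surv[idx] <<- n_colo_surv[idx] + 1L
    )
    st <- state[idx]
    det <- (st == 2L & u_det < perf$sens_nonadvanced) |
           (st == 3L & u_det < perf$sens_advanced) |
           (st == 4L & u_det < perf$sens_cancer)
    ctc_fp <- referral == "CTC" & st == 1L
    therapeutic <- det | ctc_fp

    proc_cost <- ifelse(therapeutic, params$costs$direct$colonoscopy_tx,
                        params$costs$direct$colonoscopy_dx) +
      params$costs$nonmedical$colonoscopy
    cost[idx] <<- cost[idx] + proc_cost * disc[t + 1]

    # nonadvanced adenoma removed: 5-year surveillance
    f_na <- det & st == 2L
    # advanced adenoma removed: 3-year surveillance
    f_adv <- det & st == 3L
    # cancer detected: stage by detection context, 3-year surveillance
    f_crc <- det & st == 4L

    i <- idx[f_na]
    state[i] <<- 1L; hist[i] <<- TRUE
    surv_due[i] <<- t + surveillance_interval("nonadvanced_adenoma")
    i <- idx[f_adv]
    state[i] <<- 1L; hist[i] <<- TRUE
    surv_due[i] <<- t + surveillance_interval("advanced_adenoma")
    i <- idx[f_crc]
    if (length(i)) {
      state[i] <<- 5L
      stage[i] <<- findInterval(u_stg[f_crc], stage_cum[[context]]) + 1L
      ydx[i] <<- 0L
      hist[i] <<- TRUE
      cancer[i] <<- TRUE
      surv_due[i] <<- t + surveillance_interval("crc_resected")
      cost[i] <<- cost[i] + mgmt[stage[i]] * disc[t + 1]
    }

    # CTC false positive: a real but non-adenomatous polyp is removed;
    # histology decides whether surveillance starts
    i_fp <- idx[ctc_fp]
    if (length(i_fp)) {
      adeno <- u_hist[ctc_fp] < params$histology$adenomatous_lt10mm
      j <- i_fp[adeno]
      hist[j] <<- TRUE
      surv_due[j] <<- t + surveillance_interval("nonadvanced_adenoma")
      j <- i_fp[!adeno]
      exempt_until[j] <<- t + exempt_len
      surv_due[j] <<- NA_integer_
    }

    # clean examination: decade exemption, surveillance clock cleared
    clean <- !det & !ctc_fp
    i <- idx[clean]
    exempt_until[i] <<- t + exempt_len
    surv_due[i] <<- NA_integer_

    # complications: bleed then perforation; perforation may be fatal
    pb <- ifelse(therapeutic, cmp$bleed_tx_colo, cmp$bleed_dx_colo)
    bleed <- u_bleed < pb
    i <- idx[bleed]
    n_bleed[i] <<- n_bleed[i] + 1L
    cost[i] <<- cost[i] + comp_cost$bleed * disc[t + 1]
    pp <- ifelse(therapeutic, cmp$perf_tx_colo, cmp$perf_dx_colo)
    perf_ev <- u_perf < pp
    i <- idx[perf_ev]
    n_perf[i] <<- n_perf[i] + 1L
    cost[i] <<- cost[i] + comp_cost$perforation * disc[t + 1]
    pdead <- perf_ev & u_pd < cmp$death_after_perforation
    i <- idx[pdead]
    state[i] <<- 6L
    n_pdeath[i] <<- n_pdeath[i] + 1L
    invisible(NULL)
  }

  for (t in 0:(horizon - 1)) {
    age <- start_age + t

    # years since diagnosis advance at cycle start
    is5 <- state == 5L
    ydx[is5] <- pmin(ydx[is5] + 1L, window + 1L)

    u_bg <- stream_runif(nh, n)
    u_crc <- stream_runif(nh, n)
    u_prog <- stream_runif(nh, n)
    u_sym <- stream_runif(nh, n)
    u_stg <- stream_runif(nh, n)

    # (1) background mortality
    d_bg <- background_death_prob(age, params)
    die <- state != 6L & u_bg < d_bg
    state[die] <- 6L

    # (2) CRC mortality inside the survival window
    in_win <- state == 5L & ydx >= 1L & ydx <= window
    die2 <- in_win & u_crc < hz[pmax(stage, 1L)]
    state[die2] <- 6L
    crc_death[die2] <- TRUE

    # (3) screening / surveillance contact
    if (screening) {
      u_adh <- stream_runif(sc, n)
      u_test <- stream_runif(sc, n)
      u_fu <- stream_runif(sc, n)
      u_det <- stream_runif(sc, n)
      u_stg2 <- stream_runif(sc, n)
      u_hist2 <- stream_runif(sc, n)
      u_bleed <- stream_runif(sc, n)
      u_perf <- stream_runif(sc, n)
      u_pd <- stream_runif(sc, n)
      u_psig <- stream_runif(sc, n)
      u_pdsig <- stream_runif(sc, n)

      # screening and surveillance both stop at the upper screening age
      alive <- state != 6L
      sdue <- alive & !is.na(surv_due) & surv_due <= t & age <= strat$stop_age
      s_go <- sdue & u_adh < surv_adh
      surv_due[sdue & !s_go] <- t + 1L  # recalled next year
      do_colonoscopy(which(s_go), std_row, "structural", "none", t, "surveillance",
                     u_det[s_go], u_stg2[s_go], u_hist2[s_go],
                     u_bleed[s_go], u_perf[s_go], u_pd[s_go])

      pdue <- alive & !sdue & is.na(surv_due) & state != 5L &
        age >= strat$start_age & age <= strat$stop_age &
        (t - last_offer) >= strat$interval_years &
        exempt_until <= t
      a_prob <- ifelse(ever_off, subs_adh, first_adh)
      adherent <- pdue & u_adh < a_prob
      ever_off[pdue] <- TRUE
      last_offer[pdue] <- t

      if (any(adherent)) {
        n_tests[adherent] <- n_tests[adherent] + 1L
        cost[adherent] <- cost[adherent] + (test_cost + admin) * disc[t + 1]

        if (strat$modality == "colonoscopy") {
          idx <- which(adherent)
          do_colonoscopy(idx, std_row, "structural", "none", t, "primary",
                         u_det[adherent], u_stg2[adherent], u_hist2[adherent],
                         u_bleed[adherent], u_perf[adherent], u_pd[adherent])
        } else {
          if (strat$modality == "CTC" && cmp$perf_ctc > 0) {
            # CTC perforations are costed but assumed never fatal
            pctc <- adherent & u_psig < cmp$perf_ctc
            i <- which(pctc)
            n_perf[i] <- n_perf[i] + 1L
            cost[i] <- cost[i] + comp_cost$perforation * disc[t + 1]
          }
          if (strat$modality == "flex_sig") {
            # perforation risk of the sigmoidoscopy itself
            psig <- adherent & u_psig < cmp$perf_flexsig
            i <- which(psig)
            n_perf[i] <- n_perf[i] + 1L
            cost[i] <- cost[i] + comp_cost$perforation * disc[t + 1]
            pd <- psig & u_pdsig < cmp$death_after_perforation
            i <- which(pd)
            state[i] <- 6L
            n_pdeath[i] <- n_pdeath[i] + 1L
          }
          still <- adherent & state != 6L
          pos <- still & u_test < pos_lookup[state]
          n_positive[pos] <- n_positive[pos] + 1L
          fu <- pos & u_fu < adh$colonoscopy_after_positive
          do_colonoscopy(which(fu), fu_row, dx_context, strat$modality, t, "followup",
                         u_det[fu], u_stg2[fu], u_hist2[fu],
                         u_bleed[fu], u_perf[fu], u_pd[fu])
        }
      }
    }

    # (4) lesion progression
    tr <- params$transitions
    rate_new <- ifelse(hist, tr$normal_to_nonadv_history, tr$normal_to_nonadv_no_history)
    to2 <- state == 1L & u_prog < rate_new
    to3 <- state == 2L & u_prog < tr$nonadv_to_adv
    to4 <- state == 3L & u_prog < tr$adv_to_crc
    state[to2] <- 2L
    state[to3] <- 3L
    state[to4] <- 4L

    # (5) symptomatic presentation
    present <- state == 4L & u_sym < q_sympt
    if (any(present)) {
      state[present] <- 5L
      stage[present] <- findInterval(u_stg[present], stage_cum$unscreened) + 1L
      ydx[present] <- 0L
      hist[present] <- TRUE
      cancer[present] <- TRUE
      cost[present] <- cost[present] + mgmt[stage[present]] * disc[t + 1]
      np <- sum(present)
      sympt_dx_total <- sympt_dx_total + np
      if (t > 0) sympt_dx_late <- sympt_dx_late + np
      if (t > 0 && age <= strat$stop_age) sympt_dx_era <- sympt_dx_era + np
    }

    # (6) utility accrual for survivors
    alive <- state != 6L
    if (any(alive)) {
      u_w <- utility_int(state, stage, ydx, params)
      qaly <- qaly + u_w * disc[t + 1] * alive
      ly <- ly + alive
    }
    alive_plus_dead_ok <- alive_plus_dead_ok && (sum(alive) + sum(!alive) == n)
  }

  totals <- c(
    cancers = sum(cancer),
    crc_deaths = sum(crc_death),
    primary_tests = sum(n_tests),
    positive_tests = sum(n_positive),
    colonoscopies = sum(n_colo),
    colonoscopies_primary = sum(n_colo_primary),
    colonoscopies_followup = sum(n_colo_followup),
    colonoscopies_surveillance = sum(n_colo_surv),
    bleeds = sum(n_bleed),
    perforations = sum(n_perf),
    perforation_deaths = sum(n_pdeath),
    symptomatic_diagnoses = sympt_dx_total,
    symptomatic_diagnoses_after_year0 = sympt_dx_late,
    symptomatic_diagnoses_in_screening_era = sympt_dx_era
  )
  structure(list(
    label = strat$label,
    modality = strat$modality,
    n = n,
    seed = seed,
    counts = tibble::tibble(
      metric = names(totals),
      total = as.numeric(totals),
      per_100k = as.numeric(totals) * 1e5 / n
    ),
    mean_cost = mean(cost),
    mean_qaly = mean(qaly),
    sd_cost = stats::sd(cost),
    sd_qaly = stats::sd(qaly),
    mean_life_years = mean(ly),
    conservation_ok = alive_plus_dead_ok
  ), class = "outcome_tally")
}

#' @export
print.outcome_tally <- function(x, ...) {
  cat("<outcome_tally> ", x$label, " (n = ", format(x$n, big.mark = ","),
      ", seed ", x$seed, ")\n", sep = "")
  cc <- x$counts
  for (m in c("cancers", "crc_deaths", "primary_tests", "colonoscopies")) {
    cat(sprintf("  %-22s %12s per 100,000\n", m,
                format(round(cc$per_100k[cc$metric == m]), big.mark = ",")))
  }
  cat(sprintf("  mean discounted cost   CAN$%.2f\n", x$mean_cost))
  cat(sprintf("  mean discounted QALYs  %.4f\n", x$mean_qaly))
  invisible(x)
}

tally_metric <- function(tally, metric, scale = c("per_100k", "total")) {
  scale <- match.arg(scale)
  tally$counts[[scale]][tally$counts$metric == metric]
}
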