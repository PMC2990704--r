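#' Health states of the disease model
#'
#' All colorectal cancers are assumed to arise through the
#' adenoma-carcinoma sequence: normal colon to nonadvanced adenoma to
#' advanced adenoma to CRC. A person occupies one worst-lesion state;
#' "post-polypectomy" is represented by the no-lesion state with the
#' adenoma/CRC history flag set. Diagnosed CRC additionally carries a stage
#' (I-IV) and years since diagnosis.
#'
#' @return Named integer vector of state codes.
#' @export
health_states <- function() {
  c(no_lesion = 1L, nonadvanced_adenoma = 2L, advanced_adenoma = 3L,
    crc_undiagnosed = 4L, crc_diagnosed = 5L, dead = 6L)
}

state_label <- function(code) names(health_states())[code]
state_code <- function(label) {
  hs <- health_states()
  if (any(!label %in% names(hs))) {
    stop("unknown health state '", setdiff(label, names(hs))[1], "'", call. = FALSE)
  }
  unname(hs[label])
}

#' Convert five-year mortality to a constant annual probability
#'
#' Stage-specific survival inputs are five-year mortality risks; the model
#' applies a constant annual hazard for exactly five cycles after diagnosis,
#' after which survivors revert to background mortality. The conversion
#' satisfies `1 - (1 - annual)^5 == m5`.
#'
#' @param m5 Five-year mortality risk(s) in \[0, 1\].
#' @return Annual death probability of the same length.
#' @export
#' @examples
#' convert_five_year_mortality(0.919)
convert_five_year_mortality <- function(m5) {
  if (any(!is.finite(m5)) || any(m5 < 0) || any(m5 > 1)) {
    stop("five-year mortality must lie in [0, 1]", call. = FALSE)
  }
  1 - (1 - m5)^(1 / 5)
}

annual_crc_hazards <- function(params) {
  convert_five_year_mortality(unlist(params$stage_mortality$five_year))
}

background_death_prob <- function(age, params) {
  ifelse(age < 65,
         params$strata$young$annual_background_death,
         params$strata$old$annual_background_death)
}

stratum_for_age <- function(age, params) {
  if (age < 65) params$strata$young else params$strata$old
}

#' Initialise a screening-age cohort
#'
#' Draws each person's baseline worst-lesion state from the age-stratum
#' prevalences of nonadvanced adenomas, advanced adenomas, and (undiagnosed)
#' CRC; the remainder start lesion-free.
#'
#' @param n Number of persons.
#' @param stratum A stratum parameter list (e.g.
#'   `base_case_parameters()$strata$young`).
#' @param u Optional uniform deviates (length `n`); drawn if `NULL`.
#' @return A tibble with columns `state` (character) and
#'   `history` (logical, all `FALSE`).
#' @export
initialize_cohort <- function(n, stratum, u = NULL) {
  probs <- c(stratum$prev_nonadvanced, stratum$prev_advanced, stratum$prev_crc)
  if (sum(probs) >= 1) {
    stop("baseline prevalences sum to 1 or more; no mass left for the ",
         "lesion-free state", call. = FALSE)
  }
  if (is.null(u)) u <- stats::runif(n)
  cum <- cumsum(probs)
  state <- rep.int(1L, n)
  state[u < cum[3]] <- 4L
  state[u < cum[2]] <- 3L
  state[u < cum[1]] <- 2L
  tibble::tibble(state = state_label(state), history = FALSE)
}

# vectorised internal version returning integer codes
init_states_int <- function(n, stratum, u) {
  cum <- cumsum(c(stratum$prev_nonadvanced, stratum$prev_advanced, stratum$prev_crc))
  state <- rep.int(1L, n)
  state[u < cum[3]] <- 4L
  state[u < cum[2]] <- 3L
  state[u < cum[1]] <- 2L
  state
}

#' Draw stage at diagnosis for a detection context
#'
#' Cancers found without screening (symptomatic presentation) use the
#' unscreened stage distribution; cancers initiated by a positive stool test
#' use the stool-detected distribution; cancers found by colonoscopy,
#' flexible sigmoidoscopy, or CT colonography use the structural
#' distribution, which carries the most favourable stage mix.
#'
#' @param n Number of draws.
#' @param context One of `"unscreened"`, `"stool"`, `"structural"`.
#' @param params A `crc_parameters` object.
#' @param u Optional uniforms.
#' @return Integer stages 1-4.
#' @export
sample_stage <- function(n, context, params, u = NULL) {
  dist <- params$stage_distributions[[context]]
  if (is.null(dist)) {
    stop("unknown detection context '", context, "'", call. = FALSE)
  }
  if (is.null(u)) u <- stats::runif(n)
  cum <- cumsum(unlist(dist))
  findInterval(u, cum, left.open = FALSE) + 1L
}

# One natural-history year on parallel state vectors (no screening).
# Order within the cycle: (1) background mortality; (2) CRC mortality while
# inside the five-year survival window; (3) lesion progression with the
# history-dependent new-adenoma rate; (4) symptomatic presentation of
# undiagnosed CRC. Ageing is handled by the caller. Each sub-step consumes
# one uniform per person so that runs with different screening arms share
# the same natural-history random numbers.
nh_year_step <- function(state, hist, stage, ydx, age, params,
                         u_bg, u_crc, u_prog, u_sympt, u_stage) {
  alive <- state != 6L
  died_crc <- logical(length(state))
  new_dx <- logical(length(state))

  # (1) background mortality
  d_bg <- background_death_prob(age, params)
  die_bg <- alive & (u_bg < d_bg)
  state[die_bg] <- 6L

  # (2) CRC-specific mortality, years 1..5 after diagnosis
  h <- annual_crc_hazards(params)
  in_window <- state == 5L & ydx >= 1L & ydx <= params$settings$crc_survival_window
  die_crc <- in_window & (u_crc < h[pmax(stage, 1L)])
  die_crc[is.na(die_crc)] <- FALSE
  state[die_crc] <- 6L
  died_crc <- die_crc

  # (3) progression
  tr <- params$transitions
  rate_new <- ifelse(hist, tr$normal_to_nonadv_history, tr$normal_to_nonadv_no_history)
  to_nonadv <- state == 1L & (u_prog < rate_new)
  to_adv <- state == 2L & (u_prog < tr$nonadv_to_adv)
  to_crc <- state == 3L & (u_prog < tr$adv_to_crc)
  state[to_nonadv] <- 2L
  state[to_adv] <- 3L
  state[to_crc] <- 4L

  # (4) symptomatic presentation (unscreened detection context)
  q <- params$settings$symptomatic_presentation_annual_prob
  present <- state == 4L & (u_sympt < q)
  if (any(present)) {
    state[present] <- 5L
    stage[present] <- sample_stage(sum(present), "unscreened", params, u_stage[present])
    ydx[present] <- 0L
    hist[present] <- TRUE
    new_dx <- present
  }

  list(state = state, hist = hist, stage = stage, ydx = ydx,
       died_crc = died_crc, new_dx = new_dx)
}

#' Advance persons one model year (no screening contact)
#'
#' Applies, in order, background mortality, stage-specific CRC mortality
#' within five years of diagnosis, lesion progression (with the
#' history-dependent adenoma recurrence rate), symptomatic presentation of
#' undiagnosed CRC, and the age increment. Screening contact is a separate
#' step (see [run_microsim()]).
#'
#' @param persons Tibble with columns `age`, `state` (character),
#'   `history`, `stage` (integer or NA), `years_since_dx` (integer or NA).
#' @param params A `crc_parameters` object.
#' @return The advanced tibble, with `died_crc` and `newly_diagnosed`
#'   indicator columns.
#' @export
advance_one_year <- function(persons, params) {
  n <- nrow(persons)
  state <- state_code(persons$state)
  ydx <- ifelse(is.na(persons$years_since_dx), 0L, persons$years_since_dx)
  # years-since-diagnosis advances at the start of the cycle
  ydx <- ifelse(state == 5L, pmin(ydx + 1L, 6L), ydx)
  res <- nh_year_step(
    state = state, hist = persons$history,
    stage = ifelse(is.na(persons$stage), 0L, persons$stage),
    ydx = ydx,
    age = persons$age, params = params,
    u_bg = stats::runif(n), u_crc = stats::runif(n), u_prog = stats::runif(n),
    u_sympt = stats::runif(n), u_stage = stats::runif(n)
  )
  tibble::tibble(
    age = persons$age + 1L,
    state = state_label(res$state),
    history = res$hist,
    stage = ifelse(res$state == 5L | (state == 5L & res$state == 6L),
                   res$stage, NA_integer_),
    years_since_dx = ifelse(res$state == 5L, res$ydx, NA_integer_),
    died_crc = res$died_crc,
    newly_diagnosed = res$new_dx
  )
}
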