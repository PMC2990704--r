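# Shared fixtures for the test suite.

base_params <- base_case_parameters()

# parameters with all mortality switched off (for isolating disease dynamics)
params_no_death <- local({
  p <- base_params
  p$strata$young$annual_background_death <- 0
  p$strata$old$annual_background_death <- 0
  p
})

# published strategy means (cost-effectiveness table of the reference
# analysis) used to exercise the dominance routine on known inputs
published_table4 <- tibble::tibble(
  label = c("FIT-mid", "none", "FIT-high", "FIT-low", "FOBT-high",
            "colonoscopy", "FOBT-low", "flex_sig", "CTC", "FDNA-SDT2",
            "FDNA-SDT1"),
  cost = c(1833, 1901, 2004, 2005, 2084, 2100, 2195, 2263, 2409, 2491, 2720),
  qaly = c(11.300, 11.255, 11.302, 11.282, 11.267, 11.296, 11.271, 11.291,
           11.296, 11.278, 11.265)
)

get100k <- function(res, metric) {
  res$counts$per_100k[res$counts$metric == metric]
}
get_total <- function(res, metric) {
  res$counts$total[res$counts$metric == metric]
}

# Brute-force dominance oracle: a strategy is on the efficient frontier iff
# no blend of two other strategies (including degenerate single-strategy
# blends) weakly dominates it. Written for continuous inputs without exact
# ties.
oracle_frontier <- function(df) {
  n <- nrow(df)
  on_frontier <- logical(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    for (j in seq_len(n)) {
      if (j == i) next
      # single-strategy (strong) dominance
      if (df$cost[j] <= df$cost[i] && df$qaly[j] >= df$qaly[i]) {
        dominated <- TRUE
        break
      }
      for (k in seq_len(n)) {
        if (k == i || k <= j) next
        dq <- df$qaly[k] - df$qaly[j]
        if (dq == 0) next
        lam <- (df$qaly[i] - df$qaly[j]) / dq
        if (lam < 0 || lam > 1) next
        blend_cost <- (1 - lam) * df$cost[j] + lam * df$cost[k]
        if (blend_cost <= df$cost[i]) {
          dominated <- TRUE
          break
        }
      }
      if (dominated) break
    }
    on_frontier[i] <- !dominated
  }
  on_frontier
}
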