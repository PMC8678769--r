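# shared fixtures built in code

# SBP-only cohort of flat (constant-mean) trajectory groups
flat_cohort <- function(n, means, probs, sigma, seed, grid = seq(0, 24, by = 2),
                        channel = "SBP") {
  cfg <- cohort_config(
    channels = stats::setNames(list(channel_spec(
      shapes = as.list(means), probs = probs, sigma = sigma)), channel),
    grid = grid, outcomes = NULL)
  simulate_bp_cohort(n = n, seed = seed, config = cfg)
}

# single-channel cohort from the shipped reference trajectory sets
reference_cohort <- function(n, seed, channel = c("SBP", "DBP"), noise = "iid",
                             rho = 0.6) {
  channel <- match.arg(channel)
  spec <- if (channel == "SBP") default_sbp_groups() else default_dbp_groups()
  cfg <- cohort_config(channels = stats::setNames(list(spec), channel),
                       noise = noise, rho = rho, outcomes = NULL)
  simulate_bp_cohort(n = n, seed = seed, config = cfg)
}

gbtm_formula <- value_mmhg ~ time_h | patient_id

# brute-force AUC by exhaustive pair counting (independent oracle)
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
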