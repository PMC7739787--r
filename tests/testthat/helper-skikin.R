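# Shared fixtures: simulated runs are expensive enough to be worth memoizing
# across test files (one process, fixed seeds => identical objects).
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(discipline, n_turns = 20, seed = 7, noiseless = FALSE,
                       fs = 148.15) {
  key <- paste(discipline, n_turns, seed, noiseless, fs, sep = "|")
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  pr <- default_profiles()[[discipline]]
  if (noiseless) {
    pr$vib_amp <- 0
    pr$acc_noise_sd <- 0
  }
  .sim_cache[[key]] <- simulate_run(pr, n_turns = n_turns, seed = seed, fs = fs)
  .sim_cache[[key]]
}

cached_metrics <- function(discipline, n_turns = 20, seed = 7) {
  key <- paste("m", discipline, n_turns, seed, sep = "|")
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- summarize_run(cached_sim(discipline, n_turns, seed)$run)
  .sim_cache[[key]]
}

truth_switch_samples <- function(truth, fs = 148.15) {
  round(truth$switch_times * fs) + 1L
}

# mean ground-truth ISO percentage over retained (interior) half-cycles
truth_iso_pct <- function(sim, leg, fs = 148.15) {
  sw <- truth_switch_samples(sim$truth, fs)
  labs <- sim$truth$phase_labels
  k <- length(sim$truth$leg_labels)
  vals <- c()
  for (i in 3:(k - 2)) {
    if (sim$truth$leg_labels[i] != leg) next
    span <- sw[i]:(sw[i + 1] - 1)
    vals <- c(vals, 100 * mean(labs[span] == "ISO"))
  }
  mean(vals)
}
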