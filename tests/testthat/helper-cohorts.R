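# Shared fixtures, built in code at test time.

# Short-duration parameters for fast unit-test cohorts (phase means cut
# roughly in half relative to the defaults; class ordering preserved).
fast_params <- function(seed = 1L, ...) {
  pm <- function(means, sds) {
    m <- cbind(mean = means, sd = sds)
    rownames(m) <- c("sit_to_stand", "walk_out", "turn", "walk_back",
                     "turn_and_sit")
    m
  }
  sim_params(
    phase_durations_s = list(
      non_faller = pm(c(0.8, 1.6, 0.8, 1.6, 1.0), c(0.1, 0.3, 0.1, 0.3, 0.2)),
      faller     = pm(c(1.2, 2.4, 1.2, 2.4, 1.6), c(0.2, 0.5, 0.2, 0.5, 0.3))),
    seed = seed, ...)
}

fast_cohort <- function(n = 8, seed = 1L, preprocessed = TRUE) {
  co <- simulate_cohort(n, 0.5, fast_params(seed))
  if (preprocessed) preprocess_cohort(co) else co
}

# Deterministic 3-channel matrix for segmentation tests.
ramp_matrix <- function(n) {
  cbind(ap = seq_len(n) / n, ml = sin(seq_len(n)), si = rep(0.5, n))
}
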