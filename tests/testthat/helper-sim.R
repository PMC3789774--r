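# Shared helpers: small simulation blocks used across test files.

quick_trains <- function(ratio, mu_e, contrast, trials = 5, duration = 500,
                         seed = 1, frozen = FALSE) {
  regime <- build_regime(mu_e, contrast, ratio)
  p <- membrane_params()
  lapply(seq_len(trials), function(j) {
    stim_seed <- if (frozen) derive_seed(seed, ratio, mu_e, contrast, 9, 0)
                 else derive_seed(seed, ratio, mu_e, contrast, 9, j)
    tr <- integrate_compartment(p, regime, duration = duration,
                                stimulus_seed = stim_seed,
                                channel_seed = derive_seed(seed, ratio, mu_e,
                                                           contrast, 7, j),
                                record_trace = FALSE)
    tr$spike_times
  })
}

# analytic entropy rate of i.i.d. Bernoulli letters, bits/s at 1 ms bins
bernoulli_rate <- function(p, dt_bin = 1) {
  h <- if (p <= 0 || p >= 1) 0 else -(p * log2(p) + (1 - p) * log2(1 - p))
  1000 * h / dt_bin
}
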