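# Short, coarse settings for shape/contract tests (not for accuracy checks).
fast_settings <- function(n_reps = 3L, sigma = 0.01, base_seed = 99L) {
  simulation_settings(dt = 1e-3, duration = 0.4, transient = 0.1,
                      sigma = sigma, n_reps = n_reps, base_seed = base_seed)
}

# Noise-free settings long enough for the slowest relaxation mode (~0.4 s)
# to decay below the 0.1% averaging tolerance.
noise_free_settings <- function(dt = 1e-4) {
  simulation_settings(dt = dt, duration = 9, transient = 3, sigma = 0,
                      n_reps = 1L, base_seed = 1L)
}
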