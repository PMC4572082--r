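# Shared fixtures: small problem sizes for unit tests; the acceptance file
# uses the full study conditions.

fast_config <- function(T = 200, dt = 0.01, N = 100, seed = 42L) {
  trial_config(T = T, dt = dt, N = N, seed = seed)
}

# random positive physical parameter sets for property sweeps
random_phys <- function(n, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      physical_params(
        c0 = runif(1, 0.1, 5), c1 = runif(1, 0.1, 5),
        C1 = runif(1, 0.01, 1), G1 = runif(1, 0.1, 5),
        Vth = runif(1, 0.001, 0.5), rho = runif(1, 0.5, 20),
        h = runif(1, 0.05, 1)
      )
    })
  })
}
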