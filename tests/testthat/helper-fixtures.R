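# Small parameter sets and exact lattice configurations used across tests.

tiny_params <- function(L = 20L, b = 1.1, u = 0.5, alpha = 2, K = 0.1,
                        mcs = 200L, window = 50L, reps = 2L, seed = 1L, ...) {
  sim_params(L = L, b = b, u = u, alpha = alpha, K = K, total_mcs = mcs,
             avg_window = window, n_replicates = reps, seed = seed, ...)
}

# uniform-strategy lattice with constant heterogeneity
const_state <- function(L, strategy = 1L, h = 2) {
  lattice_state(matrix(as.integer(strategy), L, L), matrix(h, L, L))
}

# random lattice drawn from a fixed seed (strategies fair coin, h on the
# 41-level grid) without touching the enclosing RNG state
rand_state <- function(L, seed) {
  withr::with_seed(seed, {
    lattice_state(matrix(sample(c(0L, 1L), L * L, TRUE), L, L),
                  matrix(((0:40) / 10)[sample.int(41L, L * L, TRUE)], L, L))
  })
}

# random model parameters for property-style loops
rand_params <- function(seed, L = 4L) {
  withr::with_seed(seed, {
    tiny_params(L = L,
                b = 1 + runif(1, 0, 0.5),
                u = runif(1),
                alpha = runif(1, 0, 6),
                K = runif(1, 0.05, 0.5))
  })
}
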