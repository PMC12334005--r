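# Random sum-to-zero effect sets and scale draws used across tests.

random_effect_set <- function(grid, scale = 1) {
  ctr <- function(M) {
    b <- rnorm(M, 0, scale)
    b - mean(b)
  }
  effect_set(rnorm(1), ctr(grid$I), ctr(grid$J), ctr(grid$K), grid = grid)
}

random_scales <- function() {
  scale_params(sigma = runif(1, 0.1, 2), sigmaA = runif(1, 0.1, 2),
               sigmaP = runif(1, 0.1, 2), sigmaC = runif(1, 0.1, 2))
}

# small dataset + matching truth for fast sampler tests
tiny_dataset <- function(seed = 1, slopes = c(0, 0, 0), amps = c(0, 0, 0),
                         grid = apc_grid(6, 6), replicates = 4) {
  truth <- make_trig_params(grid, slopes, amps, gamma = 0.1)
  list(truth = truth, data = generate_data(truth, replicates, seed = seed))
}
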