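# Shared fixtures for the unit tests: modest grid sizes keep the default
# run fast; the acceptance tests use the full acquisition-scale grids.

small_irf <- function(n_channels = 1024, window_ns = 20, seed = 100, ...) {
  make_irf(n_channels = n_channels, window_ns = window_ns, seed = seed, ...)
}

delta_irf <- function(n_channels = 1024, window_ns = 20) {
  time <- (seq_len(n_channels) - 1) * window_ns / n_channels
  counts <- numeric(n_channels)
  counts[1] <- 1e6
  decay_histogram(time, counts)
}

# closed-form Gaussian (x) exponential: the exponentially modified Gaussian,
# for a unit-area Gaussian IRF centered at mu with width sigma
emg_curve <- function(time, tau, mu, sigma) {
  0.5 * exp((sigma^2 - 2 * tau * (time - mu)) / (2 * tau^2)) *
    pracma::erfc((sigma^2 - tau * (time - mu)) / (sigma * tau * sqrt(2)))
}

default_cal <- function() hill_calibration(1.9, 71, 0.10, -0.03)
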