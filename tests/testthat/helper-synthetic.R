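# Build a channel histogram from raw event coordinates (round, clip, bin).
events_to_hist <- function(x, n_channels = 1024L, ...) {
  channel_histogram(tabulate(pmin(pmax(round(x), 1), n_channels),
                             nbins = n_channels), ...)
}

# Sample n events from a Gaussian mixture with a 2% uniform outlier share
# (fractions are the Gaussian-internal proportions, summing to 1).
rmix_hist <- function(n, means, sds, fractions, seed,
                      uniform_weight = 0.02, n_channels = 1024L, ...) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  set.seed(seed)
  K <- length(means)
  comp <- sample.int(K + 1L, n, replace = TRUE,
                     prob = c(fractions * (1 - uniform_weight),
                              uniform_weight))
  x <- numeric(n)
  for (i in seq_len(K))
    x[comp == i] <- rnorm(sum(comp == i), means[i], sds[i])
  x[comp == K + 1L] <- runif(sum(comp == K + 1L), 1, n_channels)
  events_to_hist(x, n_channels, ...)
}

# A small two-condition dataset for I/O tests.
tiny_dataset <- function(seed = 1) {
  h1 <- rmix_hist(500, 300, 50, 1, seed = seed, concentration = 0,
                  replicate = "1", pregrowth = "gal")
  h2 <- rmix_hist(500, c(250, 700), c(40, 80), c(0.5, 0.5),
                  seed = seed + 1, concentration = 0.0033,
                  replicate = "1", pregrowth = "gal")
  fc_dataset(list(h1, h2))
}

expect_mass_conserved <- function(model, tol = 1e-9) {
  expect_lt(abs(sum(model$weights) + model$uniform_weight - 1), tol)
}

trace_is_monotone <- function(trace, tol = 1e-10) {
  if (length(trace) < 2) return(TRUE)
  all(diff(trace) >= -tol * pmax(abs(trace[-length(trace)]), 1))
}
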