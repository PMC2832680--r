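test_that("smoothing preserves constants, ramps, and spreads impulses", {
  # constant input stays constant (edges renormalize)
  sm <- smooth_counts(rep(5, 300), window = 31)
  expect_equal(sm, rep(sm[1], 300), tolerance = 1e-12)
  # interior of a linear ramp is unchanged (on the normalized scale)
  ramp <- 1:500
  smr <- smooth_counts(ramp, window = 71)
  norm <- ramp * 1e4 / sum(ramp)
  interior <- 36:465
  expect_equal(smr[interior], norm[interior], tolerance = 1e-9)
  # unit impulse, total 1 event: plateau of height 1e4/71 over 71 channels
  imp <- rep(0, 300); imp[150] <- 1
  smi <- smooth_counts(imp, window = 71)
  expect_equal(smi[150 + (-35:35)], rep(1e4 / 71, 71), tolerance = 1e-9)
  expect_equal(smi[100], 0)
  expect_error(smooth_counts(rep(1, 100), window = 70), "odd")
})

test_that("centered differences are exact for affine and quadratic series", {
  x <- seq_len(400)
  aff <- 3 + 0.25 * x
  d <- central_difference(aff, span = 71)
  expect_equal(d[36:365], rep(0.25, 330), tolerance = 1e-12)
  expect_equal(central_difference(rep(7, 400), span = 71)[36:365],
               rep(0, 330))
  quad <- 0.01 * x^2
  d2 <- central_difference(as.numeric(central_difference(quad, span = 71)),
                           span = 71)
  expect_equal(d2[71:330], rep(0.02, 260), tolerance = 1e-10)
  expect_error(central_difference(1:10, span = 11), "smaller")
})

test_that("mode detection finds true peaks and rejects broad bumps", {
  h1 <- rmix_hist(30000, 300, 50, 1, seed = 81)
  ms1 <- detect_modes(h1)
  expect_length(ms1$modes, 1)
  expect_lt(abs(ms1$modes - 300), 5)

  h2 <- rmix_hist(30000, c(250, 700), c(40, 80), c(0.5, 0.5), seed = 82)
  ms2 <- detect_modes(h2)
  expect_length(ms2$modes, 2)
  expect_lt(max(abs(ms2$modes - c(250, 700))), 10)

  # a 0.5%-weight sigma-150 bump at 900: never reported as a mode
  h3 <- rmix_hist(30000, c(250, 700, 900), c(40, 80, 150),
                  c(0.4975, 0.4975, 0.005), seed = 83)
  ms3 <- detect_modes(h3)
  expect_length(ms3$modes, 2)
  expect_false(any(ms3$modes > 850 & ms3$modes < 950))
  near <- ms3$crossings[ms3$crossings$channel > 850 &
                          ms3$crossings$channel < 950, ]
  if (nrow(near)) expect_true(all(near$criterion > ms3$theta))
})

test_that("mode count is invariant to rescaling total counts", {
  h <- rmix_hist(20000, c(250, 700), c(40, 80), c(0.5, 0.5), seed = 84)
  h3x <- channel_histogram(h$counts * 3)
  expect_equal(detect_modes(h)$modes, detect_modes(h3x)$modes)
})

test_that("mode-anchored EM pins means and recovers weights", {
  h <- rmix_hist(30000, c(250, 700), c(40, 80), c(0.5, 0.5), seed = 85)
  me <- fit_me_em(h)
  expect_equal(me$model$means, me$modes$modes)
  expect_lt(max(abs(me$model$weights - 0.49)), 0.05)
  expect_mass_conserved(me$model)
  # the fixed-means optimum cannot beat the free optimum at the same K
  em <- fit_em_restarts(h, length(me$modes$modes), n_restarts = 20,
                        seed = 3)
  expect_lte(me$loglik, em$loglik + 1e-6)
  # no modes: instructive error
  flat <- channel_histogram(rep(2, 1024))
  expect_error(fit_me_em(flat), "fall back")
})

test_that("a blended high subpopulation splits EM and mode detection", {
  # broad high component merged into the low peak: one mode in the
  # density, but cross-validated EM still resolves two components
  h <- rmix_hist(30000, c(250, 340), c(40, 150), c(0.55, 0.45), seed = 21)
  expect_length(detect_modes(h)$modes, 1)
  dec <- select_num_components(h, restarts = 10, seed = 2)
  expect_gte(dec$chosen_k, 2L)
})
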