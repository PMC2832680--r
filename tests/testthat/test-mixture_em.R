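test_that("mixture log-likelihood matches the closed form and brute force", {
  # all events in one channel: per-event log p has a closed form
  counts <- rep(0, 1024); counts[500] <- 250
  h <- channel_histogram(counts)
  m <- mixture_model(500, 30, 0.98)
  expected <- log(0.02 / 1024 + 0.98 / (30 * sqrt(2 * pi)))
  expect_equal(mixture_loglik(m, h)$loglik, 250 * expected,
               tolerance = 1e-12)
  expect_equal(mixture_loglik(m, h)$mean_nll, -expected, tolerance = 1e-12)

  # brute-force event-by-event oracle on a 10-event toy histogram
  set.seed(8)
  ev <- sample(1:1024, 10, replace = TRUE)
  h10 <- events_to_hist(ev)
  m2 <- mixture_model(c(200, 640), c(35, 90), c(0.58, 0.40))
  brute <- sum(vapply(ev, function(c)
    log(0.02 / 1024 + 0.58 * dnorm(c, 200, 35) + 0.40 * dnorm(c, 640, 90)),
    numeric(1)))
  expect_equal(mixture_loglik(m2, h10)$loglik, brute, tolerance = 1e-10)
})

test_that("log-likelihood is invariant to joint translation of data and means", {
  h <- rmix_hist(2000, 300, 40, 1, seed = 11, uniform_weight = 0)
  delta <- 150
  m <- mixture_model(c(280, 330), c(30, 60), c(0.5, 0.48))
  m_shift <- mixture_model(c(280, 330) + delta, c(30, 60), c(0.5, 0.48))
  h_shift <- channel_histogram(c(rep(0, delta),
                                 h$counts[1:(1024 - delta)]))
  expect_equal(mixture_loglik(m, h)$loglik,
               mixture_loglik(m_shift, h_shift)$loglik, tolerance = 1e-9)
})

test_that("single-component EM recovers the sample moments", {
  # with the uniform component off, the K = 1 maximum likelihood fit is
  # exactly the count-weighted sample mean and standard deviation
  h0 <- rmix_hist(50000, 300, 50, 1, seed = 21, uniform_weight = 0)
  fit0 <- fit_em(h0, 1, uniform_weight = 0, tol = 1e-12)
  ch <- seq_len(1024)
  mu <- sum(h0$counts * ch) / sum(h0$counts)
  sd_ <- sqrt(sum(h0$counts * (ch - mu)^2) / sum(h0$counts))
  expect_equal(fit0$model$means, mu, tolerance = 1e-6)
  expect_equal(fit0$model$sds, sd_, tolerance = 1e-6)
  # with 2% uniform outliers present, the fixed-weight uniform component
  # absorbs them and the Gaussian still recovers the generating moments
  h <- rmix_hist(50000, 300, 50, 1, seed = 21)
  fit <- fit_em(h, 1)
  expect_lt(abs(fit$model$means - 300), 2)
  expect_lt(abs(fit$model$sds - 50), 2)
  expect_mass_conserved(fit$model)
})

test_that("a component collapsing onto one channel is eliminated", {
  counts <- rep(0, 1024); counts[400] <- 5000
  h <- channel_histogram(counts)
  fit <- fit_em(h, 1)
  expect_identical(fit$eliminated_components, 1L)
  expect_true(fit$degenerate)
  expect_length(fit$model$means, 0)
  expect_equal(fit$model$uniform_weight, 1)
  expect_equal(fit$loglik, 5000 * log(1 / 1024))
})

test_that("two-component EM recovers well-separated subpopulations", {
  h <- rmix_hist(30000, c(250, 700), c(40, 80), c(0.5, 0.5), seed = 33)
  fit <- fit_em_restarts(h, 2, n_restarts = 10, seed = 1)
  expect_lt(max(abs(fit$model$means - c(250, 700))), 5)
  expect_lt(max(abs(fit$model$sds - c(40, 80))), 5)
  expect_mass_conserved(fit$model)
  expect_true(trace_is_monotone(fit$loglik_trace))
})

test_that("restarts return the best run and are identity for one restart", {
  h <- rmix_hist(8000, c(250, 700), c(40, 80), c(0.5, 0.5), seed = 44)
  singles <- lapply(1:8, function(i)
    fit_em(h, 2, init = stochbif:::random_init(
      h, 2, stochbif:::restart_seed(5, i))))
  best <- fit_em_restarts(h, 2, n_restarts = 8, seed = 5)
  for (s in singles) expect_gte(best$loglik + 1e-9, s$loglik)
  one <- fit_em_restarts(h, 2, n_restarts = 1, seed = 5)
  expect_equal(one$model, singles[[1]]$model)
  expect_equal(one$loglik, singles[[1]]$loglik)
  # a deliberately bad initialization cannot beat the restart search
  bad_init <- mixture_model(c(1, 1.001), c(50, 50), c(0.49, 0.49))
  bad <- fit_em(h, 2, init = bad_init)
  expect_gte(best$loglik, bad$loglik - 1e-9)
})

test_that("EM ascends monotonically and conserves mass across seeds", {
  for (s in 1:5) {
    h <- rmix_hist(4000, c(250, 700), c(40, 80), c(0.6, 0.4), seed = 300 + s)
    fit <- fit_em(h, 2, init = stochbif:::random_init(
      h, 2, stochbif:::restart_seed(s, 1)))
    expect_true(trace_is_monotone(fit$loglik_trace))
    expect_mass_conserved(fit$model)
  }
})

test_that("K larger than the number of occupied channels is rejected", {
  counts <- rep(0, 1024); counts[c(100, 200)] <- 10
  expect_error(fit_em(channel_histogram(counts), 3), "occupied channels")
})
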