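test_that("the low-component weight follows the threshold-exponential form", {
  m <- conditional_mixture_model(g0 = 0.003, r = 150)
  expect_equal(weight_low(m, c(0, 0.001, 0.003)), rep(0.98, 3))
  m0 <- conditional_mixture_model(r = 0)
  expect_equal(weight_low(m0, c(0, 0.01, 10)), rep(0.98, 3))
  # half-life dose: g0 + ln(2)/r gives exactly half the plateau weight
  expect_equal(weight_low(m, 0.003 + log(2) / 150), 0.49)
})

test_that("predicted snapshot mixtures conserve mass and order", {
  m <- conditional_mixture_model()
  for (g in c(0, 0.0033, 0.0087, 0.08)) {
    p <- predict_mixture(m, g)
    expect_mass_conserved(p)
  }
  mu_high <- vapply(c(0, 0.01, 0.05, 0.08),
                    function(g) max(predict_mixture(m, g)$means),
                    numeric(1))
  expect_true(all(diff(mu_high) > 0))
})

test_that("CEM recovers the generating parameters from one replicate", {
  sp <- synthetic_spec(events_per_condition = 10000, n_replicates = 1,
                       pregrowths = "gal", replicate_jitter_sd = 0,
                       seed = 17)
  ds <- generate_dataset(sp)
  fit <- fit_cem(ds$histograms)
  truth <- sp$truth
  est <- coef(fit)
  expect_lt(abs(est[["b_high"]] - truth$b_high) / truth$b_high, 0.10)
  expect_lt(abs(est[["g0"]] - truth$g0) / truth$g0, 0.20)
  expect_lt(abs(est[["a_low"]] - truth$a_low), 10)
  expect_lt(abs(est[["sigma_high"]] - truth$sigma_high), 8)
  expect_true(fit$converged)
  # EM ascent with the ascent-guarded weight step
  expect_true(trace_is_monotone(fit$loglik_trace, tol = 1e-8))
})

test_that("an all-low dataset keeps the low weight near its plateau", {
  sp <- synthetic_spec(truth = conditional_mixture_model(g0 = 0.05),
                       concentrations = c(0, 0.01, 0.02, 0.03),
                       events_per_condition = 20000, n_replicates = 1,
                       pregrowths = "gal", replicate_jitter_sd = 0,
                       seed = 4)
  ds <- generate_dataset(sp)
  fit <- fit_cem(ds$histograms)
  expect_true(all(weight_low(fit$model, c(0, 0.01, 0.02, 0.03)) >= 0.95))
})

test_that("identifiability requires at least three distinct doses", {
  h1 <- rmix_hist(1000, 300, 50, 1, seed = 1, concentration = 0)
  h2 <- rmix_hist(1000, 300, 50, 1, seed = 2, concentration = 0.01)
  expect_error(fit_cem(list(h1)), ">= 3 distinct")
  expect_error(fit_cem(list(h1, h2)), ">= 3 distinct")
})

test_that("fitted mean curves do not cross on the observed dose range", {
  sp <- synthetic_spec(events_per_condition = 8000, n_replicates = 1,
                       pregrowths = "gal", seed = 23)
  ds <- generate_dataset(sp)
  fit <- fit_cem(ds$histograms)
  g <- seq(0, max(sp$concentrations), length.out = 200)
  m <- fit$model
  expect_true(all(m$a_high + m$b_high * g > m$a_low + m$b_low * g))
})

test_that("snapshot predictions reproduce the training likelihood", {
  sp <- synthetic_spec(events_per_condition = 4000,
                       concentrations = c(0, 0.004, 0.009, 0.02),
                       n_replicates = 1, pregrowths = "gal", seed = 31)
  ds <- generate_dataset(sp)
  fit <- fit_cem(ds$histograms)
  ll <- sum(vapply(ds$histograms, function(h)
    mixture_loglik(predict_mixture(fit$model, h$concentration), h)$loglik,
    numeric(1)))
  n <- sum(vapply(ds$histograms, function(h) sum(h$counts), numeric(1)))
  expect_equal(-ll / n, fit$mean_nll, tolerance = 1e-9)
})
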