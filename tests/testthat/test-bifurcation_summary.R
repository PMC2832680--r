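test_that("structure extraction renormalizes fractions by the Gaussian mass", {
  single <- mixture_model(300, 50, 0.98)
  st1 <- extract_structure(list(`0` = single))
  expect_identical(st1$n_subpops, 1L)
  expect_equal(st1$fraction, 1)
  both <- mixture_model(c(250, 700), c(40, 80), c(0.49, 0.49))
  st2 <- extract_structure(list(`0.0087` = both))
  expect_equal(st2$fraction, c(0.5, 0.5))
  expect_equal(sum(st2$fraction), 1, tolerance = 1e-9)
})

test_that("a vanishing low component is omitted above the report threshold", {
  m <- conditional_mixture_model(g0 = 0.003, r = 150)
  fit <- structure(list(model = m, concentrations = c(0, 0.04)),
                   class = "cem_fit")
  # weight_low(0.04) = 0.98 exp(-150*0.037) ~ 3.8e-3 < 0.01
  expect_lt(weight_low(m, 0.04), 0.01)
  st <- extract_structure(fit)
  at_high <- st[st$concentration == 0.04, ]
  expect_identical(nrow(at_high), 1L)
  expect_equal(at_high$location, m$a_high + m$b_high * 0.04)
  at_zero <- st[st$concentration == 0, ]
  expect_identical(nrow(at_zero), 1L)  # high weight is 0 below g0
  expect_equal(at_zero$location, m$a_low)
})

test_that("training-replicate evaluation reproduces the stored fit score", {
  h <- rmix_hist(5000, c(250, 700), c(40, 80), c(0.5, 0.5), seed = 61,
                 concentration = 0.0087, replicate = "1", pregrowth = "gal")
  fit <- fit_em_restarts(h, 2, n_restarts = 5, seed = 1)
  expect_equal(stochbif:::model_mean_nll(fit, h), fit$mean_nll,
               tolerance = 1e-12)
})

test_that("identical replicates give equal training and testing scores", {
  h <- rmix_hist(4000, c(250, 700), c(40, 80), c(0.5, 0.5), seed = 62,
                 concentration = 0.005)
  mk <- function(r) channel_histogram(h$counts, 0.005, r, "gal")
  ds <- fc_dataset(lapply(c("1", "2", "3"), mk))
  model <- fit_em_restarts(mk("1"), 2, n_restarts = 5, seed = 1)
  models <- list(EM = list(`gal:1` = list(`0.005` = model),
                           `gal:2` = list(`0.005` = model),
                           `gal:3` = list(`0.005` = model)))
  sc <- train_test_nll(models, ds, n_boot = 50, seed = 1)
  expect_equal(sc$scores$train, sc$scores$test, tolerance = 1e-9)
})

test_that("variability decomposition matches direct computation", {
  arr0 <- array(5, dim = c(3, 4, 2),
                dimnames = list(c("EM", "ME+EM", "CEM"), 1:4, c("P1", "P2")))
  vd0 <- variability_decomposition(arr0)
  expect_equal(vd0$bio_sd, c(0, 0))
  expect_equal(vd0$method_sd, c(0, 0))

  arr1 <- array(rep(c(100, 110, 120, 130), each = 3), dim = c(3, 4, 1))
  vd1 <- variability_decomposition(arr1)
  expect_equal(vd1$method_sd, 0)
  expect_equal(vd1$bio_sd, sd(c(100, 110, 120, 130)))

  set.seed(9)
  arr2 <- array(rnorm(24, 500, 30), dim = c(3, 4, 2))
  vd2 <- variability_decomposition(arr2)
  for (lm in 1:2) {
    expect_equal(vd2$bio_sd[lm],
                 sd(colMeans(arr2[, , lm])), tolerance = 1e-12)
    expect_equal(vd2$method_sd[lm],
                 sd(rowMeans(arr2[, , lm])), tolerance = 1e-12)
  }
  arr2[2, 3, 1] <- NA
  expect_error(variability_decomposition(arr2), "missing location")
})

test_that("replicate mismatch in concentrations is rejected", {
  mk <- function(r, g) rmix_hist(1000, 300, 50, 1, seed = 5,
                                 concentration = g, replicate = r)
  ds <- fc_dataset(list(mk("1", 0), mk("2", 0.01)))
  model <- fit_em_restarts(mk("1", 0), 1, n_restarts = 2, seed = 1)
  models <- list(EM = list(`gal:1` = list(`0` = model)))
  expect_error(train_test_nll(models, ds, n_boot = 10), "share")
})
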