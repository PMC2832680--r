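test_that("the default spec matches the emulated experimental design", {
  sp <- default_galactose_spec()
  expect_length(sp$concentrations, 17)
  expect_identical(sp$n_replicates, 4L)
  expect_identical(sp$events_per_condition, 60000L)
  expect_equal(sp$gate_fraction, 0.5)
  expect_setequal(sp$pregrowths, c("gal", "raf"))
  expect_error(synthetic_spec(concentrations = c(0, 0, 0.01)), "distinct")
  expect_error(synthetic_spec(gate_fraction = 0), "gate_fraction")
})

test_that("generation is reproducible given the seed", {
  sp <- synthetic_spec(events_per_condition = 2000,
                       concentrations = c(0, 0.005, 0.02),
                       n_replicates = 2, pregrowths = "gal", seed = 42)
  ds1 <- generate_dataset(sp)
  ds2 <- generate_dataset(sp)
  expect_identical(lapply(ds1$histograms, unclass),
                   lapply(ds2$histograms, unclass))
  ds3 <- generate_dataset(synthetic_spec(events_per_condition = 2000,
                                         concentrations = c(0, 0.005, 0.02),
                                         n_replicates = 2,
                                         pregrowths = "gal", seed = 43))
  expect_false(identical(lapply(ds1$histograms, unclass),
                         lapply(ds3$histograms, unclass)))
})

test_that("outlier and gate fractions match their nominal rates", {
  tot_out <- 0; tot_ret <- 0; tot_drawn <- 0
  for (s in 1:10) {
    sp <- synthetic_spec(events_per_condition = 3000,
                         concentrations = c(0, 0.005, 0.02),
                         n_replicates = 1, pregrowths = "gal", seed = s)
    ds <- generate_dataset(sp, keep_labels = TRUE)
    lab <- attr(ds, "labels")
    tot_out <- tot_out + sum(lab$n_outlier)
    tot_ret <- tot_ret + sum(lab$n_retained)
    tot_drawn <- tot_drawn + nrow(lab) * sp$events_per_condition
  }
  se_out <- sqrt(0.02 * 0.98 / tot_ret)
  expect_lt(abs(tot_out / tot_ret - 0.02), 3 * se_out)
  # retained events within 4 binomial SDs of events * gate_fraction
  se_ret <- sqrt(0.5 * 0.5 * tot_drawn)
  expect_lt(abs(tot_ret - 0.5 * tot_drawn), 4 * se_ret)
})

test_that("the empirical density converges to the generating mixture", {
  truth <- conditional_mixture_model()
  g <- 0.0087
  tv <- vapply(c(3000L, 60000L), function(n) {
    sp <- synthetic_spec(events_per_condition = n, concentrations = g,
                         n_replicates = 1, pregrowths = "gal",
                         replicate_jitter_sd = 0, seed = 99)
    ds <- generate_dataset(sp)
    emp <- to_density(ds$histograms[[1]])
    thr <- mixture_density(predict_mixture(truth, g))
    sum(abs(emp - thr / sum(thr))) / 2
  }, numeric(1))
  expect_lt(tv[2], tv[1])
  expect_lt(tv[2], 0.08)
})

test_that("scatter gating is independent of fluorescence", {
  base <- list(events_per_condition = 40000L, concentrations = 0.0087,
               n_replicates = 1, pregrowths = "gal",
               replicate_jitter_sd = 0, seed = 7)
  full <- generate_dataset(do.call(synthetic_spec,
                                   c(base, gate_fraction = 1)))
  gated <- generate_dataset(do.call(synthetic_spec,
                                    c(base, gate_fraction = 0.4)))
  cdf_f <- cumsum(to_density(full$histograms[[1]]))
  cdf_g <- cumsum(to_density(gated$histograms[[1]]))
  expect_lt(max(abs(cdf_f - cdf_g)), 0.02)
})

test_that("an infinite decay rate empties the low component above g0", {
  truth <- conditional_mixture_model(r = 1e9)
  sp <- synthetic_spec(truth = truth, events_per_condition = 5000,
                       concentrations = c(0, 0.004),
                       n_replicates = 1, pregrowths = "gal", seed = 3)
  ds <- generate_dataset(sp, keep_labels = TRUE)
  lab <- attr(ds, "labels")
  above <- lab[grepl(":0.004$", lab$key), ]
  expect_identical(above$n_low, 0L)
  below <- lab[grepl(":0$", lab$key), ]
  expect_identical(below$n_high, 0L)
})
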