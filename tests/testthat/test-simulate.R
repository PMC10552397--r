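test_that("the temperature grid and dilution series match the standard designs", {
  grid <- make_temperature_grid()
  expect_length(grid, 10)
  expect_equal(min(grid), 36.5)
  expect_equal(max(grid), 67.0)
  expect_true(all(diff(grid) > 0))
  expect_equal(grid[1], 36.5)   # the abundance reference temperature

  doses <- make_concentration_series()
  expect_length(doses, 10)
  expect_equal(doses[1], 0)
  expect_equal(signif(doses[-1], 2),
               c(0.098, 0.39, 1.6, 6.2, 25, 100, 400, 1600, 6400))
  ratios <- doses[-(1:2)] / doses[2:(length(doses) - 1)]
  expect_true(all(abs(ratios - 4) < 1e-9))

  expect_equal(make_concentration_series(100, 3, 10), c(0, 1, 10, 100))
})

test_that("the TR simulator is deterministic with stable substreams", {
  s1 <- simulate_tr_experiment(8, seed = 5)
  expect_equal(dim(s1$matrix$values), c(8, 60))
  s1b <- simulate_tr_experiment(8, seed = 5)
  expect_identical(s1$matrix$values, s1b$matrix$values)
  # growing the cohort leaves earlier proteins untouched
  s2 <- simulate_tr_experiment(16, seed = 5)
  expect_identical(s1$matrix$values, s2$matrix$values[1:8, ])
  expect_identical(s1$truth, s2$truth[1:8, ])

  bad <- truth_spec()
  bad$proportions["unaffected"] <- 0.5
  expect_error(simulate_tr_experiment(5, bad, seed = 1), "sum to 1")
})

test_that("an unaffected protein has unit compound/vehicle ratios without noise", {
  spec <- truth_spec(proportions = c(unaffected = 1, stabilized = 0,
                                     destabilized = 0, abundance_up = 0,
                                     abundance_down = 0))
  sim <- simulate_tr_experiment(3, spec, noise_model(0, 0, 0), seed = 2)
  ann <- sim$matrix$annotation
  for (tmp in unique(ann$temperature)) for (r in unique(ann$replicate)) {
    comp <- sim$matrix$values[, ann$temperature == tmp & ann$replicate == r &
                                ann$treatment == "compound"]
    veh <- sim$matrix$values[, ann$temperature == tmp & ann$replicate == r &
                               ann$treatment == "vehicle"]
    expect_equal(unname(comp / veh), rep(1, 3))
  }
})

test_that("noise magnitudes match the noise model", {
  spec <- truth_spec(proportions = c(unaffected = 1, stabilized = 0,
                                     destabilized = 0, abundance_up = 0,
                                     abundance_down = 0))
  sim <- simulate_tr_experiment(600, spec, noise_model(0.1, 0, 0), seed = 7)
  ann <- sim$matrix$annotation
  cvs <- c()
  for (tmp in unique(ann$temperature)) for (arm in c("vehicle", "compound")) {
    v <- sim$matrix$values[, ann$temperature == tmp & ann$treatment == arm,
                           drop = FALSE]
    cvs <- c(cvs, apply(v, 1, function(r) sd(r) / mean(r)))
  }
  # the 3-replicate sample CV underestimates the population CV by the
  # c4 correction (~0.886 at n = 3); compare the corrected mean
  expect_lt(abs(mean(cvs, na.rm = TRUE) / 0.886 - 0.1) / 0.1, 0.2)

  sim2 <- simulate_tr_experiment(500, spec, noise_model(0.1, 0.2, 0.1),
                                 seed = 9)
  n <- length(sim2$matrix$values)
  frac <- mean(is.na(sim2$matrix$values))
  ci <- qbinom(c(0.005, 0.995), n, 0.1) / n
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("the CCR simulator encodes dose responses at the right temperature", {
  spec <- truth_spec(proportions = c(unaffected = 0, stabilized = 1,
                                     destabilized = 0, abundance_up = 0,
                                     abundance_down = 0))
  sim <- simulate_ccr_experiment(3, spec, noise_model(0, 0, 0), seed = 4)
  expect_equal(dim(sim$matrix$values), c(3, 60))
  ann <- sim$matrix$annotation
  hot <- ann$assay_temperature == 50 & ann$replicate == 1
  cold <- ann$assay_temperature == 37 & ann$replicate == 1
  o_hot <- order(ann$concentration[hot])
  y_hot <- sim$matrix$values[1, hot][o_hot]
  expect_true(all(diff(y_hot) > 0))            # rises with dose at 50 degC
  y_cold <- sim$matrix$values[1, cold]
  expect_lt(diff(range(y_cold)) / mean(y_cold), 1e-12)   # flat at 37 degC

  # abundance class shows the identical relative trend at both temperatures
  spec_ab <- truth_spec(proportions = c(unaffected = 0, stabilized = 0,
                                        destabilized = 0, abundance_up = 1,
                                        abundance_down = 0))
  sim2 <- simulate_ccr_experiment(2, spec_ab, noise_model(0, 0, 0), seed = 4)
  v <- sim2$matrix$values[1, ]
  rel_hot <- v[hot][o_hot] / v[hot][o_hot][1]
  o_cold <- order(ann$concentration[cold])
  rel_cold <- v[cold][o_cold] / v[cold][o_cold][1]
  expect_equal(unname(rel_hot), unname(rel_cold), tolerance = 1e-9)
})
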