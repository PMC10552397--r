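make_tr_vectors <- function(delta_tm = 0, abundance_log2fc = 0,
                            params = melting_params(0.05, 1, 51, -0.45)) {
  design <- build_tr_design(make_temperature_grid(), 3)
  y <- noiseless_protein(design, params, delta_tm, abundance_log2fc)
  list(y = y, ann = design, params = params)
}

test_that("per-temperature tests report null, degenerate and missing cases", {
  v <- make_tr_vectors()
  pt <- per_temperature_tests(v$y, v$ann)
  expect_equal(pt$log2_ratio, rep(0, 10))
  expect_equal(pt$p, rep(1, 10))

  # exact doubling in every replicate: ratio 1, zero-variance flagged
  y2 <- v$y
  comp <- v$ann$treatment == "compound"
  y2[comp] <- 2 * y2[comp]
  pt2 <- per_temperature_tests(y2, v$ann)
  expect_equal(pt2$log2_ratio, rep(1, 10))
  expect_true(all(pt2$degenerate))
  expect_true(all(pt2$p == .Machine$double.xmin))

  # one replicate pair only: ratio reported, p absent
  one <- v$ann$replicate == 1
  pt3 <- per_temperature_tests(v$y[one], v$ann[one, ])
  expect_equal(pt3$n_pairs, rep(1, 10))
  expect_true(all(is.na(pt3$p)))
  expect_equal(pt3$log2_ratio, rep(0, 10))
})

test_that("melting-point shifts are recovered exactly without noise", {
  v <- make_tr_vectors()
  dt <- compute_delta_tm(v$y, v$ann)      # free per-arm fits
  expect_lt(abs(dt$delta_tm), 1e-6)

  v2 <- make_tr_vectors(delta_tm = 2)
  dt2 <- compute_delta_tm(v2$y, v2$ann)
  expect_lt(abs(dt2$delta_tm - 2), 1e-3)

  # conditioned fits (frozen true shape, shared amplitude) are also exact
  shape <- list(pl = 0.05, s = -0.45, tm = 51)
  dt3 <- compute_delta_tm(v2$y, v2$ann, shape = shape,
                          shared_amplitude = TRUE)
  expect_lt(abs(dt3$delta_tm - 2), 1e-5)
  expect_equal(dt3$n, 3)
})

test_that("abundance changes read out at the lowest temperature only", {
  stab <- make_tr_vectors(delta_tm = 2)
  ab <- abundance_change(stab$y, stab$ann)
  expect_lt(abs(ab$log2fc), 0.1)   # stability is not abundance

  up <- make_tr_vectors(abundance_log2fc = 1)
  ab2 <- abundance_change(up$y, up$ann)
  expect_equal(ab2$log2fc, 1)
})

test_that("the distance score collates significant temperatures", {
  pt <- data.frame(temperature = c(40, 50, 60), log2_ratio = c(0.2, 1, 1),
                   p = c(0.5, 0.2, 0.9))
  expect_equal(distance_score(pt)$score, 0)
  expect_true(is.na(distance_score(pt)$collation_ratio))

  pt$p <- c(0.5, 0.01, 0.9)
  expect_equal(distance_score(pt)$score, 1)
  expect_equal(distance_score(pt)$collation_ratio, 2)

  pt$p <- c(0.5, 0.01, 0.01)
  ds <- distance_score(pt)
  expect_equal(ds$score, sqrt(2))
  expect_equal(ds$n_significant, 2L)

  pt$log2_ratio <- c(0.2, -1, -1)
  expect_equal(distance_score(pt)$score, -sqrt(2))
})

test_that("classification requires component-level significance", {
  res <- data.frame(protein_id = "P1", delta_tm = 1.2, stab_p = 0.5,
                    abundance_log2fc = 0.4, abund_p = 0.5)
  res$per_temperature <- list(data.frame(p = rep(0.001, 10)))
  out <- classify_differential(res, alpha = 0.05)
  expect_true(out$significant)
  expect_equal(out$class, "none")   # neither component individually firm

  res$stab_p <- 1e-4
  out2 <- classify_differential(res, alpha = 0.05)
  expect_equal(out2$class, "stabilized")
  res$delta_tm <- -1.2
  expect_equal(classify_differential(res, 0.05)$class, "destabilized")
})

test_that("differential results are scale invariant and antisymmetric", {
  sim <- simulate_tr_experiment(12, seed = 71)
  nrm <- normalize_tr(sim$matrix)
  res <- analyze_differential(nrm$matrix, shape_params = nrm$report$protein_params)

  # scale invariance: a global factor changes nothing
  x10 <- nrm$matrix
  x10$values <- x10$values * 10
  pp10 <- nrm$report$protein_params
  pp10$i_min <- pp10$i_min * 10
  pp10$i_max <- pp10$i_max * 10
  res10 <- analyze_differential(x10, shape_params = pp10)
  # melting points agree up to optimizer convergence wiggle
  expect_equal(res10$delta_tm, res$delta_tm, tolerance = 1e-3)
  expect_equal(res10$abundance_log2fc, res$abundance_log2fc,
               tolerance = 1e-10)
  expect_equal(res10$distance_score, res$distance_score, tolerance = 1e-10)

  # antisymmetry: swapping arm labels negates the signed outputs
  xs <- nrm$matrix
  xs$annotation$treatment <- ifelse(xs$annotation$treatment == "compound",
                                    "vehicle", "compound")
  ress <- analyze_differential(xs, shape_params = nrm$report$protein_params)
  expect_equal(ress$delta_tm, -res$delta_tm, tolerance = 1e-4)
  expect_equal(ress$abundance_log2fc, -res$abundance_log2fc,
               tolerance = 1e-10)
  expect_equal(ress$distance_score, -res$distance_score, tolerance = 1e-10)
})

test_that("null per-temperature p-values are uniform and BH calibrated", {
  # moderate-size null cohort; the acceptance suite runs the full-size one
  spec <- truth_spec(proportions = c(unaffected = 1, stabilized = 0,
                                     destabilized = 0, abundance_up = 0,
                                     abundance_down = 0))
  sim <- simulate_tr_experiment(300, spec, noise_model(cv = 0.1), seed = 19)
  nrm <- normalize_tr(sim$matrix)
  res <- analyze_differential(nrm$matrix,
                              shape_params = nrm$report$protein_params)
  expect_lte(mean(res$significant), 0.05)
  ps <- unlist(lapply(res$per_temperature, function(pt) pt$p))
  ks <- suppressWarnings(ks.test(ps[is.finite(ps)], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("CETSA series are normalized per blot and recover the shift", {
  # a series already expressed as soluble fraction: normalization ~identity
  grid <- make_temperature_grid()
  p <- melting_params(0, 1, 50, -0.45)
  ser <- data.frame(treatment = "vehicle", replicate = 1, temperature = grid,
                    intensity = melting_model(p, grid))
  ser <- rbind(ser, transform(ser, treatment = "compound"))
  out <- analyze_cetsa(ser)
  expect_equal(out$normalized$intensity, ser$intensity, tolerance = 1e-6)

  # scale invariance: rescaling one blot changes nothing
  ser2 <- simulate_cetsa_series(delta_tm = 2, cv = 0.05, seed = 4)
  out2 <- analyze_cetsa(ser2)
  ser3 <- ser2
  sel <- ser3$treatment == "vehicle" & ser3$replicate == 1
  ser3$intensity[sel] <- 7.3 * ser3$intensity[sel]
  out3 <- analyze_cetsa(ser3)
  expect_equal(out3$delta_tm, out2$delta_tm, tolerance = 1e-6)

  # shift recovery within the simulation-oracle tolerance (free 3-parameter
  # fits from 10 immunoblot points; oracle max error 0.5 over 20 seeds)
  expect_lt(abs(out2$delta_tm - 2), 0.75)
  expect_lt(out2$stab_p, 0.05)

  # an all-zero (failed blot) series is excluded with a warning, the rest
  # analyzed
  ser4 <- ser2
  ser4$intensity[ser4$treatment == "vehicle" & ser4$replicate == 2] <- 0
  expect_warning(out4 <- analyze_cetsa(ser4), "excluded")
  expect_true(is.finite(out4$delta_tm))
})
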