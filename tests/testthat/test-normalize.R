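test_that("reference selection picks the highest-level sample deterministically", {
  base <- matrix(10^runif(30, 4, 6), 10, 3)
  same <- cbind(base[, 1], base[, 1], base[, 1])
  expect_equal(select_reference_sample(same), 1)   # tie -> lowest index

  g <- cbind(A = base[, 1], B = 2 * base[, 1], C = 4 * base[, 1])
  expect_equal(select_reference_sample(g), 3)
  # permutation equivariance
  expect_equal(select_reference_sample(g[, c(3, 1, 2)]), 1)
})

test_that("within-temperature normalization aligns samples to the reference", {
  set.seed(3)
  base <- 10^runif(20, 4, 6)
  g <- cbind(A = base, B = 2 * base, C = 4 * base)
  res <- normalize_within_temperature(g)
  expect_equal(res$reference, 3)
  expect_equal(unname(res$constants), c(4, 2, 1))
  expect_equal(res$group[, 1], res$group[, 3])
  expect_equal(res$group[, 2], res$group[, 3])

  # identical samples: identity
  same <- cbind(base, base, base)
  expect_equal(unname(normalize_within_temperature(same)$constants),
               c(1, 1, 1))

  # mixed per-protein fold changes 1/2/4 vs the reference: the constant is
  # 2^median(log2 ratio), computed here by direct enumeration
  ref <- base[1:9]
  smp <- ref * rep(c(1, 2, 4), each = 3)
  g2 <- cbind(smp = smp, ref = ref)
  res2 <- normalize_within_temperature(g2, reference = 2)
  expected_c <- 2^median(log2(ref / smp))
  expect_equal(expected_c, 2^-1)
  expect_equal(unname(res2$constants[1]), expected_c)
})

test_that("step 1 is idempotent and recovers simulated scale errors", {
  spec <- truth_spec(proportions = c(unaffected = 1, stabilized = 0,
                                     destabilized = 0, abundance_up = 0,
                                     abundance_down = 0))
  sim <- simulate_tr_experiment(50, spec, noise_model(0, 0.3, 0), seed = 21)
  s1 <- normalize_tr_step1(sim$matrix)
  # noise off: constants equal the inverse scale errors up to one factor
  # per temperature group (the reference's own error)
  ann <- sim$matrix$annotation
  for (tmp in unique(ann$temperature)) {
    ids <- ann$sample_id[ann$temperature == tmp]
    ratio <- s1$constants[ids] * 2^sim$scale_errors[ids]
    expect_lt(diff(range(ratio)) / mean(ratio), 1e-10)
  }
  # idempotence: renormalizing the output (with reference continuity, as
  # medians are not transitive across re-elected references) gives all
  # constants 1
  s1b <- normalize_tr_step1(s1$matrix, references = s1$reference_samples)
  expect_true(all(abs(s1b$constants - 1) < 1e-12))
})

test_that("global-curve alignment preserves every within-temperature ratio", {
  sim <- simulate_tr_experiment(40, seed = 33)
  s1 <- normalize_tr_step1(sim$matrix)
  s2 <- normalize_tr_step2(s1$matrix)
  ann <- s1$matrix$annotation
  for (tmp in unique(ann$temperature)) {
    cols <- ann$sample_id[ann$temperature == tmp]
    before <- s1$matrix$values[, cols[1]] / s1$matrix$values[, cols[-1]]
    after <- s2$matrix$values[, cols[1]] / s2$matrix$values[, cols[-1]]
    # one constant per group: exact up to the last ulp of the multiply
    expect_equal(before, after, tolerance = 1e-14)
  }
  # the group summary point lands exactly on the fitted curve
  regroup <- normalize_tr_step2(s2$matrix)
  expect_true(all(abs(regroup$constants - 1) < 1e-6))
})

test_that("the lowest-temperature self-comparison yields unit intensity", {
  # six identical samples at T_low: all 36 pairwise median log2 ratios are
  # zero, so I(T_low) = 2^0 = 1
  base <- 10^runif(25, 4, 6)
  g <- matrix(rep(base, 6), ncol = 6)
  expect_equal(2^meltshift:::mean_median_log2fc(g, g), 1)
})

test_that("labeling-set leveling overlays sets without touching within-set ratios", {
  design <- build_tr_design(make_temperature_grid(), 1)
  p <- melting_params(0.05, 1, 52, -0.45)
  y <- noiseless_protein(design, p)
  # set 2 observed at half the scale of set 1
  y[design$labeling_set == 2] <- 0.5 * y[design$labeling_set == 2]
  vals <- rbind(P1 = y, P2 = y * 3)
  x <- intensity_matrix(vals, design)
  s3 <- normalize_tr_step3(x)
  expect_equal(nrow(s3$excluded), 0)
  expect_lt(abs(s3$params$tm[1] - 52), 1e-4)
  # after leveling both sets lie on one curve: cross-set ratio restored
  v <- s3$matrix$values["P1", ]
  m <- melting_model(melting_params(s3$params$i_min[1], s3$params$i_max[1],
                                    s3$params$tm[1], s3$params$s[1]),
                     design$temperature)
  expect_lt(max(abs(v / m - mean(v / m))), 1e-4)

  # within-set channel ratios bit-identical before/after
  sim <- simulate_tr_experiment(12, seed = 44)
  s12 <- normalize_tr_step2(normalize_tr_step1(sim$matrix)$matrix)
  s3b <- normalize_tr_step3(s12$matrix)
  kept <- rownames(s3b$matrix$values)
  ann <- s12$matrix$annotation
  for (set in unique(ann$labeling_set)) {
    cols <- ann$sample_id[ann$labeling_set == set]
    before <- s12$matrix$values[kept, cols[1]] /
      s12$matrix$values[kept, cols[2]]
    after <- s3b$matrix$values[, cols[1]] / s3b$matrix$values[, cols[2]]
    expect_equal(before, after, tolerance = 1e-14)
  }
})

test_that("the quality filter excludes sparse proteins with a reason", {
  sim <- simulate_tr_experiment(10, noise = noise_model(0.05, 0.1, 0),
                                seed = 8)
  ann <- sim$matrix$annotation
  # knock out 4 of 10 channels of protein 1 in labeling set 1
  hit <- which(ann$labeling_set == 1)[1:4]
  sim$matrix$values[1, hit] <- NA
  nrm <- normalize_tr(sim$matrix)
  expect_true(rownames(sim$matrix$values)[1] %in% nrm$report$excluded$protein_id)
  expect_match(nrm$report$excluded$reason[1], "labeling set")
  expect_false(rownames(sim$matrix$values)[1] %in% rownames(nrm$matrix$values))
  # every protein is either analyzed or excluded, never both or neither
  expect_setequal(c(rownames(nrm$matrix$values), nrm$report$excluded$protein_id),
                  rownames(sim$matrix$values))
})

test_that("matched compound/vehicle ratios survive the full normalization bit-exactly", {
  sim <- simulate_tr_experiment(30, seed = 55)
  s1 <- normalize_tr_step1(sim$matrix)
  nrm <- normalize_tr(sim$matrix)
  ann <- sim$matrix$annotation
  kept <- rownames(nrm$matrix$values)
  for (tmp in unique(ann$temperature)) for (r in unique(ann$replicate)) {
    sel <- ann$temperature == tmp & ann$replicate == r
    comp <- ann$sample_id[sel & ann$treatment == "compound"]
    veh <- ann$sample_id[sel & ann$treatment == "vehicle"]
    before <- s1$matrix$values[kept, comp] / s1$matrix$values[kept, veh]
    after <- nrm$matrix$values[, comp] / nrm$matrix$values[, veh]
    expect_equal(before, after, tolerance = 1e-14)
  }
})

test_that("CCR normalization anchors doses to the vehicle channel", {
  design <- build_ccr_design(replicates = 1)
  base <- 10^runif(15, 4, 6)
  vals <- matrix(rep(base, nrow(design)), ncol = nrow(design),
                 dimnames = list(sprintf("P%02d", 1:15), design$sample_id))
  x <- intensity_matrix(vals, design)
  res <- normalize_ccr(x)
  expect_true(all(abs(res$constants - 1) < 1e-12))
  expect_true(all(abs(res$matrix$values - 1) < 1e-12))  # relative scale

  # a sample globally multiplied by 3 gets constant 1/3
  x2 <- x
  x2$values[, 5] <- 3 * x2$values[, 5]
  res2 <- normalize_ccr(x2)
  expect_equal(unname(res2$constants[5]), 1 / 3)

  # missing vehicle channel is a hard error
  x3 <- subset_matrix(x, samples = design$sample_id[design$concentration > 0])
  expect_error(normalize_ccr(x3), "vehicle")
})
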