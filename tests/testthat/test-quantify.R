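test_that("summed-area estimator follows the direct formula and orientation", {
  expect_equal(aggregate_xpress(200, 100), -1)
  expect_equal(aggregate_xpress(c(100, 300), c(100, 300)), 0)
  expect_equal(aggregate_xpress(c(100, 100), c(50, 200)), log2(250 / 200))
  expect_equal(aggregate_xpress(c(100, 100), c(50, 200),
                                treated_channel = "light"),
               -log2(250 / 200))
  expect_error(aggregate_xpress(c(0, 0), c(1, 2)), "zero")
})

test_that("mean-based estimator matches the arithmetic-mean oracle", {
  r <- c(-1.0, -1.1, -0.9)
  res <- aggregate_asap(rep(1000, 3), 1000 * 2^r)
  expect_equal(res$log2_fc, -1.0)
  expect_equal(res$n_peptides, 3L)
  # all light = heavy
  res0 <- aggregate_asap(rep(500, 5), rep(500, 5))
  expect_equal(res0$log2_fc, 0)
  expect_equal(res0$se_log2, 0)
})

test_that("the two estimators agree exactly when all peptides share one ratio", {
  light <- c(100, 250, 900)
  heavy <- light * 2^(-0.7)
  expect_equal(aggregate_asap(light, heavy)$log2_fc,
               aggregate_xpress(light, heavy))
})

test_that("Dixon rejection removes a single gross outlier, one pass only", {
  r <- c(rep(-1, 9) + seq(-0.04, 0.04, by = 0.01), 2.0)
  res <- aggregate_asap(rep(1000, 10), 1000 * 2^r)
  expect_equal(res$n_rejected, 1L)
  expect_equal(res$n_peptides, 9L)
  expect_lt(abs(res$log2_fc - (-1)), 0.05)
  # no rejection below 3 peptides
  res2 <- aggregate_asap(rep(100, 2), 100 * 2^c(-1, 3))
  expect_equal(res2$n_rejected, 0L)
  expect_equal(res2$n_peptides, 2L)
})

test_that("zero-area peptides are excluded; all-zero input errors", {
  res <- aggregate_asap(c(100, 0, 100), c(50, 80, 50))
  expect_equal(res$n_excluded, 1L)
  expect_equal(res$log2_fc, -1)
  expect_error(aggregate_asap(c(0, 0), c(1, 1)), "no quantifiable peptides")
})

test_that("ratio significance is 1 at the median, ~0.05 at 1.96 spreads, symmetric and monotone", {
  set.seed(101)
  pop <- rnorm(200, sd = 0.4)
  ctr <- median(pop)
  s <- mad(pop)
  expect_equal(ratio_significance(ctr, pop), 1)
  expect_equal(ratio_significance(ctr + 1.96 * s, pop), 0.05, tolerance = 1e-3)
  for (d in c(0.1, 0.5, 1.2)) {
    expect_equal(ratio_significance(ctr + d, pop),
                 ratio_significance(ctr - d, pop))
  }
  dist <- seq(0, 3, by = 0.25)
  p <- ratio_significance(ctr + dist, pop)
  expect_true(all(diff(p) < 0))
})

test_that("degenerate populations error and suggest the sd fallback", {
  pop <- c(rep(0, 60), rnorm(40))
  expect_error(ratio_significance(0.5, pop), "sd")
  expect_gt(ratio_significance(0.5, pop, spread = "sd"), 0)
  expect_error(ratio_significance(0, rnorm(10)), "at least 20")
})

test_that("concordance rule matches a brute-force truth table", {
  expect_true(concordance_filter(1.5, 2.0))
  expect_false(concordance_filter(4.0, 1.2))
  expect_true(concordance_filter(5.0, 3.5))
  grid <- expand.grid(r1 = c(0.05, 0.2, 0.32, 0.33, 0.5, 0.9, 1, 1.5, 1.99,
                             2.5, 3.0, 3.01, 4, 8),
                      r2 = c(0.05, 0.2, 0.32, 0.33, 0.5, 0.9, 1, 1.5, 1.99,
                             2.5, 3.0, 3.01, 4, 8))
  want <- mapply(function(r1, r2) {
    (max(r1, r2) / min(r1, r2) < 2.0) || (r1 > 3.0 && r2 > 3.0) ||
      (r1 < 0.33 && r2 < 0.33)
  }, grid$r1, grid$r2)
  expect_identical(unname(concordance_filter(grid$r1, grid$r2)),
                   unname(want))
  expect_error(concordance_filter(-1, 2), "> 0")
})

test_that("replicate quantification preserves the repression sign convention", {
  cfg <- sim_config(n_proteins_total = 120, detect_prob = 1,
                    frac_true_targets = 0.2,
                    effect_range_log2 = c(-1.5, -0.8),
                    peptides_per_protein = c(8L, 8L), noise_sd_log2 = 0.1,
                    seed = 31)
  sim <- simulate_silac_experiment(cfg)
  r1 <- quantify_replicate(sim$peptides[sim$peptides$replicate == "rep1", ])
  targets <- sim$truth$protein_id[sim$truth$is_target]
  expect_true(all(r1$log2_fc[r1$protein_id %in% targets] < 0))
  expect_true(all(r1$p_value > 0 & r1$p_value <= 1))
  expect_named(r1, c("protein_id", "replicate", "log2_fc", "se_log2",
                     "n_peptides", "p_value", "xpress_log2_fc", "concordant"))
})
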