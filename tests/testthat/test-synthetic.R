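test_that("zero-noise, zero-effect simulation yields all peptide ratios exactly 1", {
  cfg <- sim_config(n_proteins_total = 100, noise_sd_log2 = 0,
                    frac_true_targets = 0, seed = 11)
  sim <- simulate_silac_experiment(cfg)
  expect_true(all(sim$peptides$light_area == sim$peptides$heavy_area))
  expect_true(all(sim$truth$true_log2fc == 0))
})

test_that("identical seed gives byte-identical peptide tables", {
  cfg <- sim_config(n_proteins_total = 150, seed = 42)
  f1 <- tempfile(); f2 <- tempfile()
  write_peptide_table(simulate_silac_experiment(cfg)$peptides, f1)
  write_peptide_table(simulate_silac_experiment(cfg)$peptides, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("replicate sizes and overlap match the binomial expectation", {
  cfg <- sim_config(n_proteins_total = 2000, detect_prob = 0.92, seed = 1)
  sim <- simulate_silac_experiment(cfg)
  n1 <- sum(sim$truth$detected_rep1)
  n2 <- sum(sim$truth$detected_rep2)
  shared <- sum(sim$truth$detected_rep1 & sim$truth$detected_rep2)
  # E[n_r] = N d = 1840, sd = sqrt(N d (1-d)) ~ 12.1; band = +/- 4 sd
  expect_true(n1 >= 1791 && n1 <= 1889)
  expect_true(n2 >= 1791 && n2 <= 1889)
  # E[shared] = N d^2 ~ 1693, sd = sqrt(N d^2 (1 - d^2)) ~ 16.1
  expect_true(shared >= 1628 && shared <= 1758)
  # each replicate contains only proteins drawn as detected in it
  det1 <- sim$truth$protein_id[sim$truth$detected_rep1]
  expect_setequal(unique(sim$peptides$protein_id[
    sim$peptides$replicate == "rep1"]), det1)
})

test_that("expected peptide log2 ratio equals the true effect; downstream mean is unbiased", {
  cfg <- sim_config(n_proteins_total = 200, detect_prob = 1,
                    frac_true_targets = 1, effect_range_log2 = c(-1, -1),
                    peptides_per_protein = c(10L, 10L), noise_sd_log2 = 0.3,
                    seed = 5)
  sim <- simulate_silac_experiment(cfg)
  pep1 <- sim$peptides[sim$peptides$replicate == "rep1", ]
  est <- vapply(split(pep1, pep1$protein_id), function(d)
    aggregate_asap(d$light_area, d$heavy_area)$log2_fc, numeric(1))
  expect_lt(abs(mean(est) - (-1.0)), 0.05)
})

test_that("channel orientation flips the measured ratio", {
  base <- list(n_proteins_total = 50L, detect_prob = 1, frac_true_targets = 1,
               effect_range_log2 = c(-1, -1), noise_sd_log2 = 0, seed = 9)
  sim_h <- simulate_silac_experiment(do.call(sim_config,
    c(base, treated_channel = "heavy")))
  sim_l <- simulate_silac_experiment(do.call(sim_config,
    c(base, treated_channel = "light")))
  expect_true(all(abs(log2(sim_h$peptides$heavy_area /
                             sim_h$peptides$light_area) - (-1)) < 1e-12))
  expect_true(all(abs(log2(sim_l$peptides$light_area /
                             sim_l$peptides$heavy_area) - (-1)) < 1e-12))
})

test_that("invalid config fields are reported by name", {
  expect_error(sim_config(detect_prob = 1.4), "detect_prob")
  expect_error(sim_config(n_proteins_total = 0), "n_proteins_total")
  expect_error(sim_config(effect_range_log2 = c(-1, 0.2)),
               "effect_range_log2")
  expect_error(sim_config(peptides_per_protein = c(5L, 2L)),
               "peptides_per_protein")
  expect_error(sim_config(noise_sd_log2 = -0.1), "noise_sd_log2")
})

test_that("UTR database implants are recorded with exact coordinates and class", {
  cfg <- sim_config(n_utrs = 20L, utr_length_range = c(300L, 800L),
                    frac_target_utrs = 0.5, seed = 21)
  mirnas <- read_mirna_fasta(mirscreen_example("mirnas.fasta"))
  db <- simulate_utr_database(cfg, mirnas)
  expect_gt(nrow(db$truth), 0)
  for (i in seq_len(nrow(db$truth))) {
    tr <- db$truth[i, ]
    utr <- db$utrs[[tr$gene]]
    expect_true(tr$start >= 1 && tr$end <= nchar(utr))
    expect_identical(substr(utr, tr$start, tr$end),
                     mirscreen:::seed_site_sequence(mirnas[[tr$mirna]],
                                                    tr$site_type))
  }
  # determinism: identical FASTA bytes under the same seed
  db2 <- simulate_utr_database(cfg, mirnas)
  expect_identical(db$utrs, db2$utrs)
  expect_identical(db$interactions, db2$interactions)
})

test_that("a UTR database with zero target UTRs yields no interactions", {
  cfg <- sim_config(n_utrs = 5L, utr_length_range = c(200L, 300L),
                    frac_target_utrs = 0, seed = 2)
  db <- simulate_utr_database(cfg, c(m1 = "UAACACUGUCUGGUAACGAUGU"))
  expect_identical(nrow(db$interactions), 0L)
})
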