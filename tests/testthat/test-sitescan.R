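mir200c <- "UAAUACUGCCGGGUAAUGAUGGA"

test_that("an implanted 8mer is found at its exact position and class", {
  site <- mirscreen:::seed_site_sequence(mir200c, "8mer")
  utr <- paste0(strrep("C", 100), site, strrep("C", 100))
  hits <- find_seed_sites(utr, mir200c)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 101L)
  expect_identical(hits$end, 108L)
  expect_identical(hits$site_type, "8mer")
})

test_that("empty, all-N and antisense-only UTRs yield no sites", {
  expect_identical(nrow(find_seed_sites(strrep("N", 200), mir200c)), 0L)
  expect_identical(nrow(find_seed_sites("ACG", mir200c)), 0L)
  # sense-strand convention: the reverse complement of a site is no site
  site <- mirscreen:::seed_site_sequence(mir200c, "8mer")
  anti <- mirscreen:::dna_revcomp(paste0(strrep("C", 50), site,
                                         strrep("C", 50)))
  expect_identical(nrow(find_seed_sites(anti, mir200c)), 0L)
})

test_that("invalid UTR characters are reported with their position", {
  expect_error(find_seed_sites("ACGTXACGT", mir200c), "'X' at position 5")
})

test_that("scanner equals the brute-force enumeration oracle", {
  set.seed(13)
  for (i in 1:50) {
    utr <- random_dna(sample(60:500, 1))
    mir <- random_rna(sample(19:23, 1))
    wob <- i %% 2 == 0
    expect_identical(find_seed_sites(utr, mir, allow_wobble = wob),
                     oracle_scan(utr, mir, allow_wobble = wob),
                     info = sprintf("case %d", i))
  }
})

test_that("wobble mode finds G:U-paired seeds that strict mode rejects", {
  mir <- "UAGCAGCACGUAAAUAUUGGCG"   # seed (2-7) AGCAGC
  # strict site core is GCTGCT; wobble allows T opposite miRNA G
  utr <- paste0(strrep("A", 30), "GTTGCT", strrep("C", 30))
  expect_identical(nrow(find_seed_sites(utr, mir)), 0L)
  expect_gt(nrow(find_seed_sites(utr, mir, allow_wobble = TRUE)), 0)
})

test_that("surrogate scores are deterministic, non-positive and ordered by class", {
  utr <- random_dna(200)
  s <- vapply(c("8mer", "7mer-m8", "7mer-A1", "6mer"), function(ty)
    score_site(ty, utr, 100, 107), numeric(1))
  expect_identical(s, vapply(names(s), function(ty)
    score_site(ty, utr, 100, 107), numeric(1)))
  expect_true(all(s <= 0))
  expect_true(s[["8mer"]] < s[["7mer-m8"]])
  expect_true(s[["7mer-m8"]] < s[["7mer-A1"]])
  expect_true(s[["7mer-A1"]] < s[["6mer"]])
  expect_error(score_site("9mer", utr, 1, 8), "unknown site type")
})

test_that("combined UTR score is the additive, permutation-invariant sum", {
  expect_equal(combined_utr_score(c(-0.45, -0.88)), -1.33)
  expect_equal(combined_utr_score(c(-0.88, -0.45)), -1.33)
  expect_equal(combined_utr_score(data.frame(score = numeric())), 0)
  expect_equal(combined_utr_score(-0.5), -0.5)
})

test_that("external score tables are attached verbatim, bypassing the surrogate", {
  set.seed(4)
  utrs <- c(PRKACB = random_dna(3191))
  tab <- load_site_scores(mirscreen_example("prkacb_mir200c_sites.tsv"))
  res <- scan_utrs(utrs, c(`hsa-miR-200c-3p` = mir200c), score_table = tab)
  expect_identical(res$predictions$n_sites, 2L)
  expect_equal(res$predictions$combined_score, -1.33)
  expect_identical(res$sites$start, c(841L, 2399L))
  expect_equal(res$sites$score, c(-0.45, -0.88))
})

test_that("every simulated implant is recovered by the scanner", {
  cfg <- sim_config(n_utrs = 15L, utr_length_range = c(300L, 900L),
                    frac_target_utrs = 0.6, seed = 8)
  mirnas <- read_mirna_fasta(mirscreen_example("mirnas.fasta"))
  db <- simulate_utr_database(cfg, mirnas)
  res <- scan_utrs(db$utrs, mirnas)
  for (i in seq_len(nrow(db$truth))) {
    tr <- db$truth[i, ]
    hit <- res$sites[res$sites$gene == tr$gene &
                       res$sites$mirna == tr$mirna &
                       res$sites$start == tr$start, ]
    expect_identical(nrow(hit), 1L)
    expect_identical(hit$end, tr$end)
    expect_identical(hit$site_type, tr$site_type)
  }
  # and the scanner as a whole equals the oracle on these UTRs
  for (g in names(db$utrs)[1:5]) {
    for (m in names(mirnas)) {
      got <- res$sites[res$sites$gene == g & res$sites$mirna == m,
                       c("start", "end", "site_type")]
      rownames(got) <- NULL
      expect_identical(got, oracle_scan(db$utrs[[g]], mirnas[[m]]))
    }
  }
})

test_that("consensus votes count predictor-set membership", {
  lists <- read_gene_lists(file.path(
    mirscreen_example("predictors"),
    c("targetscan.txt", "miranda.txt", "pictar.txt", "pita.txt",
      "diana_microt.txt", "rna22.txt")))
  v <- consensus_votes(c("CFL2", "FSCN1", "PRKACB", "PRKACA", "NOPE"), lists)
  expect_identical(v$votes, c("6/6", "3/6", "6/6", "2/6", "0/6"))
  expect_error(consensus_votes("CFL2", setNames(lists, rep("x", 6))),
               "duplicate")
})
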