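#' Simulate a two-replicate SILAC screening experiment
#'
#' Generates peptide-level light/heavy area tables for two biological
#' replicates, together with the ground truth needed to score any downstream
#' analysis. Each protein is identified in a given replicate with
#' probability `detect_prob` (independent Bernoulli draws, the simplest
#' mechanism reproducing the partial proteome overlap of repeated
#' mass-spectrometry runs). Peptide intensities are drawn log-normally
#' around a per-protein base abundance; the peptide log2 light/heavy ratio
#' is the protein's true effect plus Gaussian noise of SD `noise_sd_log2`,
#' so the expected log2 ratio of every peptide equals the true effect.
#'
#' With the default `treated_channel = "heavy"`, a repressed protein
#' (negative true effect) has heavy/light < 1 and a negative estimated
#' log2 fold change downstream.
#'
#' @param config A [sim_config()] object.
#' @return A list with components:
#'   * `peptides`: data.frame with columns `protein_id`, `peptide_seq`,
#'     `replicate` (`"rep1"`/`"rep2"`), `light_area`, `heavy_area`;
#'   * `truth`: data.frame with columns `protein_id`, `true_log2fc`
#'     (exactly 0 for non-targets), `is_target`, `detected_rep1`,
#'     `detected_rep2`.
#' @examples
#' sim <- simulate_silac_experiment(sim_config(n_proteins_total = 50, seed = 1))
#' head(sim$peptides)
#' @export
simulate_silac_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_proteins_total
  protein_id <- sprintf("PROT%05d", seq_len(n))

  n_targets <- round(config$frac_true_targets * n)
  is_target <- rep(FALSE, n)
  if (n_targets > 0) is_target[sample.int(n, n_targets)] <- TRUE
  true_log2fc <- numeric(n)
  true_log2fc[is_target] <- runif(n_targets,
                                  config$effect_range_log2[1],
                                  config$effect_range_log2[2])

  base_abund <- rlnorm(n, meanlog = log(1e6), sdlog = 1)
  detected <- matrix(rbinom(2L * n, 1L, config$detect_prob) == 1L, ncol = 2)

  pep_tables <- lapply(1:2, function(r) {
    idx <- which(detected[, r])
    if (length(idx) == 0) {
      return(data.frame(protein_id = character(), peptide_seq = character(),
                        replicate = character(), light_area = numeric(),
                        heavy_area = numeric()))
    }
    k <- sample(seq(config$peptides_per_protein[1],
                    config$peptides_per_protein[2]),
                length(idx), replace = TRUE)
    rows_protein <- rep(idx, k)
    m <- length(rows_protein)
    # peptide-to-peptide ionization efficiency spread around protein abundance
    control_area <- base_abund[rows_protein] * rlnorm(m, 0, 0.5)
    eps <- if (config$noise_sd_log2 > 0) rnorm(m, 0, config$noise_sd_log2)
           else numeric(m)
    treated_area <- control_area * 2^(true_log2fc[rows_protein] + eps)
    if (config$treated_channel == "heavy") {
      light <- control_area; heavy <- treated_area
    } else {
      light <- treated_area; heavy <- control_area
    }
    data.frame(
      protein_id = protein_id[rows_protein],
      peptide_seq = random_peptides(m),
      replicate = paste0("rep", r),
      light_area = light,
      heavy_area = heavy,
      stringsAsFactors = FALSE
    )
  })

  list(
    peptides = do.call(rbind, pep_tables),
    truth = data.frame(
      protein_id = protein_id,
      true_log2fc = true_log2fc,
      is_target = is_target,
      detected_rep1 = detected[, 1],
      detected_rep2 = detected[, 2],
      stringsAsFactors = FALSE
    )
  )
}

# Tryptic-looking random peptide sequences (end in K/R), length 8-20.
random_peptides <- function(m) {
  if (m == 0) return(character())
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M",
          "N", "P", "Q", "S", "T", "V", "W", "Y")
  len <- sample(8:20, m, replace = TRUE)
  body <- vapply(len, function(l)
    paste(sample(aa, l - 1, replace = TRUE), collapse = ""), character(1))
  paste0(body, sample(c("K", "R"), m, replace = TRUE))
}

#' Simulate a 3'UTR database with implanted miRNA binding sites
#'
#' Synthesizes random 3'UTR sequences (DNA alphabet, uniform base
#' composition) and implants exact Watson-Crick seed-complementary sites
#' for the supplied miRNAs into a subset of them, recording every implant
#' in an interaction table and in the ground truth. Implanted sites are
#' written on the UTR sense strand; bases flanking an implant are forced to
#' not extend the match, so the implanted site class is recovered exactly
#' by the scanner. Site classes are sampled from 8mer, 7mer-m8 and 7mer-A1.
#'
#' @param config A [sim_config()] object (fields `n_utrs`,
#'   `utr_length_range`, `frac_target_utrs`, `sites_per_target_range`,
#'   `seed` are used; the seed is offset so UTR synthesis is independent of
#'   the peptide tables drawn from the same config).
#' @param mirnas Named character vector of mature miRNA sequences
#'   (RNA alphabet, 5'->3', length >= 8), or a `Biostrings::RNAStringSet`.
#' @return A list with components:
#'   * `utrs`: named character vector of UTR sequences (DNA);
#'   * `interactions`: data.frame `mirna`, `gene`, `start`, `end`,
#'     `site_type`, `score` (surrogate score of each implanted site);
#'   * `truth`: data.frame of implanted sites, identical coordinates.
#' @examples
#' cfg <- sim_config(n_utrs = 10, utr_length_range = c(200L, 400L), seed = 3)
#' db <- simulate_utr_database(cfg, c(`miR-x` = "UAACACUGUCUGGUAACGAUGU"))
#' db$interactions
#' @export
simulate_utr_database <- function(config, mirnas) {
  stopifnot(inherits(config, "sim_config"))
  mirnas <- as_mirna_set(mirnas)
  set.seed(config$seed + 104729L)  # offset: independent stream from peptides

  genes <- sprintf("GENE%04d", seq_len(config$n_utrs))
  len <- sample(seq(config$utr_length_range[1], config$utr_length_range[2]),
                config$n_utrs, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  utrs <- vapply(len, function(l)
    paste(sample(bases, l, replace = TRUE), collapse = ""), character(1))
  names(utrs) <- genes

  n_targets <- round(config$frac_target_utrs * config$n_utrs)
  target_idx <- if (n_targets > 0) sort(sample.int(config$n_utrs, n_targets))
                else integer()
  classes <- c("8mer", "7mer-m8", "7mer-A1")

  rows <- list()
  for (i in target_idx) {
    mir_i <- 1L + (i - 1L) %% length(mirnas)
    mir_seq <- mirnas[[mir_i]]
    n_sites <- sample(seq(config$sites_per_target_range[1],
                          config$sites_per_target_range[2]), 1)
    occupied <- integer()
    for (s in seq_len(n_sites)) {
      type <- sample(classes, 1)
      site <- seed_site_sequence(mir_seq, type)
      w <- nchar(site)
      if (len[i] < w + 2) {
        stop(sprintf("UTR %s (length %d) is shorter than site length %d",
                     genes[i], len[i], w), call. = FALSE)
      }
      # place away from UTR ends and previously implanted sites
      pos <- NA
      for (try in 1:50) {
        p <- sample(2:(len[i] - w), 1)
        if (!any(abs(p - occupied) < w + 2)) { pos <- p; break }
      }
      if (is.na(pos)) next
      occupied <- c(occupied, pos)
      utr <- utrs[[i]]
      substr(utr, pos, pos + w - 1) <- site
      # guard flanks so the class cannot be upgraded by chance
      m8c <- dna_complement(rna_to_dna(substr(mir_seq, 8, 8)))
      if (!type %in% c("8mer", "7mer-m8")) {
        if (substr(utr, pos - 1, pos - 1) == m8c)
          substr(utr, pos - 1, pos - 1) <- switch(m8c, A = "C", C = "A",
                                                  G = "T", T = "G")
      }
      if (!type %in% c("8mer", "7mer-A1")) {
        if (substr(utr, pos + w, pos + w) == "A")
          substr(utr, pos + w, pos + w) <- "C"
      }
      utrs[[i]] <- utr
      rows[[length(rows) + 1]] <- data.frame(
        mirna = names(mirnas)[mir_i], gene = genes[i],
        start = as.integer(pos), end = as.integer(pos + w - 1),
        site_type = type,
        stringsAsFactors = FALSE)
    }
  }
  interactions <- if (length(rows)) do.call(rbind, rows)
                  else data.frame(mirna = character(), gene = character(),
                                  start = integer(), end = integer(),
                                  site_type = character())
  interactions$score <- if (nrow(interactions))
    mapply(function(g, st, en, ty)
      score_site(ty, utrs[[g]], st, en), interactions$gene,
      interactions$start, interactions$end, interactions$site_type)
  else numeric()
  list(utrs = utrs, interactions = interactions, truth = interactions)
}

# The UTR sense-strand sequence (5'->3', DNA) matched by a site class.
# Layout 5'->3': [complement of m8][complement of m7..m2][A opposite m1].
seed_site_sequence <- function(mirna_seq, type) {
  s <- rna_to_dna(mirna_seq)
  core <- dna_revcomp(substr(s, 2, 7))      # complement of m2..m7, reversed
  m8c <- dna_complement(substr(s, 8, 8))
  switch(type,
         "6mer" = core,
         "7mer-A1" = paste0(core, "A"),
         "7mer-m8" = paste0(m8c, core),
         "8mer" = paste0(m8c, core, "A"),
         stop(sprintf("unknown site type '%s'", type), call. = FALSE))
}

as_mirna_set <- function(mirnas) {
  if (inherits(mirnas, "XStringSet")) {
    mirnas <- setNames(as.character(mirnas), names(mirnas))
  }
  if (!is.character(mirnas) || is.null(names(mirnas)) ||
      any(!nzchar(names(mirnas))))
    stop("'mirnas' must be a named character vector or named RNAStringSet",
         call. = FALSE)
  mirnas <- toupper(mirnas)
  bad <- grepl("[^ACGU]", mirnas)
  if (any(bad))
    stop(sprintf("miRNA '%s' contains non-RNA characters",
                 names(mirnas)[which(bad)[1]]), call. = FALSE)
  short <- nchar(mirnas) < 8
  if (any(short))
    stop(sprintf("miRNA '%s' is shorter than 8 nt",
                 names(mirnas)[which(short)[1]]), call. = FALSE)
  mirnas
}

rna_to_dna <- function(x) chartr("Uu", "Tt", x)

dna_complement <- function(x) chartr("ACGTN", "TGCAN", x)

dna_revcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(dna_complement(s), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}
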