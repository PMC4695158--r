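#' Simulation configuration for the synthetic SILAC / UTR generator
#'
#' Bundles and validates every tunable of the synthetic-data module. The
#' defaults emulate the proteome coverage of a two-replicate SILAC screen on
#' an Orbitrap-class instrument: with `n_proteins_total = 2350` expressed
#' proteins and a per-replicate identification probability of
#' `detect_prob = 0.86`, a simulated replicate identifies ~2,000 proteins
#' and ~1,730 are shared between two replicates. True targets are a small
#' minority (`frac_true_targets`) with log2 effects drawn uniformly from
#' `effect_range_log2`; the default interval \[-1.6, -0.4\] spans the effect
#' sizes typically confirmed for miRNA-repressed proteins.
#'
#' @param n_proteins_total Number of expressed proteins in the simulated
#'   proteome (>= 1).
#' @param detect_prob Probability that a given protein is identified in a
#'   given replicate; drives the partial replicate overlap that is intrinsic
#'   to shotgun proteomics.
#' @param frac_true_targets Fraction of proteins carrying a true repression
#'   effect.
#' @param effect_range_log2 Length-2 numeric, interval (min, max) of true
#'   log2 fold changes; the upper bound must be negative (repression).
#' @param peptides_per_protein Length-2 integer bounds (min, max) of the
#'   uniform number of quantified peptides per detected protein.
#' @param noise_sd_log2 Standard deviation of peptide-level measurement
#'   noise on the log2-ratio scale.
#' @param treated_channel Which SILAC channel carries the miRNA-treated
#'   cells, `"heavy"` (default) or `"light"`. With the default, repression
#'   gives heavy/light < 1.
#' @param seed Integer RNG seed; identical seeds give byte-identical output.
#' @param n_utrs Number of 3'UTR sequences to synthesize.
#' @param utr_length_range Length-2 integer bounds of UTR lengths (nt).
#' @param frac_target_utrs Fraction of UTRs that receive implanted sites.
#' @param sites_per_target_range Length-2 integer bounds of the number of
#'   sites implanted per target UTR.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_proteins_total = 100, seed = 7)
#' cfg$detect_prob
#' @export
sim_config <- function(n_proteins_total = 2350,
                       detect_prob = 0.86,
                       frac_true_targets = 0.01,
                       effect_range_log2 = c(-1.6, -0.4),
                       peptides_per_protein = c(3L, 12L),
                       noise_sd_log2 = 0.3,
                       treated_channel = c("heavy", "light"),
                       seed = 1L,
                       n_utrs = 60L,
                       utr_length_range = c(500L, 3000L),
                       frac_target_utrs = 0.5,
                       sites_per_target_range = c(1L, 3L)) {
  treated_channel <- match.arg(treated_channel)
  check_count <- function(x, name, min = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
        x != round(x))
      stop(sprintf("'%s' must be a single integer >= %d", name, min),
           call. = FALSE)
  }
  check_prob <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      stop(sprintf("'%s' must be a probability in [0, 1]", name),
           call. = FALSE)
  }
  check_bounds <- function(x, name) {
    if (!is.numeric(x) || length(x) != 2 || any(is.na(x)) || x[1] > x[2] ||
        any(x < 1) || any(x != round(x)))
      stop(sprintf("'%s' must be two increasing integers >= 1", name),
           call. = FALSE)
  }
  check_count(n_proteins_total, "n_proteins_total")
  check_prob(detect_prob, "detect_prob")
  check_prob(frac_true_targets, "frac_true_targets")
  check_prob(frac_target_utrs, "frac_target_utrs")
  if (!is.numeric(effect_range_log2) || length(effect_range_log2) != 2 ||
      any(is.na(effect_range_log2)) ||
      effect_range_log2[1] > effect_range_log2[2] ||
      effect_range_log2[2] >= 0)
    stop("'effect_range_log2' must be an increasing interval with upper bound < 0",
         call. = FALSE)
  check_bounds(peptides_per_protein, "peptides_per_protein")
  check_bounds(utr_length_range, "utr_length_range")
  check_bounds(sites_per_target_range, "sites_per_target_range")
  if (!is.numeric(noise_sd_log2) || length(noise_sd_log2) != 1 ||
      is.na(noise_sd_log2) || noise_sd_log2 < 0)
    stop("'noise_sd_log2' must be a single number >= 0", call. = FALSE)
  check_count(seed, "seed", min = 0)
  check_count(n_utrs, "n_utrs")
  structure(list(
    n_proteins_total = as.integer(n_proteins_total),
    detect_prob = detect_prob,
    frac_true_targets = frac_true_targets,
    effect_range_log2 = effect_range_log2,
    peptides_per_protein = as.integer(peptides_per_protein),
    noise_sd_log2 = noise_sd_log2,
    treated_channel = treated_channel,
    seed = as.integer(seed),
    n_utrs = as.integer(n_utrs),
    utr_length_range = as.integer(utr_length_range),
    frac_target_utrs = frac_target_utrs,
    sites_per_target_range = as.integer(sites_per_target_range)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("SILAC/UTR simulation configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
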