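# Dixon's Q critical values, two-tailed, alpha = 0.05, n = 3..30
# (standard published table for the r10 statistic).
.dixon_q05 <- c(
  0.970, 0.829, 0.710, 0.625, 0.568, 0.526, 0.493, 0.466, 0.444, 0.426,
  0.410, 0.396, 0.384, 0.374, 0.365, 0.356, 0.349, 0.342, 0.337, 0.331,
  0.326, 0.321, 0.317, 0.312, 0.308, 0.305, 0.301, 0.298)

# Per-peptide log2(treated/control) ratios for one protein in one replicate.
# Peptides with a zero area in either channel are excluded; the retained
# logical is returned as an attribute so callers can report exclusions.
peptide_log2_ratios <- function(light_area, heavy_area,
                                treated_channel = "heavy") {
  usable <- light_area > 0 & heavy_area > 0
  treated <- if (treated_channel == "heavy") heavy_area else light_area
  control <- if (treated_channel == "heavy") light_area else heavy_area
  r <- log2(treated[usable] / control[usable])
  attr(r, "n_excluded") <- sum(!usable)
  r
}

#' Aggregate peptide ratios into a protein log2 fold change (ASAPRatio-style)
#'
#' Averages per-peptide log2(treated/control) ratios for one protein in one
#' replicate, after a single outlier-rejection pass with Dixon's Q test
#' (alpha = 0.05, most extreme value only, applied for 3 <= n <= 30
#' peptides). Peptides with a zero area in either channel are excluded
#' before estimation. Weights are uniform: the peptide-level noise variance
#' is estimated from the within-protein scatter, which is common to all
#' peptides of the protein, so inverse-variance weighting reduces to the
#' arithmetic mean with standard error sd/sqrt(n).
#'
#' @param light_area,heavy_area Numeric vectors of per-peptide channel
#'   areas (same length, >= 0).
#' @param treated_channel `"heavy"` (default) or `"light"`: which channel
#'   carries the treated cells.
#' @return A list with `log2_fc`, `se_log2`, `n_peptides` (used after
#'   exclusion and outlier rejection), `n_excluded`, `n_rejected`.
#' @examples
#' aggregate_asap(c(100, 100, 100), c(50, 46, 56))
#' @export
aggregate_asap <- function(light_area, heavy_area,
                           treated_channel = c("heavy", "light")) {
  treated_channel <- match.arg(treated_channel)
  stopifnot(length(light_area) == length(heavy_area))
  r <- peptide_log2_ratios(light_area, heavy_area, treated_channel)
  n_excluded <- attr(r, "n_excluded")
  if (length(r) == 0)
    stop("no quantifiable peptides: every peptide has a zero area in one channel",
         call. = FALSE)
  n_rejected <- 0L
  n <- length(r)
  if (n >= 3 && n <= 30) {
    rs <- sort(r)
    rng <- rs[n] - rs[1]
    if (rng > 0) {
      q_low <- (rs[2] - rs[1]) / rng
      q_high <- (rs[n] - rs[n - 1]) / rng
      q_crit <- .dixon_q05[n - 2]
      # single pass, most extreme suspect only
      if (max(q_low, q_high) > q_crit) {
        drop_val <- if (q_high >= q_low) rs[n] else rs[1]
        r <- r[-which(r == drop_val)[1]]
        n_rejected <- 1L
      }
    }
  }
  n_used <- length(r)
  list(log2_fc = mean(r),
       se_log2 = if (n_used > 1) sd(r) / sqrt(n_used) else 0,
       n_peptides = n_used,
       n_excluded = n_excluded,
       n_rejected = n_rejected)
}

#' Aggregate peptide areas into a protein log2 fold change (XPRESS-style)
#'
#' The companion estimator: the ratio of summed treated areas to summed
#' control areas across all peptides of the protein, log2-transformed.
#' Agrees exactly with [aggregate_asap()] when all peptides share the same
#' ratio.
#'
#' @inheritParams aggregate_asap
#' @return A single log2 fold change.
#' @examples
#' aggregate_xpress(200, 100)  # log2(100/200) = -1
#' @export
aggregate_xpress <- function(light_area, heavy_area,
                             treated_channel = c("heavy", "light")) {
  treated_channel <- match.arg(treated_channel)
  stopifnot(length(light_area) == length(heavy_area))
  treated <- if (treated_channel == "heavy") heavy_area else light_area
  control <- if (treated_channel == "heavy") light_area else heavy_area
  if (sum(control) <= 0 || sum(treated) <= 0)
    stop("summed area is zero in one channel; ratio undefined", call. = FALSE)
  log2(sum(treated) / sum(control))
}

#' Significance of a protein ratio against the replicate's ratio population
#'
#' Two-sided tail probability of a protein's log2 fold change under a
#' normal model centered and scaled robustly on the whole replicate's
#' protein ratio population (center = median, spread = MAD with the usual
#' 1.4826 consistency factor). A protein sitting at the population median
#' gets p = 1; p decreases monotonically with distance from the median and
#' is symmetric around it. This is a declared stand-in for the published
#' ASAPRatio significance model, which fits the normalized ratio histogram.
#'
#' @param log2_fc Protein log2 fold change(s) to test (vectorized).
#' @param population Numeric vector of all protein log2 fold changes in the
#'   same replicate (length >= 20).
#' @param spread `"mad"` (default) or `"sd"`; `"sd"` is the fallback for
#'   degenerate populations whose MAD is zero.
#' @return p-value(s) in (0, 1].
#' @examples
#' pop <- rnorm(100)
#' ratio_significance(median(pop), pop)  # 1
#' @export
ratio_significance <- function(log2_fc, population, spread = c("mad", "sd")) {
  spread <- match.arg(spread)
  if (length(population) < 20)
    stop("population must contain at least 20 protein ratios", call. = FALSE)
  center <- median(population)
  s <- if (spread == "mad") mad(population) else sd(population)
  if (s == 0)
    stop(paste0("degenerate ratio population (spread = 0); ",
                "re-run with spread = \"sd\" or inspect the input"),
         call. = FALSE)
  p <- 2 * pnorm(-abs(log2_fc - center) / s)
  pmax(pmin(p, 1), .Machine$double.xmin)
}

#' Cross-algorithm concordance rule for a protein ratio
#'
#' A protein ratio is accepted when the two quantification algorithms
#' diverge less than twofold on the linear scale, or when both report an
#' extreme ratio in the same direction (both > 3.0 or both < 0.33).
#'
#' @param ratio1,ratio2 Linear-scale fold changes (> 0) from the two
#'   algorithms (vectorized).
#' @return Logical vector.
#' @examples
#' concordance_filter(1.5, 2.0)   # TRUE  (divergence 1.33)
#' concordance_filter(4.0, 1.2)   # FALSE (divergence 3.33)
#' concordance_filter(5.0, 3.5)   # TRUE  (both > 3.0)
#' @export
concordance_filter <- function(ratio1, ratio2) {
  if (any(ratio1 <= 0) || any(ratio2 <= 0))
    stop("linear fold changes must be > 0", call. = FALSE)
  divergence <- pmax(ratio1, ratio2) / pmin(ratio1, ratio2)
  divergence < 2.0 | (ratio1 > 3.0 & ratio2 > 3.0) |
    (ratio1 < 0.33 & ratio2 < 0.33)
}

#' Quantify all proteins of one replicate from a peptide table
#'
#' Runs [aggregate_asap()] and [aggregate_xpress()] per protein, computes
#' the replicate-wide ratio significance of each protein with
#' [ratio_significance()] (each replicate forms its own population, since
#' replicates are measured in distinct runs), and applies the
#' [concordance_filter()] to the two estimates.
#'
#' @param peptides Data.frame with columns `protein_id`, `light_area`,
#'   `heavy_area` (a `replicate` column, if present, must hold a single
#'   value).
#' @param treated_channel `"heavy"` (default) or `"light"`.
#' @return Data.frame with one row per protein: `protein_id`, `replicate`,
#'   `log2_fc`, `se_log2`, `n_peptides`, `p_value`, `xpress_log2_fc`,
#'   `concordant`.
#' @export
quantify_replicate <- function(peptides,
                               treated_channel = c("heavy", "light")) {
  treated_channel <- match.arg(treated_channel)
  required <- c("protein_id", "light_area", "heavy_area")
  missing_cols <- setdiff(required, names(peptides))
  if (length(missing_cols))
    stop(sprintf("peptide table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  replicate <- if ("replicate" %in% names(peptides)) {
    u <- unique(peptides$replicate)
    if (length(u) > 1)
      stop("quantify_replicate() expects a single replicate; split first",
           call. = FALSE)
    u
  } else NA_character_
  split_idx <- split(seq_len(nrow(peptides)), peptides$protein_id)
  rows <- lapply(names(split_idx), function(pid) {
    i <- split_idx[[pid]]
    a <- aggregate_asap(peptides$light_area[i], peptides$heavy_area[i],
                        treated_channel)
    x <- aggregate_xpress(peptides$light_area[i], peptides$heavy_area[i],
                          treated_channel)
    data.frame(protein_id = pid, replicate = replicate,
               log2_fc = a$log2_fc, se_log2 = a$se_log2,
               n_peptides = a$n_peptides, xpress_log2_fc = x,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_value <- ratio_significance(out$log2_fc, out$log2_fc)
  out$concordant <- concordance_filter(2^out$log2_fc, 2^out$xpress_log2_fc)
  out[c("protein_id", "replicate", "log2_fc", "se_log2", "n_peptides",
        "p_value", "xpress_log2_fc", "concordant")]
}
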