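#' Combine two replicate p-values into a merged p-value
#'
#' Fisher's method for two independent p-values: the statistic
#' `x = -2 (ln p1 + ln p2)` follows a chi-square distribution with 4
#' degrees of freedom under the null, whose survival function has the
#' closed form `exp(-x/2) * (1 + x/2)`. Stouffer's Z-based combination is
#' available as an alternative.
#'
#' @param p1,p2 p-values in (0, 1] (vectorized).
#' @param method `"fisher"` (default) or `"stouffer"`.
#' @return Combined p-value(s) in (0, 1].
#' @examples
#' combine_pvalues(0.05, 0.05)  # ~0.0175
#' combine_pvalues(1, 1)        # 1
#' @export
combine_pvalues <- function(p1, p2, method = c("fisher", "stouffer")) {
  method <- match.arg(method)
  if (any(p1 <= 0 | p1 > 1) || any(p2 <= 0 | p2 > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  if (method == "fisher") {
    x <- -2 * (log(p1) + log(p2))
    p <- exp(-x / 2) * (1 + x / 2)
  } else {
    z <- (stats::qnorm(p1, lower.tail = FALSE) +
            stats::qnorm(p2, lower.tail = FALSE)) / sqrt(2)
    p <- stats::pnorm(z, lower.tail = FALSE)
  }
  pmax(pmin(p, 1), .Machine$double.xmin)
}

#' Apply the candidate filter cascade to merged replicate records
#'
#' A protein passes the screen when (i) the merged p-value is below
#' `p_threshold` (strictly), (ii) its abundance decreases by more than
#' `decrease_threshold` in *both* replicates — i.e. the linear fold change
#' is strictly below `1 - decrease_threshold` (log2 fold change below
#' log2(0.75) for the default 25%), and (iii) both replicate fold changes
#' are negative. Criterion (iii) is implied by (ii) for any positive
#' decrease threshold but is reported as its own flag.
#'
#' @param candidates Data.frame with columns `log2_fc_rep1`, `log2_fc_rep2`
#'   and `combined_p` (rows with `NA` fold changes are marked ineligible).
#' @param p_threshold Merged p-value cutoff (default 0.1, strict).
#' @param decrease_threshold Minimum fractional decrease required in both
#'   replicates (default 0.25, strict).
#' @return The input with added logical columns `pass_p`, `pass_decrease`,
#'   `pass_direction`, `eligible` and `verdict`
#'   (= `pass_p & pass_decrease & pass_direction`).
#' @examples
#' candidate_filter(data.frame(log2_fc_rep1 = -1.06, log2_fc_rep2 = -0.96,
#'                             combined_p = 4.57e-4))$verdict
#' @export
candidate_filter <- function(candidates, p_threshold = 0.1,
                             decrease_threshold = 0.25) {
  stopifnot(is.data.frame(candidates))
  required <- c("log2_fc_rep1", "log2_fc_rep2", "combined_p")
  missing_cols <- setdiff(required, names(candidates))
  if (length(missing_cols))
    stop(sprintf("candidate table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (p_threshold <= 0 || p_threshold >= 1)
    stop("'p_threshold' must lie in (0, 1)", call. = FALSE)
  if (decrease_threshold <= 0 || decrease_threshold >= 1)
    stop("'decrease_threshold' must lie in (0, 1)", call. = FALSE)
  fc_cut <- log2(1 - decrease_threshold)
  eligible <- !is.na(candidates$log2_fc_rep1) &
    !is.na(candidates$log2_fc_rep2) & !is.na(candidates$combined_p)
  candidates$eligible <- eligible
  candidates$pass_p <- eligible & candidates$combined_p < p_threshold
  candidates$pass_decrease <- eligible &
    candidates$log2_fc_rep1 < fc_cut & candidates$log2_fc_rep2 < fc_cut
  candidates$pass_direction <- eligible &
    candidates$log2_fc_rep1 < 0 & candidates$log2_fc_rep2 < 0
  candidates$verdict <- candidates$pass_p & candidates$pass_decrease &
    candidates$pass_direction
  candidates
}

#' Merge two replicate quantifications and screen for target candidates
#'
#' Intersects the proteins of two per-replicate quantification tables
#' (proteins seen in only one replicate are ineligible for screening),
#' keeps proteins whose ratios pass the cross-algorithm concordance rule in
#' both replicates, merges the per-replicate significances with
#' [combine_pvalues()], and applies [candidate_filter()]. Candidates are
#' returned sorted by merged p-value.
#'
#' @param ratios_rep1,ratios_rep2 Data.frames as produced by
#'   [quantify_replicate()] (columns `protein_id`, `log2_fc`, `p_value`;
#'   optional `concordant`).
#' @inheritParams candidate_filter
#' @param p_method Passed to [combine_pvalues()].
#' @return A list with:
#'   * `candidates`: one row per shared concordant protein, columns
#'     `protein_id`, `log2_fc_rep1`, `log2_fc_rep2`, `p_rep1`, `p_rep2`,
#'     `combined_p` and the filter flags, sorted by `combined_p`;
#'   * `summary`: list with counts `n_rep1`, `n_rep2`, `n_shared`,
#'     `n_concordant`, `n_pass`.
#' @export
screen_candidates <- function(ratios_rep1, ratios_rep2, p_threshold = 0.1,
                              decrease_threshold = 0.25,
                              p_method = c("fisher", "stouffer")) {
  p_method <- match.arg(p_method)
  for (tab in list(ratios_rep1, ratios_rep2)) {
    missing_cols <- setdiff(c("protein_id", "log2_fc", "p_value"), names(tab))
    if (length(missing_cols))
      stop(sprintf("ratio table lacks column(s): %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  shared <- intersect(ratios_rep1$protein_id, ratios_rep2$protein_id)
  if (length(shared) == 0)
    warning("no proteins shared between replicates; empty candidate list")
  r1 <- ratios_rep1[match(shared, ratios_rep1$protein_id), ]
  r2 <- ratios_rep2[match(shared, ratios_rep2$protein_id), ]
  conc <- rep(TRUE, length(shared))
  if ("concordant" %in% names(ratios_rep1)) conc <- conc & r1$concordant
  if ("concordant" %in% names(ratios_rep2)) conc <- conc & r2$concordant
  cand <- data.frame(
    protein_id = shared[conc],
    log2_fc_rep1 = r1$log2_fc[conc],
    log2_fc_rep2 = r2$log2_fc[conc],
    p_rep1 = r1$p_value[conc],
    p_rep2 = r2$p_value[conc],
    stringsAsFactors = FALSE
  )
  cand$combined_p <- if (nrow(cand))
    combine_pvalues(cand$p_rep1, cand$p_rep2, p_method) else numeric()
  cand <- candidate_filter(cand, p_threshold, decrease_threshold)
  cand <- cand[order(cand$combined_p), ]
  rownames(cand) <- NULL
  list(
    candidates = cand,
    summary = list(
      n_rep1 = nrow(ratios_rep1),
      n_rep2 = nrow(ratios_rep2),
      n_shared = length(shared),
      n_concordant = sum(conc),
      n_pass = sum(cand$verdict)
    )
  )
}
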