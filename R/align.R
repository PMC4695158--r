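#' Substitution matrix for nucleotide alignment
#'
#' A simple full-DNA scoring scheme (default match +5, mismatch -4, any
#' comparison involving `N` scoring -2), the conventional parameterization
#' for global nucleotide alignment.
#'
#' @param match,mismatch,n_score Scores for identical bases, different
#'   bases, and pairs involving `N`.
#' @return A numeric matrix with dimnames over `A`, `C`, `G`, `T`, `N`.
#' @export
dna_substitution_matrix <- function(match = 5, mismatch = -4, n_score = -2) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m) <- match
  m["N", ] <- n_score
  m[, "N"] <- n_score
  m
}

protein_substitution_matrix <- function() {
  # BLOSUM62 as distributed with Biostrings (identical to EBLOSUM62)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Global pairwise alignment with affine gaps (Needle-style)
#'
#' Optimal Needleman-Wunsch/Gotoh global alignment under BLOSUM62
#' (protein) or a +5/-4 full-DNA matrix (dna), with affine gap penalties
#' (default gap open 10.0, gap extend 0.5, a gap of length L costing
#' `open + ext*(L-1)`) and unpenalized end gaps — the defaults of the
#' EMBOSS Needle tool. Identity and similarity are computed over the full
#' alignment length including gap columns; "similar" counts residue pairs
#' with a positive substitution score (identities included), the EMBOSS
#' convention.
#'
#' @param a,b Sequences (single non-empty strings).
#' @param alphabet `"protein"` or `"dna"`.
#' @param gap_open,gap_extend Affine gap penalties (positive numbers).
#' @param end_gaps_free If `TRUE` (default), end gaps are not penalized.
#' @param substitution_matrix Optional square numeric matrix with residue
#'   dimnames, overriding the alphabet default.
#' @return An object of class `alignment_result`: list with `aligned_a`,
#'   `aligned_b` (gapped strings of equal length), `score`,
#'   `alignment_length`, `n_identical`, `n_similar`, `n_gaps`, `identity`,
#'   `similarity`.
#' @examples
#' al <- global_align("HEAGAWGHEE", "PAWHEAE")
#' al$identity
#' @export
global_align <- function(a, b, alphabet = c("protein", "dna"),
                         gap_open = 10, gap_extend = 0.5,
                         end_gaps_free = TRUE,
                         substitution_matrix = NULL) {
  alphabet <- match.arg(alphabet)
  if (!is.character(a) || length(a) != 1 || !nzchar(a) ||
      !is.character(b) || length(b) != 1 || !nzchar(b))
    stop("'a' and 'b' must be single non-empty strings", call. = FALSE)
  a <- toupper(a); b <- toupper(b)
  sub <- if (!is.null(substitution_matrix)) substitution_matrix
         else if (alphabet == "protein") protein_substitution_matrix()
         else dna_substitution_matrix()
  if (is.null(rownames(sub)) || !identical(rownames(sub), colnames(sub)))
    stop("substitution matrix must have identical row/column names",
         call. = FALSE)
  res <- .gotoh_align(a, b, sub, rownames(sub), gap_open, gap_extend,
                      end_gaps_free)
  annotate_alignment(res$aligned_a, res$aligned_b, res$score, sub)
}

annotate_alignment <- function(aligned_a, aligned_b, score, sub) {
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  len <- length(ca)
  is_gap <- ca == "-" | cb == "-"
  ident <- !is_gap & ca == cb
  simil <- !is_gap
  if (any(simil)) {
    simil[simil] <- sub[cbind(ca[!is_gap], cb[!is_gap])] > 0
  }
  structure(list(
    aligned_a = aligned_a, aligned_b = aligned_b, score = score,
    alignment_length = len,
    n_identical = sum(ident), n_similar = sum(simil),
    n_gaps = sum(ca == "-") + sum(cb == "-"),
    identity = sum(ident) / len,
    similarity = sum(simil) / len
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, width = 60, ...) {
  cat(sprintf("Global alignment: length %d, score %.1f\n",
              x$alignment_length, x$score))
  cat(sprintf("Identity:   %d/%d (%.1f%%)\n", x$n_identical,
              x$alignment_length, 100 * x$identity))
  cat(sprintf("Similarity: %d/%d (%.1f%%)\n", x$n_similar,
              x$alignment_length, 100 * x$similarity))
  cat(sprintf("Gaps:       %d\n", x$n_gaps))
  for (off in seq(1, x$alignment_length, by = width)) {
    to <- min(off + width - 1, x$alignment_length)
    cat(substr(x$aligned_a, off, to), "\n")
    cat(substr(x$aligned_b, off, to), "\n\n")
  }
  invisible(x)
}

#' Isoform divergence report
#'
#' For each named group of protein isoforms (reference listed first),
#' aligns every member globally against the group reference and reports
#' identity and similarity, optionally annotated with each member's 3'UTR
#' length. Near-identical protein isoforms with divergent 3'UTRs are
#' exactly the configuration in which isoform-specific miRNA regulation
#' arises.
#'
#' @param groups Named list; each element a named character vector of
#'   protein sequences whose first entry is the group reference.
#' @param utrs Optional named character vector of 3'UTR sequences (DNA),
#'   names matching member names; used to report UTR lengths.
#' @param digits Rounding (half-up) applied to the reported fractions;
#'   default 2. Full precision is available via [global_align()].
#' @return Data.frame `group`, `member`, `identity`, `similarity`,
#'   `utr_length` (NA where no UTR is supplied). Reference members report
#'   1.00/1.00 by convention.
#' @export
divergence_report <- function(groups, utrs = NULL, digits = 2) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  round_half_up <- function(x, d) floor(x * 10^d + 0.5) / 10^d
  rows <- list()
  for (gname in names(groups)) {
    members <- groups[[gname]]
    if (is.null(names(members)) || any(!nzchar(names(members))))
      stop(sprintf("members of group '%s' must be named", gname),
           call. = FALSE)
    ref <- members[[1]]
    for (i in seq_along(members)) {
      if (i == 1) {
        ident <- 1; simil <- 1
      } else {
        al <- global_align(ref, members[[i]], alphabet = "protein")
        ident <- al$identity; simil <- al$similarity
      }
      mname <- names(members)[i]
      rows[[length(rows) + 1]] <- data.frame(
        group = gname, member = mname,
        identity = round_half_up(ident, digits),
        similarity = round_half_up(simil, digits),
        utr_length = if (!is.null(utrs) && mname %in% names(utrs))
          nchar(utrs[[mname]]) else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
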