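.site_classes <- c("8mer", "7mer-m8", "7mer-A1", "6mer")  # strongest first

validate_utr <- function(utr, gene = "UTR") {
  if (!is.character(utr) || length(utr) != 1)
    stop("'utr' must be a single character string", call. = FALSE)
  utr <- toupper(utr)
  bad <- regexpr("[^ACGTN]", utr)
  if (bad > 0)
    stop(sprintf("%s contains invalid character '%s' at position %d",
                 gene, substr(utr, bad, bad), bad), call. = FALSE)
  utr
}

#' Find miRNA seed-complementary sites in a 3'UTR
#'
#' Scans the UTR sense strand (5'->3', DNA alphabet) for Watson-Crick
#' matches to the miRNA seed (positions 2-7 of the mature sequence, read
#' from its 5' end) and classifies each match into the canonical site
#' hierarchy: a 6mer core extends to 7mer-m8 when the UTR also pairs with
#' miRNA position 8, to 7mer-A1 when an adenine faces miRNA position 1,
#' and to 8mer when both hold. Coordinates are 1-based, inclusive, and span
#' the full matched region, so the site length is 6, 7 or 8 nt depending on
#' class. Overlapping matches of the same miRNA are merged and reported
#' once at the highest class. `N` never matches. Only the sense strand is
#' scanned: miRNA targeting acts on the single-stranded mRNA.
#'
#' @param utr UTR sequence (single string, alphabet ACGTN; lowercase
#'   accepted).
#' @param mirna Mature miRNA sequence (RNA alphabet, 5'->3', length >= 8).
#' @param allow_wobble If `TRUE`, G:U wobble pairs count as seed pairing
#'   (miRNA G may face UTR T, miRNA U may face UTR G). Default `FALSE`:
#'   strictly Watson-Crick, the canonical seed definition.
#' @return Data.frame with columns `start`, `end`, `site_type` (one of
#'   `"8mer"`, `"7mer-m8"`, `"7mer-A1"`, `"6mer"`), ordered by `start`;
#'   zero rows when nothing matches.
#' @examples
#' mir <- "UAAUACUGCC"           # seed (2-7): AAUACU
#' utr <- paste0(strrep("C", 20), "CAGTATTA", strrep("C", 20))
#' find_seed_sites(utr, mir)     # one 8mer at 21
#' @export
find_seed_sites <- function(utr, mirna, allow_wobble = FALSE) {
  utr <- validate_utr(utr)
  mirna <- as_mirna_set(setNames(mirna, "query"))[[1]]
  empty <- data.frame(start = integer(), end = integer(),
                      site_type = character(), stringsAsFactors = FALSE)
  L <- nchar(utr)
  if (L < 6) return(empty)
  uc <- strsplit(utr, "")[[1]]

  # allowed UTR base(s) opposite each miRNA seed base
  allowed <- function(mb) {
    wc <- switch(mb, A = "T", C = "G", G = "C", U = "A")
    if (allow_wobble && mb == "G") c(wc, "T")
    else if (allow_wobble && mb == "U") c(wc, "G")
    else wc
  }
  mseed <- strsplit(mirna, "")[[1]]
  # site core layout 5'->3' on the UTR: opposite m7, m6, ..., m2
  core_allowed <- lapply(mseed[7:2], allowed)
  m8_allowed <- allowed(mseed[8])

  ok <- rep(TRUE, L - 5)
  for (j in 1:6) {
    ok <- ok & uc[j:(L - 6 + j)] %in% core_allowed[[j]]
  }
  starts <- which(ok)
  if (length(starts) == 0) return(empty)

  has_m8 <- starts > 1 & uc[pmax(starts - 1, 1)] %in% m8_allowed
  has_a1 <- (starts + 6) <= L & uc[pmin(starts + 6, L)] == "A"
  site_type <- ifelse(has_m8 & has_a1, "8mer",
               ifelse(has_m8, "7mer-m8",
               ifelse(has_a1, "7mer-A1", "6mer")))
  site_start <- ifelse(has_m8, starts - 1L, starts)
  site_end <- ifelse(has_a1, starts + 6L, starts + 5L)
  sites <- data.frame(start = as.integer(site_start),
                      end = as.integer(site_end),
                      site_type = site_type, stringsAsFactors = FALSE)

  # merge overlapping sites: keep the highest class, then leftmost
  rank <- match(sites$site_type, .site_classes)
  sites <- sites[order(rank, sites$start), ]
  keep <- logical(nrow(sites))
  occ_start <- integer(); occ_end <- integer()
  for (i in seq_len(nrow(sites))) {
    if (!any(sites$start[i] <= occ_end & sites$end[i] >= occ_start)) {
      keep[i] <- TRUE
      occ_start <- c(occ_start, sites$start[i])
      occ_end <- c(occ_end, sites$end[i])
    }
  }
  sites <- sites[keep, ]
  sites <- sites[order(sites$start), ]
  rownames(sites) <- NULL
  sites
}

#' Surrogate score for a miRNA binding site
#'
#' A deterministic stand-in for regression-based site scores (more negative
#' = stronger predicted repression): a base weight by site class
#' (8mer < 7mer-m8 < 7mer-A1 < 6mer, all <= 0) scaled by the AU content of
#' the flanking UTR context (AU-rich flanks improve site accessibility).
#' When scores from an external prediction table are available, attach them
#' verbatim with [load_site_scores()] / [scan_utrs()] instead.
#'
#' @param site_type One of `"8mer"`, `"7mer-m8"`, `"7mer-A1"`, `"6mer"`.
#' @param utr UTR sequence containing the site.
#' @param start,end 1-based inclusive site coordinates.
#' @param flank Number of flanking nucleotides per side used for the AU
#'   adjustment (default 30).
#' @return A single score <= 0.
#' @export
score_site <- function(site_type, utr, start, end, flank = 30) {
  base <- c("8mer" = -0.35, "7mer-m8" = -0.20, "7mer-A1" = -0.12,
            "6mer" = -0.03)
  if (!site_type %in% names(base))
    stop(sprintf("unknown site type '%s'", site_type), call. = FALSE)
  utr <- validate_utr(utr)
  L <- nchar(utr)
  if (start < 1 || end > L || start >= end)
    stop("site coordinates fall outside the UTR", call. = FALSE)
  ctx <- paste0(substr(utr, max(1, start - flank), start - 1),
                substr(utr, end + 1, min(L, end + flank)))
  au <- if (nchar(ctx) == 0) 0.5 else {
    cc <- strsplit(ctx, "")[[1]]
    mean(cc %in% c("A", "T"))
  }
  unname(base[site_type] * (0.5 + au))
}

#' Combined per-UTR score of a site list
#'
#' The arithmetic sum of the site scores of one miRNA on one UTR; 0 when no
#' site was found. Additive and invariant to site order.
#'
#' @param sites Data.frame with a `score` column (possibly zero rows), or a
#'   numeric vector of site scores.
#' @return A single number.
#' @examples
#' combined_utr_score(c(-0.45, -0.88))  # -1.33
#' @export
combined_utr_score <- function(sites) {
  scores <- if (is.data.frame(sites)) sites$score else sites
  if (is.null(scores) || length(scores) == 0) return(0)
  sum(scores)
}

#' Load an external site-score table
#'
#' Reads a TSV of externally predicted sites (columns `gene`, `mirna`,
#' `start`, `end`, `score`); scores are attached verbatim downstream,
#' bypassing the surrogate scorer.
#'
#' @param path Path to the TSV (single header line).
#' @return Data.frame with the five columns above.
#' @export
load_site_scores <- function(path) {
  tab <- read_tsv_checked(path, c("gene", "mirna", "start", "end", "score"))
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tab$score <- as.numeric(tab$score)
  tab
}

#' Scan a UTR set against a miRNA set
#'
#' Runs [find_seed_sites()] for every (UTR, miRNA) pair and scores sites
#' with [score_site()], or — for pairs present in an external score table —
#' takes the table's sites and scores verbatim.
#'
#' @param utrs Named character vector of UTR sequences (DNA), e.g. from
#'   [read_utr_fasta()].
#' @param mirnas Named character vector of mature miRNA sequences (RNA).
#' @param score_table Optional data.frame from [load_site_scores()].
#' @param allow_wobble Passed to [find_seed_sites()].
#' @return A list with:
#'   * `predictions`: data.frame `gene`, `mirna`, `n_sites`,
#'     `combined_score`;
#'   * `sites`: data.frame `gene`, `mirna`, `start`, `end`, `site_type`,
#'     `score` (one row per site).
#' @export
scan_utrs <- function(utrs, mirnas, score_table = NULL,
                      allow_wobble = FALSE) {
  if (is.null(names(utrs)) || any(!nzchar(names(utrs))))
    stop("'utrs' must be named by gene", call. = FALSE)
  mirnas <- as_mirna_set(mirnas)
  site_rows <- list()
  pred_rows <- list()
  for (g in names(utrs)) {
    for (m in names(mirnas)) {
      ext <- if (!is.null(score_table))
        score_table[score_table$gene == g & score_table$mirna == m, ,
                    drop = FALSE]
      else NULL
      if (!is.null(ext) && nrow(ext) > 0) {
        sites <- data.frame(gene = g, mirna = m, start = ext$start,
                            end = ext$end, site_type = NA_character_,
                            score = ext$score, stringsAsFactors = FALSE)
      } else {
        found <- find_seed_sites(utrs[[g]], mirnas[[m]], allow_wobble)
        sites <- if (nrow(found) == 0) NULL else
          data.frame(gene = g, mirna = m, start = found$start,
                     end = found$end, site_type = found$site_type,
                     score = vapply(seq_len(nrow(found)), function(i)
                       score_site(found$site_type[i], utrs[[g]],
                                  found$start[i], found$end[i]),
                       numeric(1)),
                     stringsAsFactors = FALSE)
      }
      if (!is.null(sites)) site_rows[[length(site_rows) + 1]] <- sites
      pred_rows[[length(pred_rows) + 1]] <- data.frame(
        gene = g, mirna = m,
        n_sites = if (is.null(sites)) 0L else nrow(sites),
        combined_score = if (is.null(sites)) 0 else
          combined_utr_score(sites),
        stringsAsFactors = FALSE)
    }
  }
  list(
    predictions = do.call(rbind, pred_rows),
    sites = if (length(site_rows)) do.call(rbind, site_rows) else
      data.frame(gene = character(), mirna = character(), start = integer(),
                 end = integer(), site_type = character(), score = numeric())
  )
}

#' Consensus votes across predictor gene lists
#'
#' Counts, for each queried gene, how many of `k` named predictor gene
#' sets contain it, mirroring the "n/k algorithms predict this target"
#' consensus used to triage candidates.
#'
#' @param genes Character vector of gene identifiers.
#' @param predictor_lists Named list of character vectors (one per
#'   prediction algorithm); names must be unique.
#' @return Data.frame `gene`, `votes_n`, `votes_k`, `votes` (e.g. `"3/6"`).
#' @examples
#' consensus_votes("CFL2", list(a = "CFL2", b = c("CFL2", "X"), c = "Y"))
#' @export
consensus_votes <- function(genes, predictor_lists) {
  if (!is.list(predictor_lists) || length(predictor_lists) < 1)
    stop("'predictor_lists' must be a non-empty named list", call. = FALSE)
  nms <- names(predictor_lists)
  if (is.null(nms) || any(!nzchar(nms)))
    stop("every predictor list must be named", call. = FALSE)
  if (anyDuplicated(nms))
    stop(sprintf("duplicate predictor name(s): %s",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")),
         call. = FALSE)
  k <- length(predictor_lists)
  n <- vapply(genes, function(g)
    sum(vapply(predictor_lists, function(set) g %in% set, logical(1))),
    integer(1))
  data.frame(gene = genes, votes_n = unname(n), votes_k = k,
             votes = sprintf("%d/%d", n, k), stringsAsFactors = FALSE)
}
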