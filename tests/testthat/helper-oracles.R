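# Independent oracles used by the property tests. These deliberately do not
# share code with the package implementation.

# Brute-force seed-site scanner: enumerate every UTR position, test seed
# complementarity character by character, classify, then resolve overlaps
# (highest class wins, then leftmost).
oracle_scan <- function(utr, mirna, allow_wobble = FALSE) {
  utr <- toupper(utr)
  mirna <- toupper(mirna)
  pairs_ok <- function(mb, ub) {
    wc <- c(A = "T", C = "G", G = "C", U = "A")[[mb]]
    if (ub == wc) return(TRUE)
    if (allow_wobble && mb == "G" && ub == "T") return(TRUE)
    if (allow_wobble && mb == "U" && ub == "G") return(TRUE)
    FALSE
  }
  u <- strsplit(utr, "")[[1]]
  m <- strsplit(mirna, "")[[1]]
  L <- length(u)
  hits <- list()
  for (s in seq_len(max(L - 5, 0))) {
    # core: u[s + k] pairs miRNA position 7 - k, k = 0..5
    core <- all(vapply(0:5, function(k) pairs_ok(m[7 - k], u[s + k]),
                       logical(1)))
    if (!core) next
    m8 <- s > 1 && pairs_ok(m[8], u[s - 1])
    a1 <- s + 6 <= L && u[s + 6] == "A"
    type <- if (m8 && a1) "8mer" else if (m8) "7mer-m8" else
      if (a1) "7mer-A1" else "6mer"
    hits[[length(hits) + 1]] <- data.frame(
      start = if (m8) s - 1L else s,
      end = if (a1) s + 6L else s + 5L,
      site_type = type, stringsAsFactors = FALSE)
  }
  if (length(hits) == 0)
    return(data.frame(start = integer(), end = integer(),
                      site_type = character(), stringsAsFactors = FALSE))
  h <- do.call(rbind, hits)
  rank <- match(h$site_type, c("8mer", "7mer-m8", "7mer-A1", "6mer"))
  h <- h[order(rank, h$start), ]
  kept <- h[0, ]
  for (i in seq_len(nrow(h))) {
    overlaps <- nrow(kept) > 0 &&
      any(h$start[i] <= kept$end & h$end[i] >= kept$start)
    if (!overlaps) kept <- rbind(kept, h[i, ])
  }
  kept <- kept[order(kept$start), ]
  rownames(kept) <- NULL
  kept
}

# Independent Gotoh score (no traceback): three-state affine DP, gap of
# length L costs open + ext * (L - 1), optionally free end gaps.
oracle_gotoh_score <- function(a, b, sub, open, ext, free_ends = TRUE) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -Inf
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- if (free_ends) 0 else -open - ext * (i - 2)
  for (j in 2:(m + 1)) Y[1, j] <- if (free_ends) 0 else -open - ext * (j - 2)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- sub[av[i - 1], bv[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open, Y[i - 1, j] - open,
                     X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open, X[i, j - 1] - open,
                     Y[i, j - 1] - ext)
    }
  }
  if (free_ends) {
    max(vapply(1:(n + 1), function(i) max(M[i, m + 1], X[i, m + 1],
                                          Y[i, m + 1]), numeric(1)),
        vapply(1:(m + 1), function(j) max(M[n + 1, j], X[n + 1, j],
                                          Y[n + 1, j]), numeric(1)))
  } else {
    max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  }
}

# Recompute an alignment score from emitted gapped strings under the same
# gap model (used to check the implementation's traceback consistency).
rescore_alignment <- function(aligned_a, aligned_b, sub, open, ext,
                              free_ends = TRUE) {
  ca <- strsplit(aligned_a, "")[[1]]; cb <- strsplit(aligned_b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  both <- which(ca != "-" & cb != "-")
  win <- if (free_ends && length(both)) range(both) else c(1, length(ca))
  if (free_ends && length(both) == 0) return(0)
  score <- 0
  in_gap_a <- FALSE; in_gap_b <- FALSE
  for (k in win[1]:win[2]) {
    if (ca[k] == "-") {
      score <- score - if (in_gap_a) ext else open
      in_gap_a <- TRUE; in_gap_b <- FALSE
    } else if (cb[k] == "-") {
      score <- score - if (in_gap_b) ext else open
      in_gap_b <- TRUE; in_gap_a <- FALSE
    } else {
      score <- score + sub[ca[k], cb[k]]
      in_gap_a <- FALSE; in_gap_b <- FALSE
    }
  }
  score
}

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

random_rna <- function(n = 22) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Brute-force cluster intersection: scan all miRNAs, keep those covering
# every queried gene.
oracle_cluster <- function(genes, table) {
  mirs <- unique(table$mirna)
  sort(mirs[vapply(mirs, function(m) {
    covered <- unique(table$gene[table$mirna == m])
    all(genes %in% covered)
  }, logical(1))])
}
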