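#' Aggregate an interaction table to unique (miRNA, gene) pairs
#'
#' Drops exact duplicate rows, then sums per-site scores into one combined
#' score per (miRNA, gene) pair, yielding the set-semantics table the
#' cluster operations work on.
#'
#' @param table Data.frame with columns `mirna`, `gene` and optionally
#'   `score` (per-site or per-pair; missing scores are treated as 0).
#' @return Data.frame `mirna`, `gene`, `score` with unique pairs.
#' @export
aggregate_interactions <- function(table) {
  missing_cols <- setdiff(c("mirna", "gene"), names(table))
  if (length(missing_cols))
    stop(sprintf("interaction table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (is.null(table$score)) table$score <- 0
  table <- unique(table[c("mirna", "gene", "score")])
  if (any(table$score > 0))
    stop("interaction scores must be <= 0 (more negative = stronger)",
         call. = FALSE)
  out <- aggregate(score ~ mirna + gene, data = table, FUN = sum)
  out[order(out$gene, out$mirna), c("mirna", "gene", "score")]
}

#' miRNAs targeting every gene of a query set
#'
#' Exact intersection of the per-gene miRNA binder sets: the miRNAs that
#' simultaneously target all queried genes ("miRNA target cluster"
#' membership). A gene absent from the table has no binders, so the
#' intersection becomes empty (with a warning).
#'
#' @param genes Non-empty character vector of gene identifiers.
#' @param table Interaction data.frame (`mirna`, `gene`, optional `score`).
#' @return Character vector of miRNA names (sorted).
#' @export
mirnas_targeting_all <- function(genes, table) {
  if (length(genes) == 0)
    stop("empty gene set: the all-miRNAs answer is never what you want",
         call. = FALSE)
  tab <- aggregate_interactions(table)
  absent <- setdiff(genes, tab$gene)
  if (length(absent)) {
    warning(sprintf("gene(s) absent from interaction table: %s",
                    paste(absent, collapse = ", ")))
    return(character())
  }
  per_gene <- lapply(genes, function(g) tab$mirna[tab$gene == g])
  sort(Reduce(intersect, per_gene))
}

#' Rank cluster miRNAs by summed binding score
#'
#' For every miRNA targeting all cluster genes, sums its per-gene combined
#' scores across the cluster and ranks ascending (most negative = strongest
#' predicted repression first); ties break lexicographically by miRNA name.
#'
#' @inheritParams mirnas_targeting_all
#' @return Data.frame `mirna`, `summed_score`, `rank`, strongest first.
#' @export
rank_cluster_mirnas <- function(genes, table) {
  tab <- aggregate_interactions(table)
  cluster <- mirnas_targeting_all(genes, table)
  if (length(cluster) == 0)
    return(data.frame(mirna = character(), summed_score = numeric(),
                      rank = integer()))
  sub <- tab[tab$mirna %in% cluster & tab$gene %in% genes, ]
  summed <- tapply(sub$score, sub$mirna, sum)
  out <- data.frame(mirna = names(summed),
                    summed_score = as.numeric(summed),
                    stringsAsFactors = FALSE)
  out <- out[order(out$summed_score, out$mirna), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Distinct-miRNA coverage per gene
#'
#' Number of distinct miRNAs with at least one binding site in each gene's
#' 3'UTR (duplicated rows counted once).
#'
#' @param table Interaction data.frame (`mirna`, `gene`).
#' @return Named integer vector, one entry per gene in the table.
#' @export
coverage_counts <- function(table) {
  if (nrow(table) == 0) return(setNames(integer(), character()))
  tab <- aggregate_interactions(table)
  counts <- tapply(tab$mirna, tab$gene, function(x) length(unique(x)))
  setNames(as.integer(counts), names(counts))
}

#' Mine a miRNA target cluster for a gene set
#'
#' Convenience wrapper combining [mirnas_targeting_all()] and
#' [rank_cluster_mirnas()] into one report.
#'
#' @inheritParams mirnas_targeting_all
#' @return An object of class `target_cluster`: list with `genes`,
#'   `mirnas`, `ranking` (data.frame), `n_mirnas`.
#' @export
target_cluster <- function(genes, table) {
  ranking <- rank_cluster_mirnas(genes, table)
  structure(list(genes = genes, mirnas = ranking$mirna, ranking = ranking,
                 n_mirnas = nrow(ranking)),
            class = "target_cluster")
}

#' @export
print.target_cluster <- function(x, ...) {
  cat(sprintf("miRNA target cluster over {%s}\n",
              paste(x$genes, collapse = ", ")))
  cat(sprintf("%d miRNA(s) target the complete cluster\n", x$n_mirnas))
  if (x$n_mirnas > 0) print(x$ranking, row.names = FALSE)
  invisible(x)
}
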