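# Shared TSV reader with schema validation. All pipeline tables are
# tab-separated, single header line, UTF-8, '.' decimal.
read_tsv_checked <- function(path, required, numeric_cols = character()) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop(sprintf("%s: missing column(s): %s", basename(path),
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    bad <- which(is.na(v) & !is.na(tab[[cc]]) & nzchar(tab[[cc]]))
    if (length(bad))
      stop(sprintf("%s: column '%s' is not numeric at line %d",
                   basename(path), cc, bad[1] + 1L), call. = FALSE)
    tab[[cc]] <- v
  }
  tab
}

#' Read and write peptide quantification tables
#'
#' The peptide table schema is one row per peptide observation with columns
#' `protein_id`, `peptide_seq`, `replicate`, `light_area`, `heavy_area`
#' (tab-separated, single header line). Reading validates the schema and
#' reports the offending line on malformed numeric fields; negative areas
#' are rejected.
#'
#' @param path File path.
#' @return `read_peptide_table()`: a validated data.frame.
#' @export
read_peptide_table <- function(path) {
  tab <- read_tsv_checked(path,
                          c("protein_id", "peptide_seq", "replicate",
                            "light_area", "heavy_area"),
                          numeric_cols = c("light_area", "heavy_area"))
  neg <- which(tab$light_area < 0 | tab$heavy_area < 0)
  if (length(neg))
    stop(sprintf("%s: negative area at line %d", basename(path),
                 neg[1] + 1L), call. = FALSE)
  empty_pep <- which(!nzchar(tab$peptide_seq))
  if (length(empty_pep))
    stop(sprintf("%s: empty peptide_seq at line %d", basename(path),
                 empty_pep[1] + 1L), call. = FALSE)
  tab
}

#' @rdname read_peptide_table
#' @param peptides Data.frame in the peptide table schema.
#' @export
write_peptide_table <- function(peptides, path) {
  write.table(peptides, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an interaction table
#'
#' Reads a miRNA-gene interaction TSV (columns `mirna`, `gene`, optional
#' `score` and per-site coordinates).
#'
#' @param path File path.
#' @return Data.frame.
#' @export
read_interaction_table <- function(path) {
  tab <- read_tsv_checked(path, c("mirna", "gene"))
  if ("score" %in% names(tab)) tab$score <- as.numeric(tab$score)
  tab
}

#' Read predictor gene lists
#'
#' Each prediction algorithm contributes one plain-text file with one gene
#' identifier per line; the file name (without extension) names the
#' algorithm.
#'
#' @param paths Character vector of file paths.
#' @return Named list of character vectors, suitable for
#'   [consensus_votes()].
#' @export
read_gene_lists <- function(paths) {
  out <- lapply(paths, function(p) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
    x <- readLines(p, warn = FALSE)
    x[nzchar(trimws(x))]
  })
  names(out) <- sub("\\.[^.]*$", "", basename(paths))
  out
}

#' Read sequence FASTA files
#'
#' Thin wrappers over Biostrings' FASTA readers returning named character
#' vectors: UTRs in the DNA alphabet, mature miRNAs in the RNA alphabet,
#' proteins in the amino-acid alphabet. Names are truncated at the first
#' whitespace of the FASTA header.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_utr_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_utr_fasta
#' @export
read_mirna_fasta <- function(path) {
  x <- Biostrings::readRNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_utr_fasta
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Joined candidate evaluation report
#'
#' Joins the proteomic screen verdicts with the in-silico evaluation: per
#' candidate, the two replicate fold changes, the merged p-value, the
#' consensus votes across prediction algorithms, and the binding-site count
#' and combined score for the screened miRNA. A machine-readable JSON twin
#' of the TSV report can be written alongside it.
#'
#' @param candidates Data.frame from [screen_candidates()]`$candidates`
#'   (or any table with `protein_id`, `log2_fc_rep1`, `log2_fc_rep2`,
#'   `combined_p`, `verdict`).
#' @param predictions Optional data.frame from [scan_utrs()]`$predictions`
#'   filtered to one miRNA (columns `gene`, `n_sites`, `combined_score`).
#' @param votes Optional data.frame from [consensus_votes()].
#' @return Data.frame, one row per candidate, sorted by `combined_p`.
#' @export
screen_report <- function(candidates, predictions = NULL, votes = NULL) {
  out <- candidates[order(candidates$combined_p),
                    intersect(c("protein_id", "log2_fc_rep1", "log2_fc_rep2",
                                "combined_p", "verdict"), names(candidates))]
  if (!is.null(votes)) {
    i <- match(out$protein_id, votes$gene)
    out$votes <- votes$votes[i]
  }
  if (!is.null(predictions)) {
    if (length(unique(predictions$mirna)) > 1)
      stop("'predictions' must be filtered to a single miRNA", call. = FALSE)
    i <- match(out$protein_id, predictions$gene)
    out$n_sites <- predictions$n_sites[i]
    out$combined_score <- predictions$combined_score[i]
  }
  rownames(out) <- NULL
  out
}

#' @rdname screen_report
#' @param report Data.frame returned by `screen_report()`.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @export
write_screen_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    write.table(report, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(report, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  invisible(report)
}

#' Path to a bundled example/fixture data file
#'
#' @param file File name under the package's `extdata/` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a vector of file names).
#' @examples
#' mirscreen_example()
#' @export
mirscreen_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "mirscreen"),
                      recursive = TRUE))
  p <- system.file("extdata", file, package = "mirscreen")
  if (!nzchar(p))
    stop(sprintf("no bundled file '%s'", file), call. = FALSE)
  p
}
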