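#' Write named sequences to FASTA
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path input path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @keywords internal
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
read_tsv <- function(path, ...) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write per-species gene position tables
#'
#' Gene coordinates are 0-based order indices within scaffolds, not
#' base pairs.
#'
#' @param genes gene table (as in [simulate_gene_families()]).
#' @param path output TSV path.
#' @export
write_gene_positions <- function(genes, path) {
  write_tsv(genes[, c("gene_id", "species", "scaffold", "order_index")],
            path)
}

#' Write a counts matrix as TSV (gene_id + sample columns)
#' @param counts genes x samples matrix with dimnames.
#' @param path output TSV path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a counts TSV written by [write_counts()]
#' @param path input path.
#' @return genes x samples integer matrix.
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  m
}

#' Write an orthology map to TSV
#' @param orthology an `orthology_map`.
#' @param path output path.
#' @export
write_orthology <- function(orthology, path) {
  write_tsv(orthology$genes, path)
}
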