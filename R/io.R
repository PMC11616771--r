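#' Readers and writers for the tabular input formats
#'
#' All matrices travel as TSV with samples in rows (first column = sample
#' id) and genes in columns. Protein sequences travel as FASTA (record name
#' = gene symbol). PPI edges travel as a three-column TSV
#' (`gene1`, `gene2`, `evidence_class`); label tables as five-column TSV
#' (`gene1`, `gene2`, `label`, `source`, `cancer`).
#'
#' @name elisl_io
NULL

#' @param path file path.
#' @return `read_omics_matrix`: numeric matrix with sample row names and
#'   gene column names.
#' @rdname elisl_io
#' @export
read_omics_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix TSV needs a sample-id column plus genes")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' @param m matrix to write; `id` names the first (sample id) column.
#' @param id header of the sample-id column.
#' @rdname elisl_io
#' @export
write_omics_matrix <- function(m, path, id = "sample") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @return `read_protein_fasta`: named character vector of amino-acid
#'   sequences, one per gene.
#' @rdname elisl_io
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(aa))
  seqs
}

#' @param seqs named character vector of sequences.
#' @rdname elisl_io
#' @export
write_protein_fasta <- function(seqs, path) {
  aa <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' @return `read_ppi_edges`: data frame with `gene1`, `gene2`,
#'   `evidence_class`.
#' @rdname elisl_io
#' @export
read_ppi_edges <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene1", "gene2", "evidence_class")
  if (!all(need %in% names(df))) {
    stop("PPI edge TSV needs columns: ", paste(need, collapse = ", "))
  }
  df[, need]
}

#' @return `read_sl_labels`: an `sl_labels` table.
#' @rdname elisl_io
#' @export
read_sl_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene1", "gene2", "label")
  if (!all(need %in% names(df))) {
    stop("label TSV needs columns: ", paste(need, collapse = ", "))
  }
  ok <- !is.na(df$gene1) & !is.na(df$gene2) & df$gene1 != "" & df$gene2 != "" &
    df$gene1 != df$gene2
  if (any(!ok)) {
    message(sum(!ok), " malformed label record(s) rejected")
    df <- df[ok, , drop = FALSE]
  }
  sl_labels(df$gene1, df$gene2, df$label,
            source = if ("source" %in% names(df)) df$source else "unknown",
            cancer = if ("cancer" %in% names(df)) df$cancer else "PAN")
}

#' @param labels an `sl_labels` table.
#' @rdname elisl_io
#' @export
write_sl_labels <- function(labels, path) {
  df <- data.frame(gene1 = labels$gene_a, gene2 = labels$gene_b,
                   label = labels$label, source = labels$source,
                   cancer = labels$cancer, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @return `read_clinical`: data frame with columns `sample`, `time`,
#'   `event`, `age`, `sex`, `cancer` (time in months).
#' @rdname elisl_io
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  if (!all(need %in% names(df))) {
    stop("clinical TSV needs columns: ", paste(need, collapse = ", "))
  }
  df
}

#' @return `read_mutations`: data frame with `sample`, `gene`,
#'   `variant_class`.
#' @rdname elisl_io
#' @export
read_mutations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "gene", "variant_class")
  if (!all(need %in% names(df))) {
    stop("mutation TSV needs columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Read / write gene embedding tables
#'
#' A gene embedding table is a named list-free structure: a numeric
#' gene x dimension matrix with gene symbols as row names. On disk it is a
#' TSV whose first column is the gene symbol, so precomputed embeddings
#' (e.g. from an external protein language model) can be imported and
#' bypass the built-in embedders.
#'
#' @param path file path.
#' @return `read_embedding_table`: numeric gene x d matrix.
#' @export
read_embedding_table <- function(path) {
  m <- read_omics_matrix(path)
  if (any(!is.finite(m))) stop("embedding table must be finite")
  m
}

#' @param table gene x d embedding matrix.
#' @rdname read_embedding_table
#' @export
write_embedding_table <- function(table, path) {
  write_omics_matrix(table, path, id = "gene")
}
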