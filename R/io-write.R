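# Plain-text writers paired with the module readers, so every simulated
# artifact can be written to disk and round-tripped.

#' Write a gene list (one symbol per line, optional length column)
#'
#' @param genes Data frame with `gene_id` and optionally `length_bp`, or a
#'   character vector of symbols.
#' @param path Output path.
#' @export
write_gene_list <- function(genes, path) {
  if (is.character(genes)) genes <- tibble(gene_id = genes)
  cols <- intersect(c("gene_id", "length_bp"), names(genes))
  readr::write_tsv(genes[, cols], path, col_names = FALSE)
  invisible(path)
}

#' Write a mutation table in the minimal four-column dialect
#'
#' @param records Tibble (`gene_id`, `sample_id`, `cohort`,
#'   `variant_class`).
#' @param path Output path.
#' @export
write_mutation_table <- function(records, path) {
  out <- records %>%
    mutate(variant_class = as.character(.data$variant_class)) %>%
    select("gene_id", "sample_id", "cohort", "variant_class")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write an interaction network as a two-column edge list
#'
#' @param network `igraph` object.
#' @param path Output path.
#' @export
write_edge_list <- function(network, path) {
  ends <- igraph::as_edgelist(network)
  readr::write_tsv(tibble(from = ends[, 1], to = ends[, 2]), path,
                   col_names = FALSE)
  invisible(path)
}

#' Write an expression matrix as gene-by-sample TSV
#'
#' @param mat Expression tibble.
#' @param path Output path.
#' @export
write_expression_matrix <- function(mat, path) {
  readr::write_tsv(mat, path)
  invisible(path)
}

#' Write codon pairs as FASTA (`<id>_a` / `<id>_b` records)
#'
#' @param pairs Tibble (`pair_id`, `seq_a`, `seq_b`).
#' @param path Output path.
#' @export
write_codon_pairs <- function(pairs, path) {
  lines <- unlist(lapply(seq_len(nrow(pairs)), function(i) {
    c(paste0(">", pairs$pair_id[[i]], "_a"), pairs$seq_a[[i]],
      paste0(">", pairs$pair_id[[i]], "_b"), pairs$seq_b[[i]])
  }))
  readr::write_lines(lines, path)
  invisible(path)
}
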