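# Expression normalisation: median scaling for RSEM-style cancer matrices,
# RPKM for organ exon coverage, and per-organ log2 Z-scores.
#
# An expression matrix is a wide tibble: first column `gene_id`, remaining
# columns numeric sample (or organ) values. The normalisation state is
# carried in the "expr_state" attribute
# (RAW -> MEDIAN_NORMALIZED; RPKM -> LOG2 -> ZSCORE).

expr_state <- function(mat) attr(mat, "expr_state") %||% "RAW"

set_expr_state <- function(mat, state) {
  attr(mat, "expr_state") <- state
  mat
}

expr_values <- function(mat) {
  stopifnot(is.data.frame(mat), names(mat)[1] == "gene_id")
  as.matrix(mat[, -1, drop = FALSE])
}

#' Median-normalise an expression matrix
#'
#' Divides each sample column by its median over genes with a positive
#' value, so that the post-normalisation median of those genes is exactly 1.
#' Zeros stay zero; within-sample rank order is preserved. Idempotent.
#'
#' @param mat Expression tibble (`gene_id` + numeric sample columns), state
#'   `RAW` or `MEDIAN_NORMALIZED`.
#' @return The normalised tibble, state `MEDIAN_NORMALIZED`.
#' @export
median_normalize <- function(mat) {
  v <- expr_values(mat)
  if (any(v < 0, na.rm = TRUE)) {
    stop_dg("Negative values in a raw expression matrix.",
            "dualgene_domain_error")
  }
  if (!expr_state(mat) %in% c("RAW", "MEDIAN_NORMALIZED")) {
    stop_dg("median_normalize expects a RAW (or already median-normalised) matrix.",
            "dualgene_state_error")
  }
  out <- mat
  for (j in seq_len(ncol(v))) {
    pos <- v[, j] > 0
    if (!any(pos)) {
      stop_dg(sprintf("Sample '%s' has no positive values.",
                      colnames(v)[j]), "dualgene_degenerate_sample")
    }
    out[[j + 1L]] <- v[, j] / median(v[pos, j])
  }
  set_expr_state(out, "MEDIAN_NORMALIZED")
}

#' Average expression per gene within cohorts
#'
#' @param mat Expression tibble.
#' @param groups Tibble (`sample`, `cohort`) assigning every sample column
#'   to exactly one cohort.
#' @return Tibble `gene_id` + one column per cohort holding the arithmetic
#'   mean over that cohort's samples.
#' @export
mean_per_gene <- function(mat, groups) {
  stopifnot(all(c("sample", "cohort") %in% names(groups)))
  samples <- names(mat)[-1]
  missing <- setdiff(samples, groups$sample)
  if (length(missing) > 0L) {
    stop_dg(paste0("Samples without a cohort assignment: ",
                   paste(missing, collapse = ", ")),
            "dualgene_format_error")
  }
  v <- expr_values(mat)
  out <- tibble(gene_id = mat$gene_id)
  for (co in unique(groups$cohort[groups$sample %in% samples])) {
    cols <- groups$sample[groups$cohort == co]
    out[[co]] <- rowMeans(v[, intersect(samples, cols), drop = FALSE])
  }
  set_expr_state(out, expr_state(mat))
}

#' Reads per kilobase of feature per million mapped reads
#'
#' `rpkm = read_count / ((feature_length_bp / 1e3) * (total_mapped / 1e6))`.
#'
#' @param read_count Non-negative read count(s).
#' @param feature_length_bp Feature length in base pairs (> 0).
#' @param total_mapped_reads Library size in mapped reads (> 0).
#' @return Numeric RPKM value(s).
#' @export
#' @examples
#' rpkm(100, 2000, 1e7) # 5
rpkm <- function(read_count, feature_length_bp, total_mapped_reads) {
  assert_positive(feature_length_bp, "feature_length_bp")
  assert_positive(total_mapped_reads, "total_mapped_reads")
  if (any(read_count < 0)) {
    stop_dg("`read_count` must be non-negative.", "dualgene_domain_error")
  }
  read_count / ((feature_length_bp / 1e3) * (total_mapped_reads / 1e6))
}

#' Per-gene, per-organ RPKM from exon coverage
#'
#' Collapses exon-level read counts to gene level (summed exon counts over
#' summed exon lengths), computes per-sample RPKM against the sample's total
#' mapped reads (the sum of its exon counts), and averages replicate samples
#' within each organ.
#'
#' @param exon_cov Tibble (`gene_id`, `exon_id`, `exon_length_bp`, `sample`,
#'   `read_count`).
#' @param sample_organ Tibble (`sample`, `organ`).
#' @return Expression tibble `gene_id` + one RPKM column per organ, state
#'   `RPKM`.
#' @export
organ_rpkm <- function(exon_cov, sample_organ) {
  need <- c("gene_id", "exon_id", "exon_length_bp", "sample", "read_count")
  stopifnot(all(need %in% names(exon_cov)),
            all(c("sample", "organ") %in% names(sample_organ)))
  per_sample <- exon_cov %>%
    group_by(.data$sample) %>%
    mutate(total_mapped = sum(.data$read_count)) %>%
    group_by(.data$gene_id, .data$sample, .data$total_mapped) %>%
    summarise(n_reads = sum(.data$read_count),
              len = sum(.data$exon_length_bp), .groups = "drop") %>%
    mutate(rpkm = rpkm(.data$n_reads, .data$len, .data$total_mapped))
  wide <- per_sample %>%
    left_join(as_tibble(sample_organ), by = "sample") %>%
    group_by(.data$gene_id, .data$organ) %>%
    summarise(rpkm = mean(.data$rpkm), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "organ", values_from = "rpkm",
                       values_fill = 0)
  set_expr_state(wide, "RPKM")
}

#' Per-organ log2 Z-scores
#'
#' Transforms RPKM values to `log2(x + pseudocount)` and standardises every
#' organ column to mean 0 and (n-1) standard deviation 1. Applied to an
#' already log-transformed or Z-scored matrix, the log step is skipped, so
#' the operation is idempotent.
#'
#' @param mat Expression tibble, state `RPKM`/`RAW` (values are logged) or
#'   `LOG2`/`ZSCORE` (standardised only).
#' @param pseudocount Added before the log to handle zeros; default 1.
#' @return Z-scored tibble, state `ZSCORE`.
#' @export
log2_zscore <- function(mat, pseudocount = 1) {
  v <- expr_values(mat)
  if (nrow(v) < 2L) {
    stop_dg("Need at least 2 genes per organ to standardise.",
            "dualgene_domain_error")
  }
  if (expr_state(mat) %in% c("RAW", "RPKM", "MEDIAN_NORMALIZED")) {
    if (any(v < 0)) {
      stop_dg("Negative values in an RPKM matrix.", "dualgene_domain_error")
    }
    v <- log2(v + pseudocount)
  }
  out <- mat
  for (j in seq_len(ncol(v))) {
    s <- sd(v[, j])
    if (!is.finite(s) || s == 0) {
      stop_dg(sprintf("Organ '%s' has zero variance; Z-score undefined.",
                      colnames(v)[j]), "dualgene_degenerate_sample")
    }
    out[[j + 1L]] <- (v[, j] - mean(v[, j])) / s
  }
  set_expr_state(out, "ZSCORE")
}

#' Read a gene-by-sample expression matrix
#'
#' @param path TSV with a header; first column gene symbols, remaining
#'   columns numeric sample values.
#' @return Expression tibble, state `RAW`.
#' @export
read_expression_matrix <- function(path) {
  mat <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  names(mat)[1] <- "gene_id"
  mat$gene_id <- normalize_symbols(mat$gene_id)
  set_expr_state(as_tibble(mat), "RAW")
}
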