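# Somatic-mutation profiling: MAF-like ingestion, the non-silent filter,
# per-gene counts and the length/case-normalised mutation-rate statistic.

# Standard MAF Variant_Classification tokens -> closed 10-value vocabulary.
MAF_CLASS_MAP <- c(
  Missense_Mutation = "MISSENSE",
  Nonsense_Mutation = "NONSENSE",
  Silent            = "SILENT",
  In_Frame_Ins      = "IN_FRAME_INS",
  Frame_Shift_Ins   = "FRAME_SHIFT_INS",
  Frame_Shift_Del   = "FRAME_SHIFT_DEL",
  In_Frame_Del      = "IN_FRAME_DEL",
  Splice_Site       = "SPLICE_SITE",
  Nonstop_Mutation  = "NONSTOP",
  RNA               = "RNA"
)

#' Read a MAF-like somatic mutation table
#'
#' Accepts either standard MAF column names (`Hugo_Symbol`,
#' `Tumor_Sample_Barcode`, `Variant_Classification`, plus a cohort column)
#' or the minimal four-column dialect (`gene`/`gene_id`, `sample`/
#' `sample_id`, `cohort`, `class`/`variant_class`). Standard MAF
#' classification tokens are mapped onto the internal 10-value vocabulary;
#' rows with unmapped tokens (e.g. `Translation_Start_Site`) are skipped and
#' tallied.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param cohort Optional single cohort label applied to every row when the
#'   file carries no cohort column (per-cohort files).
#' @return Tibble (`gene_id`, `sample_id`, `cohort`, `variant_class`) with
#'   attribute `n_skipped` (count of unmapped-class rows, warned about).
#' @export
read_mutation_table <- function(path, cohort = NULL) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  pick <- function(...) {
    cand <- intersect(c(...), names(raw))
    if (length(cand) > 0L) cand[[1L]] else NA_character_
  }
  gene_col <- pick("Hugo_Symbol", "gene_id", "gene")
  sample_col <- pick("Tumor_Sample_Barcode", "sample_id", "sample")
  class_col <- pick("Variant_Classification", "variant_class", "class")
  cohort_col <- pick("cohort", "cancer_type", "Cohort")
  for (nm in c(gene_col, sample_col, class_col)) {
    if (is.na(nm)) {
      stop_dg(paste0("Required column missing: need gene (Hugo_Symbol), ",
                     "sample (Tumor_Sample_Barcode) and class ",
                     "(Variant_Classification) columns."),
              "dualgene_format_error")
    }
  }
  cls_raw <- raw[[class_col]]
  cls <- ifelse(cls_raw %in% VARIANT_CLASSES, cls_raw,
                unname(MAF_CLASS_MAP[cls_raw]))
  n_skipped <- sum(is.na(cls))
  if (n_skipped > 0L) {
    warn(sprintf("%d record(s) with unmapped variant classification skipped.",
                 n_skipped))
  }
  out <- tibble(
    gene_id = normalize_symbols(raw[[gene_col]]),
    sample_id = raw[[sample_col]],
    cohort = if (!is.na(cohort_col)) raw[[cohort_col]]
             else if (!is.null(cohort)) as.character(cohort)
             else NA_character_,
    variant_class = factor(cls, levels = VARIANT_CLASSES)
  )
  out <- out[!is.na(cls), , drop = FALSE]
  if (any(!nzchar(out$sample_id))) {
    stop_dg("Empty sample identifiers found.", "dualgene_format_error")
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Keep only protein-altering (non-silent) mutations
#'
#' Retains missense, nonsense, in-frame and frameshift indels, splice-site
#' and nonstop records; removes silent and non-coding RNA records. Row order
#' is preserved.
#'
#' @param records Mutation tibble with a `variant_class` column.
#' @return The filtered tibble, with attribute `n_removed`.
#' @export
filter_non_silent <- function(records) {
  stopifnot("variant_class" %in% names(records))
  keep <- as.character(records$variant_class) %in% NON_SILENT_CLASSES
  out <- records[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Per-gene mutation counts
#'
#' Counts records per gene (optionally per cohort); every gene of the
#' partition appears, with zero for genes without records.
#'
#' @param records Mutation tibble (already filtered as desired).
#' @param partition Gene partition from [partition_universe()] (needs
#'   `gene_id`, `set_label`).
#' @param scope `"ALL"` for pan-cohort totals or `"cohort"` for per-cohort
#'   counts.
#' @return Tibble (`gene_id`, `set_label`[, `cohort`], `n`).
#' @export
count_per_gene <- function(records, partition, scope = c("ALL", "cohort")) {
  scope <- arg_match(scope)
  base <- partition %>% select("gene_id", "set_label")
  if (scope == "ALL") {
    counts <- records %>% count(.data$gene_id)
    base %>%
      left_join(counts, by = "gene_id") %>%
      mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  } else {
    cohorts <- unique(records$cohort)
    tidyr::expand_grid(base, cohort = cohorts) %>%
      left_join(records %>% count(.data$gene_id, .data$cohort),
                by = c("gene_id", "cohort")) %>%
      mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  }
}

#' Per-gene mutation rate
#'
#' The rate statistic is mutations per base pair per case:
#' `(total_count / n_cases) / length_bp`. The total count includes both
#' silent and non-silent records.
#'
#' @param total_count Non-negative mutation count(s).
#' @param n_cases Number of cases in the cohort (> 0).
#' @param length_bp Gene length in base pairs (> 0).
#' @return Numeric rate vector (recycled to the common length).
#' @export
#' @examples
#' mutation_rate(10, 5, 1000) # 0.002
mutation_rate <- function(total_count, n_cases, length_bp) {
  assert_positive(n_cases, "n_cases")
  assert_positive(length_bp, "length_bp")
  if (any(total_count < 0)) {
    stop_dg("`total_count` must be non-negative.", "dualgene_domain_error")
  }
  (total_count / n_cases) / length_bp
}

#' Build per-gene, per-cohort mutation profiles
#'
#' For every partition gene and cohort present in `records`, computes the
#' non-silent count, the total (silent + non-silent) count, and the mutation
#' rate. `n_cases` defaults to the number of distinct sample ids seen in the
#' cohort unless an override table is supplied.
#'
#' @param records Unfiltered mutation tibble (silent/RNA still present).
#' @param partition Gene partition with `gene_id`, `set_label`, `length_bp`.
#' @param cohort_sizes Optional tibble (`cohort`, `n_cases`) overriding the
#'   observed distinct-sample counts.
#' @return Tibble (`gene_id`, `set_label`, `cohort`, `n_nonsilent`,
#'   `n_total`, `n_cases`, `length_bp`, `rate`).
#' @export
mutation_profiles <- function(records, partition, cohort_sizes = NULL) {
  stopifnot("length_bp" %in% names(partition))
  nonsilent <- filter_non_silent(records)
  coding <- records %>%
    filter(as.character(.data$variant_class) != "RNA")
  if (is.null(cohort_sizes)) {
    cohort_sizes <- records %>%
      group_by(cohort = .data$cohort) %>%
      summarise(n_cases = dplyr::n_distinct(.data$sample_id),
                .groups = "drop")
  }
  count_per_gene(nonsilent, partition, scope = "cohort") %>%
    rename(n_nonsilent = "n") %>%
    left_join(coding %>% count(.data$gene_id, .data$cohort, name = "n_total"),
              by = c("gene_id", "cohort")) %>%
    mutate(n_total = ifelse(is.na(.data$n_total), 0L, .data$n_total)) %>%
    left_join(cohort_sizes, by = "cohort") %>%
    left_join(partition %>% select("gene_id", "length_bp"), by = "gene_id") %>%
    mutate(rate = mutation_rate(.data$n_total, .data$n_cases,
                                .data$length_bp))
}

# Default mapping from variant class to potential functional impact.
DEFAULT_IMPACT_MAP <- c(
  NONSENSE = "LOF_POTENTIAL", FRAME_SHIFT_INS = "LOF_POTENTIAL",
  FRAME_SHIFT_DEL = "LOF_POTENTIAL", SPLICE_SITE = "LOF_POTENTIAL",
  NONSTOP = "LOF_POTENTIAL",
  MISSENSE = "GOF_POTENTIAL", IN_FRAME_INS = "GOF_POTENTIAL",
  IN_FRAME_DEL = "GOF_POTENTIAL",
  SILENT = "EXCLUDED", RNA = "EXCLUDED"
)

#' Classify variant classes by potential functional impact
#'
#' Maps each variant class to `LOF_POTENTIAL` (truncating/splice-disrupting
#' classes), `GOF_POTENTIAL` (protein-altering but length-preserving or
#' in-frame classes) or `EXCLUDED` (silent, non-coding RNA). The mapping is
#' a convention, not a prediction, and can be overridden.
#'
#' @param variant_class Character or factor vector of variant classes.
#' @param impact_map Named character vector overriding the default mapping.
#' @return Factor over `LOF_POTENTIAL`, `GOF_POTENTIAL`, `EXCLUDED`.
#' @export
classify_functional_impact <- function(variant_class,
                                       impact_map = DEFAULT_IMPACT_MAP) {
  cls <- as.character(variant_class)
  if (!all(cls %in% names(impact_map))) {
    stop_dg("Variant class outside the impact map.", "dualgene_domain_error")
  }
  factor(unname(impact_map[cls]),
         levels = c("LOF_POTENTIAL", "GOF_POTENTIAL", "EXCLUDED"))
}
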