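#' Read a gene list file
#'
#' Reads a plain-text gene list: one symbol per line, an optional second
#' tab-separated column with the gene's coding/exonic length in base pairs,
#' and `#` comment lines. Symbols are uppercased and whitespace-stripped;
#' no alias resolution is attempted.
#'
#' @param path Path to the list file.
#' @return A tibble with columns `gene_id` and, when present in the file,
#'   `length_bp`.
#' @export
read_gene_list <- function(path) {
  lines <- readr::read_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- tibble(gene_id = normalize_symbols(vapply(parts, `[[`, "", 1L)))
  if (any(lengths(parts) >= 2L)) {
    out$length_bp <- as.integer(vapply(parts, function(p) {
      if (length(p) >= 2L) p[[2L]] else NA_character_
    }, ""))
  }
  out
}

#' Intersect oncogene and tumor-suppressor candidate lists
#'
#' Genes present in both an oncogene list and a tumor-suppressor list are the
#' candidates for dual-role ("double-agent") status. Symbols are case
#' normalised (uppercased, whitespace stripped) before comparison.
#'
#' @param onc_list,tsg_list Character vectors of gene symbols.
#' @return Sorted character vector of candidate symbols. An empty
#'   intersection is returned with a warning, not an error.
#' @export
#' @examples
#' intersect_candidates(c("A", "B", "C"), c("B", "C", "D"))
intersect_candidates <- function(onc_list, tsg_list) {
  if (length(onc_list) == 0L) {
    stop_dg("`onc_list` is empty.", "dualgene_empty_input")
  }
  if (length(tsg_list) == 0L) {
    stop_dg("`tsg_list` is empty.", "dualgene_empty_input")
  }
  out <- sort(intersect(unique(normalize_symbols(onc_list)),
                        unique(normalize_symbols(tsg_list))))
  if (length(out) == 0L) {
    warn("No genes shared between the oncogene and tumor-suppressor lists.")
  }
  out
}

#' Partition a gene universe into POTSF / ONC / TSG / NCRG sets
#'
#' Every universe gene receives exactly one label: `POTSF` if in the curated
#' dual-role list, `ONC` if only in the oncogene list, `TSG` if only in the
#' tumor-suppressor list, `NCRG` if in neither. Genes in both parent lists
#' but not curated as dual-role are labelled `UNRESOLVED` and excluded from
#' all four comparison sets.
#'
#' @param universe Data frame with `gene_id` and optionally `length_bp`.
#' @param onc_list,tsg_list Character vectors of parent-list symbols.
#' @param curated_potsf Character vector of curated dual-role symbols; must
#'   be a subset of `intersect_candidates(onc_list, tsg_list)`.
#' @return A tibble (`gene_id`, `length_bp` if supplied, `set_label` as a
#'   factor over POTSF/ONC/TSG/NCRG/UNRESOLVED), one row per universe gene,
#'   with attribute `n_skipped`: the number of listed genes absent from the
#'   universe (also warned about).
#' @export
partition_universe <- function(universe, onc_list, tsg_list,
                               curated_potsf = character()) {
  stopifnot(is.data.frame(universe), "gene_id" %in% names(universe))
  genes <- normalize_symbols(universe$gene_id)
  if (anyDuplicated(genes)) {
    stop_dg("Universe gene ids must be unique.", "dualgene_domain_error")
  }
  onc <- unique(normalize_symbols(onc_list))
  tsg <- unique(normalize_symbols(tsg_list))
  cur <- unique(normalize_symbols(curated_potsf))

  overlap <- intersect(onc, tsg)
  bad <- setdiff(cur, overlap)
  if (length(bad) > 0L) {
    stop_dg(paste0("Curated dual-role genes not in the oncogene/tumor-",
                   "suppressor overlap: ", paste(bad, collapse = ", ")),
            "dualgene_curation_error")
  }

  missing <- setdiff(union(onc, tsg), genes)
  if (length(missing) > 0L) {
    warn(sprintf("%d listed gene(s) absent from the universe; skipped.",
                 length(missing)))
  }

  in_onc <- genes %in% onc
  in_tsg <- genes %in% tsg
  label <- rep("NCRG", length(genes))
  label[in_onc & !in_tsg] <- "ONC"
  label[!in_onc & in_tsg] <- "TSG"
  label[in_onc & in_tsg] <- "UNRESOLVED"
  label[genes %in% cur] <- "POTSF"

  out <- as_tibble(universe)
  out$gene_id <- genes
  out$set_label <- factor(label, levels = SET_LEVELS)
  attr(out, "n_skipped") <- length(missing)
  out
}

#' Count genes per set label
#'
#' @param partition Output of [partition_universe()].
#' @return Tibble (`set_label`, `n`) covering all five labels.
#' @export
set_counts <- function(partition) {
  partition %>%
    count(.data$set_label, .drop = FALSE) %>%
    as_tibble()
}

#' Classify dual-role genes into transcription factors, kinases and others
#'
#' @param potsf_genes Character vector of dual-role gene symbols.
#' @param class_map Data frame (`gene_id`, `potsf_class`) with classes among
#'   `TF`, `KINASE`, `OTHER`. Genes missing from the map fall back to
#'   `OTHER` with a warning.
#' @return Tibble (`potsf_class`, `n`); counts sum to `length(potsf_genes)`.
#' @export
classify_potsf <- function(potsf_genes, class_map) {
  lv <- c("TF", "KINASE", "OTHER")
  genes <- unique(normalize_symbols(potsf_genes))
  if (length(genes) == 0L) {
    return(tibble(potsf_class = factor(lv, levels = lv), n = 0L))
  }
  stopifnot(all(c("gene_id", "potsf_class") %in% names(class_map)))
  map <- setNames(toupper(class_map$potsf_class),
                  normalize_symbols(class_map$gene_id))
  cls <- unname(map[genes])
  if (anyNA(cls)) {
    warn(sprintf("%d dual-role gene(s) missing from class_map; set to OTHER.",
                 sum(is.na(cls))))
    cls[is.na(cls)] <- "OTHER"
  }
  if (!all(cls %in% lv)) {
    stop_dg("potsf_class values must be TF, KINASE or OTHER.",
            "dualgene_domain_error")
  }
  tibble(gene_id = genes, potsf_class = factor(cls, levels = lv)) %>%
    count(.data$potsf_class, .drop = FALSE)
}

#' Tally gene-annotation associations
#'
#' Given (gene, label) association pairs -- e.g. gene-to-cancer-type links --
#' computes the number of distinct labels per gene and the share of all
#' association pairs held by each label. Duplicated pairs count once.
#'
#' @param assoc_table Data frame with columns `gene_id` and `label`.
#' @return List of two tibbles: `per_gene` (`gene_id`, `n_labels`) and
#'   `per_label` (`label`, `n_genes`, `percentage`), the latter in
#'   descending percentage order with ties broken lexicographically.
#'   Percentages sum to 100 (exactly, unrounded); round for display.
#' @export
tally_associations <- function(assoc_table) {
  stopifnot(all(c("gene_id", "label") %in% names(assoc_table)))
  pairs <- assoc_table %>%
    as_tibble() %>%
    mutate(gene_id = normalize_symbols(.data$gene_id)) %>%
    distinct(.data$gene_id, .data$label)
  if (nrow(pairs) == 0L) {
    return(list(
      per_gene = tibble(gene_id = character(), n_labels = integer()),
      per_label = tibble(label = character(), n_genes = integer(),
                         percentage = numeric())
    ))
  }
  per_gene <- pairs %>%
    count(.data$gene_id, name = "n_labels") %>%
    arrange(desc(.data$n_labels), .data$gene_id)
  per_label <- pairs %>%
    count(.data$label, name = "n_genes") %>%
    mutate(percentage = 100 * .data$n_genes / sum(.data$n_genes)) %>%
    arrange(desc(.data$percentage), .data$label)
  list(per_gene = per_gene, per_label = per_label)
}

#' Load the packaged dual-role gene classification table
#'
#' Returns the packaged curated list of 83 dual-role genes with their
#' functional class (41 transcription factors, 13 kinases, 29 others).
#' The symbol `WT` is preserved verbatim from the source table.
#'
#' @return Tibble (`gene_id`, `potsf_class`).
#' @export
load_potsf_table <- function() {
  path <- system.file("extdata", "table1_potsf.tsv", package = "dualgene",
                      mustWork = TRUE)
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = "cc") %>%
    mutate(gene_id = normalize_symbols(.data$gene_id))
}

#' Load the default cancer-cohort sample sizes
#'
#' Eleven pan-cancer cohort labels (colon and rectum merged as COADREAD)
#' with their RNA-seq sample counts, used as default `n_cases` values.
#'
#' @return Tibble (`cohort`, `n_cases`).
#' @export
load_cohort_sizes <- function() {
  path <- system.file("extdata", "cohort_sizes.tsv", package = "dualgene",
                      mustWork = TRUE)
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = "ci")
}
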