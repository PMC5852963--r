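# Synthetic-data generators emulating the study's inputs: a partitioned
# gene universe, Poisson somatic-mutation tables over cancer cohorts,
# log-normal expression matrices with set-specific location shifts, a
# hub-biased growing interactome, and codon pairs evolved at a target
# omega. Every generator is a pure function of its arguments and `seed`.

# Printed per-class mutation counts used as default class proportions
# (renormalised; their published sum exceeds the published total, so they
# are used only as relative weights).
CLASS_WEIGHTS <- c(
  MISSENSE = 416847, NONSENSE = 39869, SILENT = 134635,
  IN_FRAME_INS = 916, FRAME_SHIFT_INS = 5134, FRAME_SHIFT_DEL = 10743,
  IN_FRAME_DEL = 3590, SPLICE_SITE = 10190, NONSTOP = 784, RNA = 10659
)

#' Default variant-class probabilities
#'
#' Proportional to the published per-class pan-cancer counts.
#'
#' @return Named numeric vector over the 10 variant classes, summing to 1.
#' @export
default_class_probs <- function() {
  CLASS_WEIGHTS[VARIANT_CLASSES] / sum(CLASS_WEIGHTS)
}

# Default set-specific mutation-rate multipliers: dual-role genes and
# oncogenes carry the elevated burden, tumor suppressors a mild one.
DEFAULT_RATE_MULT <- c(POTSF = 3, ONC = 2.5, TSG = 1.2, NCRG = 1)

# Default network attachment attractiveness, mirroring the observed mean
# degree ordering (POTSF >> ONC ~ TSG > NCRG).
DEFAULT_ATTRACT <- c(POTSF = 4, ONC = 2, TSG = 2, NCRG = 1)

# Default log2-scale expression locations: tumor suppressors shifted +1,
# the qualitative normal-organ pattern.
DEFAULT_EXPR_LOC <- c(POTSF = 6, ONC = 6, TSG = 7, NCRG = 6)

#' Simulate a partitioned gene universe
#'
#' Gene lengths are log-normal (default median 1500 bp, sdlog 0.6, floored
#' at 90 bp); dual-role genes receive a TF/KINASE/OTHER class drawn with
#' the curated 41/13/29 proportions.
#'
#' @param n_genes Named integer vector of set sizes; defaults to the
#'   curated set sizes (83 dual-role, 1320 oncogenes, 952 tumor
#'   suppressors) plus 1000 non-cancer genes.
#' @param length_meanlog,length_sdlog Log-normal length parameters.
#' @param seed Integer RNG seed.
#' @return Tibble (`gene_id`, `set_label`, `length_bp`, `potsf_class`).
#' @export
simulate_universe <- function(n_genes = c(POTSF = 83, ONC = 1320,
                                          TSG = 952, NCRG = 1000),
                              length_meanlog = log(1500),
                              length_sdlog = 0.6,
                              seed = 1) {
  stopifnot(all(names(n_genes) %in% SET_LEVELS), all(n_genes >= 0))
  with_seed(seed, {
    labels <- rep(names(n_genes), times = n_genes)
    n <- length(labels)
    lengths <- pmax(90L, as.integer(round(rlnorm(n, length_meanlog,
                                                 length_sdlog))))
    cls <- rep(NA_character_, n)
    is_potsf <- labels == "POTSF"
    cls[is_potsf] <- sample(c("TF", "KINASE", "OTHER"), sum(is_potsf),
                            replace = TRUE, prob = c(41, 13, 29) / 83)
    tibble(
      gene_id = sprintf("G%05d", seq_len(n)),
      set_label = factor(labels, levels = SET_LEVELS),
      length_bp = lengths,
      potsf_class = cls
    )
  })
}

#' Simulate a MAF-like somatic mutation table
#'
#' Per gene and cohort, the mutation count is
#' `Poisson(base_rate * multiplier(set) * length_bp * n_cases)`; variant
#' classes are drawn from `class_probs` and sample ids uniformly over the
#' cohort's cases.
#'
#' @param universe Output of [simulate_universe()].
#' @param cohorts Tibble (`cohort`, `n_cases`); defaults to the packaged
#'   11-cohort table.
#' @param base_rate Mutations per base pair per case for a multiplier-1
#'   gene; default `6e-6` (pan-cancer scale: roughly 0.009 mutations per
#'   gene per case at a 1.5 kb coding length).
#' @param rate_multiplier Named per-set multipliers.
#' @param class_probs Named probabilities over the 10 variant classes.
#' @param seed Integer RNG seed.
#' @return Tibble (`gene_id`, `sample_id`, `cohort`, `variant_class`).
#' @export
simulate_mutations <- function(universe,
                               cohorts = load_cohort_sizes(),
                               base_rate = 6e-6,
                               rate_multiplier = DEFAULT_RATE_MULT,
                               class_probs = default_class_probs(),
                               seed = 1) {
  stopifnot(abs(sum(class_probs) - 1) < 1e-8, all(rate_multiplier > 0))
  with_seed(seed, {
    grid <- tidyr::expand_grid(
      universe %>% select("gene_id", "set_label", "length_bp"),
      cohorts
    ) %>%
      mutate(
        mult = unname(rate_multiplier[as.character(.data$set_label)]),
        lambda = base_rate * .data$mult * .data$length_bp * .data$n_cases,
        n_mut = rpois(dplyr::n(), .data$lambda)
      ) %>%
      filter(.data$n_mut > 0)
    if (nrow(grid) == 0L) {
      return(tibble(gene_id = character(), sample_id = character(),
                    cohort = character(),
                    variant_class = factor(character(),
                                           levels = VARIANT_CLASSES)))
    }
    recs <- grid %>%
      tidyr::uncount(.data$n_mut) %>%
      mutate(
        sample_id = sprintf("%s_S%04d", .data$cohort,
                            as.integer(ceiling(stats::runif(dplyr::n()) *
                                                 .data$n_cases))),
        variant_class = factor(
          sample(names(class_probs), dplyr::n(), replace = TRUE,
                 prob = class_probs),
          levels = VARIANT_CLASSES
        )
      ) %>%
      select("gene_id", "sample_id", "cohort", "variant_class")
    recs
  })
}

#' Generate the pan-cancer class-count fixture
#'
#' A mutation table of exactly 617,354 records with exactly 134,635
#' `SILENT` and 10,659 `RNA` records; the remaining 472,060 non-silent
#' records are allocated across the eight non-silent classes proportionally
#' to their published counts (largest-remainder rounding). Gene, sample and
#' cohort columns are filled from a small synthetic pool so the table flows
#' through the standard readers and filters.
#'
#' @param seed Integer RNG seed (controls only the row shuffle and
#'   gene/sample assignment, not the class counts).
#' @return Tibble (`gene_id`, `sample_id`, `cohort`, `variant_class`) with
#'   617,354 rows.
#' @export
simulate_class_fixture <- function(seed = 1) {
  total <- 617354L
  fixed <- c(SILENT = 134635L, RNA = 10659L)
  ns_weights <- CLASS_WEIGHTS[NON_SILENT_CLASSES]
  ns_total <- total - sum(fixed)
  raw <- ns_weights / sum(ns_weights) * ns_total
  ns_counts <- floor(raw)
  rem <- ns_total - sum(ns_counts)
  top_up <- order(raw - ns_counts, decreasing = TRUE)[seq_len(rem)]
  ns_counts[top_up] <- ns_counts[top_up] + 1L
  counts <- c(ns_counts, fixed)
  stopifnot(sum(counts) == total)
  with_seed(seed, {
    classes <- sample(rep(names(counts), times = counts))
    cohorts <- load_cohort_sizes()
    co <- sample(cohorts$cohort, total, replace = TRUE,
                 prob = cohorts$n_cases)
    tibble(
      gene_id = sprintf("G%05d", sample.int(20947L, total, replace = TRUE)),
      sample_id = sprintf("%s_S%04d", co,
                          sample.int(500L, total, replace = TRUE)),
      cohort = co,
      variant_class = factor(classes, levels = VARIANT_CLASSES)
    )
  })
}

#' Simulate a log-normal expression matrix
#'
#' Values are `2^N(location(set), sigma)` per gene and sample, so
#' set-specific location shifts are recoverable on the log2 scale.
#'
#' @param universe Output of [simulate_universe()].
#' @param n_samples Samples (columns) to draw; default 6.
#' @param expr_location Named per-set log2 locations.
#' @param sigma Log2-scale standard deviation; default 2. `sigma = 0`
#'   produces constant columns (useful for exercising degenerate-input
#'   errors downstream).
#' @param sample_prefix Column-name prefix; default `"S"`.
#' @param seed Integer RNG seed.
#' @return Expression tibble (`gene_id` + sample columns), state `RAW`.
#' @export
simulate_expression <- function(universe, n_samples = 6,
                                expr_location = DEFAULT_EXPR_LOC,
                                sigma = 2, sample_prefix = "S",
                                seed = 1) {
  loc <- unname(expr_location[as.character(universe$set_label)])
  with_seed(seed, {
    out <- tibble(gene_id = universe$gene_id)
    for (j in seq_len(n_samples)) {
      out[[sprintf("%s%02d", sample_prefix, j)]] <-
        2^rnorm(nrow(universe), mean = loc, sd = sigma)
    }
    set_expr_state(out, "RAW")
  })
}

#' Simulate a hub-biased interactome
#'
#' Growth model: the first `m` nodes form a complete graph; each later node
#' attaches to `m` distinct existing nodes sampled with probability
#' proportional to `(degree + 1) * attractiveness(set)` (the `+1` keeps
#' newly added nodes reachable). The resulting graph is simple with exactly
#' `choose(m, 2) + (n_nodes - m) * m` edges.
#'
#' @param universe Output of [simulate_universe()].
#' @param n_nodes Number of genes to place in the network (sampled from the
#'   universe without replacement); default 500.
#' @param m Edges added per new node; default 2.
#' @param attractiveness Named per-set attachment multipliers.
#' @param seed Integer RNG seed.
#' @return Simple undirected `igraph` with `set_label` vertex attributes.
#' @export
simulate_network <- function(universe, n_nodes = 500, m = 2,
                             attractiveness = DEFAULT_ATTRACT,
                             seed = 1) {
  stopifnot(n_nodes >= 1, m >= 1, n_nodes <= nrow(universe),
            all(attractiveness > 0))
  with_seed(seed, {
    picked <- universe[sample.int(nrow(universe), n_nodes), ]
    att <- unname(attractiveness[as.character(picked$set_label)])
    deg <- integer(n_nodes)
    from <- integer(0); to <- integer(0)
    n0 <- min(m, n_nodes)
    if (n0 >= 2L) {
      init <- utils::combn(seq_len(n0), 2L)
      from <- init[1L, ]; to <- init[2L, ]
      deg[seq_len(n0)] <- n0 - 1L
    }
    if (n_nodes > n0) {
      for (i in (n0 + 1L):n_nodes) {
        existing <- seq_len(i - 1L)
        k <- min(m, length(existing))
        p <- (deg[existing] + 1) * att[existing]
        targets <- sample(existing, k, prob = p)
        from <- c(from, rep.int(i, k)); to <- c(to, targets)
        deg[targets] <- deg[targets] + 1L
        deg[i] <- deg[i] + k
      }
    }
    g <- igraph::graph_from_edgelist(
      cbind(picked$gene_id[from], picked$gene_id[to]), directed = FALSE
    )
    g <- igraph::add_vertices(
      g, sum(!picked$gene_id %in% igraph::V(g)$name),
      name = picked$gene_id[!picked$gene_id %in% igraph::V(g)$name]
    )
    label_network(g, picked)
  })
}

#' Simulate a codon-aligned sequence pair under selection strength omega
#'
#' The ancestral sequence is drawn uniformly over sense codons. In the
#' derived copy, each nucleotide position receives (with probability `t`) a
#' proposed change to a uniform alternative base; synonymous proposals are
#' always accepted, nonsynonymous proposals with probability `omega`, and
#' proposals creating a stop codon never. One proposal round per site keeps
#' the realised divergence close to `t` on synonymous sites and
#' `omega * t` on nonsynonymous sites.
#'
#' @param n_codons Number of codons.
#' @param omega Target dN/dS in `[0, Inf)`.
#' @param t Per-site proposal probability (branch length); default 0.1.
#' @param seed Integer RNG seed.
#' @return List with elements `seq_a` (ancestor) and `seq_b` (derived).
#' @export
simulate_codon_pair <- function(n_codons, omega, t = 0.1, seed = 1) {
  stopifnot(n_codons >= 1, omega >= 0, t >= 0, t <= 1)
  with_seed(seed, {
    anc <- sample(SENSE_CODONS, n_codons, replace = TRUE)
    der <- anc
    hit <- stats::runif(3L * n_codons) < t
    acc <- stats::runif(3L * n_codons)
    pick <- sample.int(3L, 3L * n_codons, replace = TRUE)
    for (idx in which(hit)) {
      ci <- (idx - 1L) %/% 3L + 1L
      pos <- (idx - 1L) %% 3L + 1L
      cur <- der[[ci]]
      alt_base <- setdiff(BASES, substr(cur, pos, pos))[[pick[[idx]]]]
      alt <- cur
      substr(alt, pos, pos) <- alt_base
      if (GENETIC_CODE_DG[[alt]] == "*") next
      syn <- GENETIC_CODE_DG[[alt]] == GENETIC_CODE_DG[[cur]]
      if (syn || acc[[idx]] < omega) der[[ci]] <- alt
    }
    list(seq_a = paste0(anc, collapse = ""),
         seq_b = paste0(der, collapse = ""))
  })
}
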