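# The three set-comparison tests used throughout (two-sided KS, Wilcoxon
# rank-sum, Pearson chi-square) and the all-pairs comparison matrix with
# significance annotation at alpha = 0.05. All p-values come from the base
# stats routines; exact small-sample behaviour is checked against
# exhaustive-permutation oracles in the test suite.

#' Two-sided two-sample Kolmogorov-Smirnov test
#'
#' Exact p-value (network algorithm) when `min(n, m) <= 10` and the data
#' are tie-free; asymptotic otherwise.
#'
#' @param x,y Non-empty numeric vectors.
#' @return One-row tibble (`statistic` = D, `p_value`).
#' @export
ks_compare <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop_dg("KS test requires non-empty samples.", "dualgene_empty_input")
  }
  exact <- min(length(x), length(y)) <= 10
  res <- suppressWarnings(
    ks.test(x, y, alternative = "two.sided",
            exact = if (exact) TRUE else FALSE)
  )
  tibble(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Wilcoxon rank-sum test
#'
#' Exact p-value when `min(n, m) <= 10` and the data are tie-free; normal
#' approximation with tie-corrected variance otherwise. The reported
#' statistic is the rank-sum of `x` (the Mann-Whitney U plus
#' `n(n+1)/2`). Fully tied data return p = 1 with a warning.
#'
#' @param x,y Non-empty numeric vectors.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return One-row tibble (`statistic`, `p_value`).
#' @export
wilcoxon_compare <- function(x, y, alternative = c("two.sided", "greater",
                                                   "less")) {
  alternative <- arg_match(alternative)
  if (length(x) == 0L || length(y) == 0L) {
    stop_dg("Wilcoxon test requires non-empty samples.",
            "dualgene_empty_input")
  }
  n <- length(x)
  rank_sum <- sum(rank(c(x, y))[seq_len(n)])
  if (length(unique(c(x, y))) == 1L) {
    warn("All values tied; Wilcoxon p-value set to 1.")
    return(tibble(statistic = rank_sum, p_value = 1))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 10 && !ties
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact)
  )
  tibble(statistic = rank_sum, p_value = res$p.value)
}

#' Pearson chi-square test of independence
#'
#' No continuity correction (matching an r x c test on count-scale data).
#' The fraction of cells with expected count below 5 is returned so callers
#' can judge the asymptotic approximation.
#'
#' @param tab Matrix (or object coercible to one) of non-negative counts
#'   with positive row and column sums.
#' @return One-row tibble (`statistic` = X-squared, `df`, `p_value`,
#'   `frac_expected_lt5`).
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(rowSums(tab) <= 0) || any(colSums(tab) <= 0)) {
    stop_dg("Chi-square table needs non-negative counts and positive margins.",
            "dualgene_domain_error")
  }
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  frac_low <- mean(res$expected < 5)
  if (frac_low > 0) {
    warn(sprintf("%.0f%% of cells have expected count < 5.",
                 100 * frac_low))
  }
  tibble(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = res$p.value, frac_expected_lt5 = frac_low)
}

#' All-pairs gene-set comparisons
#'
#' Runs the chosen test on every unordered pair of sets and annotates each
#' result with the significant side: when p < alpha, `higher` names the set
#' with the greater mean (the convention used to place significance stars);
#' otherwise `higher` is `NA`. No multiple-testing correction is applied by
#' default; `adjust = "BH"` adds Benjamini-Hochberg adjusted significance.
#'
#' @param data Data frame in long form.
#' @param value Column (tidy-eval) holding the per-gene values.
#' @param set Column (tidy-eval) holding the set labels.
#' @param test `"wilcoxon"` (default) or `"ks"`.
#' @param alpha Significance level; default 0.05.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A `dg_comparisons` tibble: `test`, `set_a`, `set_b`,
#'   `statistic`, `p_value`, `higher`, `significant`.
#' @export
compare_sets <- function(data, value, set, test = c("wilcoxon", "ks"),
                         alpha = 0.05, adjust = c("none", "BH")) {
  test <- arg_match(test)
  adjust <- arg_match(adjust)
  vals <- dplyr::pull(data, {{ value }})
  sets <- as.character(dplyr::pull(data, {{ set }}))
  labels <- unique(sets)
  if (length(labels) < 2L) {
    stop_dg("Need at least two sets to compare.", "dualgene_domain_error")
  }
  pairs <- utils::combn(sort(labels), 2L)
  fn <- if (test == "ks") ks_compare else wilcoxon_compare
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    xa <- vals[sets == a]; xb <- vals[sets == b]
    r <- fn(xa, xb)
    tibble(test = toupper(test), set_a = a, set_b = b,
           statistic = r$statistic, p_value = r$p_value,
           mean_a = mean(xa), mean_b = mean(xb))
  })
  if (adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  }
  out <- out %>%
    mutate(
      significant = .data$p_value < alpha,
      higher = ifelse(.data$significant,
                      ifelse(.data$mean_a >= .data$mean_b,
                             .data$set_a, .data$set_b),
                      NA_character_)
    ) %>%
    select(-"mean_a", -"mean_b")
  class(out) <- c("dg_comparisons", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Tidy a set-comparison table
#'
#' @param x A `dg_comparisons` object.
#' @param ... Unused.
#' @return Plain tibble of the comparison rows.
#' @method tidy dg_comparisons
#' @export
tidy.dg_comparisons <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "dg_comparisons")
  as_tibble(out)
}

#' One-row summary of a set-comparison table
#'
#' @param x A `dg_comparisons` object.
#' @param ... Unused.
#' @return Tibble (`n_comparisons`, `n_significant`, `alpha`).
#' @method glance dg_comparisons
#' @export
glance.dg_comparisons <- function(x, ...) {
  tibble(
    n_comparisons = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha") %||% 0.05
  )
}
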