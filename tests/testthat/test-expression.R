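mk_expr <- function(values, state = "RAW") {
  # values: named list of sample columns
  out <- tibble::tibble(gene_id = sprintf("G%02d", seq_along(values[[1]])))
  for (nm in names(values)) out[[nm]] <- values[[nm]]
  attr(out, "expr_state") <- state
  out
}

test_that("median normalisation scales each sample to unit positive median", {
  m <- mk_expr(list(s1 = c(2, 4, 8)))
  out <- median_normalize(m)
  expect_equal(out$s1, c(0.5, 1, 2))

  # zeros are excluded from the median and stay zero
  m2 <- mk_expr(list(s1 = c(0, 3, 9, 3)))
  out2 <- median_normalize(m2)
  expect_equal(out2$s1, c(0, 1, 3, 1))

  # idempotent
  expect_equal(median_normalize(out2)$s1, out2$s1)

  # rank order preserved on random data
  set.seed(7)
  m3 <- mk_expr(list(a = rlnorm(50), b = rlnorm(50)))
  out3 <- median_normalize(m3)
  expect_equal(order(out3$a), order(m3$a))
  expect_equal(order(out3$b), order(m3$b))
  post_medians <- vapply(c("a", "b"), function(j) {
    median(out3[[j]][m3[[j]] > 0])
  }, numeric(1))
  expect_equal(unname(post_medians), c(1, 1), tolerance = 1e-9)

  # all-zero sample is an error naming the sample
  expect_error(median_normalize(mk_expr(list(bad = c(0, 0)))), "bad")
})

test_that("per-gene cohort means equal brute-force loop means", {
  m <- mk_expr(list(s1 = c(1, 5), s2 = c(3, 7)))
  groups <- tibble::tibble(sample = c("s1", "s2"), cohort = c("K", "K"))
  out <- mean_per_gene(m, groups)
  expect_equal(out$K, c(2, 6))

  # two single-sample cohorts return the samples unchanged
  g2 <- tibble::tibble(sample = c("s1", "s2"), cohort = c("A", "B"))
  out2 <- mean_per_gene(m, g2)
  expect_equal(out2$A, m$s1)
  expect_equal(out2$B, m$s2)

  # 20 x 10 random matrix vs an explicit loop
  set.seed(3)
  vals <- replicate(10, runif(20), simplify = FALSE)
  names(vals) <- sprintf("s%02d", 1:10)
  m3 <- mk_expr(vals)
  g3 <- tibble::tibble(sample = names(vals),
                       cohort = rep(c("C1", "C2"), each = 5))
  out3 <- mean_per_gene(m3, g3)
  for (i in 1:20) {
    expect_equal(out3$C1[i], mean(sapply(1:5, function(j) vals[[j]][i])))
    expect_equal(out3$C2[i], mean(sapply(6:10, function(j) vals[[j]][i])))
  }

  expect_error(mean_per_gene(m, tibble::tibble(sample = "s1",
                                               cohort = "A")),
               "s2")
})

test_that("rpkm follows the reads-per-kb-per-million formula", {
  expect_equal(rpkm(100, 2000, 1e7), 5)
  expect_equal(rpkm(0, 500, 1e6), 0)
  expect_error(rpkm(10, 0, 1e6), "feature_length_bp")
  expect_error(rpkm(10, 100, 0), "total_mapped_reads")
  expect_error(rpkm(-1, 100, 1e6), "read_count")
})

test_that("organ RPKM collapses exons and averages replicates", {
  # gene A: two exons; filler gene makes library sizes controllable
  exon_cov <- tibble::tibble(
    gene_id = rep(c("A", "A", "FILL"), 2),
    exon_id = rep(c("e1", "e2", "f1"), 2),
    exon_length_bp = rep(c(600, 1400, 1000), 2),
    sample = rep(c("s1", "s2"), each = 3),
    read_count = c(40, 60, 999900, 120, 180, 999700)
  )
  so <- tibble::tibble(sample = c("s1", "s2"), organ = "liver")
  out <- organ_rpkm(exon_cov, so)
  # s1: gene A = 100 reads over 2 kb in a 1e6-read library -> RPKM 50
  # s2: 300 reads over 2 kb in 1e6 -> 150; organ mean = 100
  expect_equal(out$liver[out$gene_id == "A"], mean(c(50, 150)))
})

test_that("per-organ Z-scores have exact zero mean and unit sd", {
  # log2 values 1,2,3 standardise to -1,0,1
  m <- mk_expr(list(organ1 = 2^c(1, 2, 3)), state = "LOG2")
  m$organ1 <- c(1, 2, 3) # already log2
  z <- log2_zscore(m)
  expect_equal(z$organ1, c(-1, 0, 1))

  set.seed(11)
  m2 <- mk_expr(list(brain = rlnorm(100), heart = rlnorm(100)),
                state = "RPKM")
  z2 <- log2_zscore(m2)
  for (col in c("brain", "heart")) {
    expect_lt(abs(mean(z2[[col]])), 1e-9)
    expect_lt(abs(sd(z2[[col]]) - 1), 1e-9)
  }

  # idempotence: standardising a Z-scored matrix changes nothing
  expect_equal(log2_zscore(z2)$brain, z2$brain, tolerance = 1e-12)

  # constant column is an error
  expect_error(log2_zscore(mk_expr(list(flat = c(2, 2, 2)))), "flat")
})

test_that("Z-scores are scale invariant for pseudocount zero", {
  set.seed(13)
  m <- mk_expr(list(o1 = rlnorm(60, 2), o2 = rlnorm(60, 1)),
               state = "RPKM")
  m_scaled <- m
  m_scaled$o1 <- m$o1 * 17.3
  m_scaled$o2 <- m$o2 * 17.3
  attr(m_scaled, "expr_state") <- "RPKM"
  z1 <- log2_zscore(m, pseudocount = 0)
  z2 <- log2_zscore(m_scaled, pseudocount = 0)
  expect_equal(z1$o1, z2$o1, tolerance = 1e-12)
  expect_equal(z1$o2, z2$o2, tolerance = 1e-12)
})

test_that("expression matrices round-trip through writer and reader", {
  uni <- simulate_universe(n_genes = c(ONC = 10, TSG = 10), seed = 4)
  m <- simulate_expression(uni, n_samples = 3, seed = 4)
  path <- tempfile(fileext = ".tsv")
  write_expression_matrix(m, path)
  back <- read_expression_matrix(path)
  expect_equal(back$gene_id, m$gene_id)
  expect_equal(back$S01, m$S01, tolerance = 1e-12)
})

test_that("a +1 log2 location shift is detected by one-sided Wilcoxon", {
  uni <- simulate_universe(n_genes = c(ONC = 500, TSG = 500), seed = 31)
  detected <- logical(100)
  for (s in 1:100) {
    m <- simulate_expression(uni, n_samples = 1,
                             expr_location = c(ONC = 6, TSG = 7),
                             sigma = 2, seed = 200 + s)
    vals <- log2(m$S01)
    x_tsg <- vals[uni$set_label == "TSG"]
    x_onc <- vals[uni$set_label == "ONC"]
    detected[s] <- wilcoxon_compare(x_tsg, x_onc,
                                    alternative = "greater")$p_value < 0.05
  }
  expect_gte(sum(detected), 95)
})
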