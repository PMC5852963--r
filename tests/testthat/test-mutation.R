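test_that("MAF dialect tokens map onto the internal vocabulary", {
  maf <- tempfile(fileext = ".maf")
  writeLines(c(
    "Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification\tcohort",
    "TP53\tS1\tMissense_Mutation\tBRCA",
    "KRAS\tS2\tNonsense_Mutation\tBRCA",
    "EGFR\tS1\tSilent\tLUAD"
  ), maf)
  rec <- read_mutation_table(maf)
  expect_equal(nrow(rec), 3L)
  expect_equal(as.character(rec$variant_class),
               c("MISSENSE", "NONSENSE", "SILENT"))
  expect_equal(rec$cohort, c("BRCA", "BRCA", "LUAD"))

  # unmapped token skipped and tallied
  writeLines(c(
    "Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification",
    "TP53\tS1\tTranslation_Start_Site",
    "TP53\tS1\tMissense_Mutation"
  ), maf)
  expect_warning(rec2 <- read_mutation_table(maf, cohort = "GBM"),
                 "unmapped")
  expect_equal(nrow(rec2), 1L)
  expect_equal(attr(rec2, "n_skipped"), 1L)
  expect_equal(rec2$cohort, "GBM")

  # missing required column is an error naming the need
  writeLines(c("gene\tclass", "TP53\tSilent"), maf)
  expect_error(read_mutation_table(maf), "Tumor_Sample_Barcode")
})

test_that("simulated mutation tables round-trip through the reader", {
  uni <- simulate_universe(n_genes = c(POTSF = 20, NCRG = 30), seed = 5)
  rec <- simulate_mutations(uni, tibble::tibble(cohort = "C1",
                                                n_cases = 50L),
                            base_rate = 2e-5, seed = 5)
  expect_gt(nrow(rec), 100)
  path <- tempfile(fileext = ".tsv")
  write_mutation_table(rec, path)
  back <- read_mutation_table(path)
  expect_equal(table(back$variant_class), table(rec$variant_class))
  expect_equal(nrow(back), nrow(rec))
  expect_equal(sort(unique(back$gene_id)), sort(unique(rec$gene_id)))
})

test_that("non-silent filter retains exactly the protein-altering classes", {
  all_mis <- tibble::tibble(variant_class = rep("MISSENSE", 5))
  expect_equal(nrow(filter_non_silent(all_mis)), 5L)
  all_sil <- tibble::tibble(variant_class = rep("SILENT", 5))
  expect_equal(nrow(filter_non_silent(all_sil)), 0L)

  # conservation: retained + removed = input, on random class mixes
  set.seed(1)
  for (rep in 1:5) {
    classes <- sample(c("MISSENSE", "NONSENSE", "SILENT", "RNA",
                        "SPLICE_SITE", "FRAME_SHIFT_DEL"),
                      200, replace = TRUE)
    df <- tibble::tibble(variant_class = classes)
    out <- filter_non_silent(df)
    expect_equal(nrow(out) + attr(out, "n_removed"), 200L)
    expect_false(any(out$variant_class %in% c("SILENT", "RNA")))
    # order preserved
    expect_equal(out$variant_class,
                 classes[!classes %in% c("SILENT", "RNA")])
  }
})

test_that("per-gene counts include zero-count genes and are additive", {
  uni <- toy_universe()
  rec <- tibble::tibble(
    gene_id = c("P1", "P1", "P1", "O1"),
    sample_id = "S1",
    cohort = c("C1", "C1", "C2", "C1"),
    variant_class = "MISSENSE"
  )
  counts <- count_per_gene(rec, uni, scope = "ALL")
  expect_equal(nrow(counts), nrow(uni))
  expect_equal(counts$n[counts$gene_id == "P1"], 3L)
  expect_equal(counts$n[counts$gene_id == "N2"], 0L)
  expect_equal(sum(counts$n), nrow(rec))

  per_cohort <- count_per_gene(rec, uni, scope = "cohort")
  total <- per_cohort |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(n = sum(n))
  expect_equal(dplyr::arrange(total, gene_id)$n,
               dplyr::arrange(counts, gene_id)$n)
})

test_that("generated Poisson counts match their configured mean", {
  # 200 equal-length genes, multiplier 1: expected count per gene
  # base_rate * 1500 bp * 100 cases = 5
  uni <- simulate_universe(n_genes = c(NCRG = 200), length_sdlog = 0,
                           seed = 2)
  expect_true(all(uni$length_bp == 1500L))
  rec <- simulate_mutations(uni, tibble::tibble(cohort = "C1",
                                                n_cases = 100L),
                            base_rate = 5 / (1500 * 100),
                            rate_multiplier = c(NCRG = 1), seed = 2)
  counts <- count_per_gene(rec, uni, scope = "ALL")
  se <- sqrt(5 / 200)
  expect_lt(abs(mean(counts$n) - 5), 3 * se)
})

test_that("mutation rate follows (count / cases) / length exactly", {
  expect_equal(mutation_rate(10, 5, 1000), 0.002)
  expect_equal(mutation_rate(0, 100, 5000), 0)
  # vectorised call equals scalar calls
  tab <- tibble::tibble(n = c(3, 7, 0), cases = c(10, 20, 30),
                        len = c(100, 200, 300))
  expect_equal(mutation_rate(tab$n, tab$cases, tab$len),
               mapply(mutation_rate, tab$n, tab$cases, tab$len))
  # homogeneity
  expect_equal(mutation_rate(20, 5, 1000), 2 * mutation_rate(10, 5, 1000))
  expect_equal(mutation_rate(10, 10, 1000), mutation_rate(10, 5, 1000) / 2)
  expect_equal(mutation_rate(10, 5, 2000), mutation_rate(10, 5, 1000) / 2)
  expect_error(mutation_rate(10, 0, 1000), "n_cases")
  expect_error(mutation_rate(10, 5, -1), "length_bp")
})

test_that("mutation profiles satisfy the rate identity", {
  uni <- toy_universe()
  rec <- simulate_mutations(uni, tibble::tibble(cohort = c("C1", "C2"),
                                                n_cases = c(10L, 20L)),
                            base_rate = 1e-3, seed = 9)
  prof <- mutation_profiles(rec, uni,
                            tibble::tibble(cohort = c("C1", "C2"),
                                           n_cases = c(10L, 20L)))
  expect_true(all(prof$n_nonsilent <= prof$n_total))
  expect_equal(prof$rate, (prof$n_total / prof$n_cases) / prof$length_bp)
  # silent records count in n_total but not n_nonsilent
  n_sil <- sum(rec$variant_class == "SILENT")
  expect_equal(sum(prof$n_total) - sum(prof$n_nonsilent),
               n_sil)
})

test_that("functional-impact classes follow the default mapping", {
  expect_equal(as.character(classify_functional_impact("NONSENSE")),
               "LOF_POTENTIAL")
  expect_equal(as.character(classify_functional_impact("MISSENSE")),
               "GOF_POTENTIAL")
  expect_equal(as.character(classify_functional_impact("SILENT")),
               "EXCLUDED")
  expect_equal(
    as.character(classify_functional_impact(
      c("FRAME_SHIFT_INS", "IN_FRAME_INS", "RNA"))),
    c("LOF_POTENTIAL", "GOF_POTENTIAL", "EXCLUDED")
  )
  # custom map overrides
  m <- c(MISSENSE = "LOF_POTENTIAL")
  expect_equal(as.character(classify_functional_impact("MISSENSE", m)),
               "LOF_POTENTIAL")
  expect_error(classify_functional_impact("SILENT", m), "impact map")
})

test_that("set-specific rate multipliers are recoverable from profiles", {
  uni <- simulate_universe(n_genes = c(POTSF = 200, NCRG = 200), seed = 21)
  cohorts <- tibble::tibble(cohort = "C1", n_cases = 100L)
  ratios <- numeric(20)
  reject <- logical(20)
  for (s in 1:20) {
    rec <- simulate_mutations(uni, cohorts,
                              rate_multiplier = c(POTSF = 3, NCRG = 1),
                              seed = 100 + s)
    prof <- mutation_profiles(rec, uni, cohorts)
    rp <- prof$rate[prof$set_label == "POTSF"]
    rn <- prof$rate[prof$set_label == "NCRG"]
    ratios[s] <- mean(rp) / mean(rn)
    reject[s] <- suppressWarnings(ks_compare(rp, rn)$p_value) < 0.05
  }
  expect_lt(abs(mean(ratios) - 3) / 3, 0.10)
  expect_true(all(reject))
})
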