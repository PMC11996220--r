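test_that("generated cohorts honour the configuration and are deterministic", {
  cfg <- synthetic_config(n_per_class = c(CN = 15, MCI = 20, AD = 10),
                          n_genes = 40, seed = 31)
  d <- generate_cohort(cfg)
  expect_equal(as.integer(table(factor(d$labels, c("CN", "MCI", "AD")))),
               c(15L, 20L, 10L))
  expect_equal(ncol(d$genotype), 40)
  expect_equal(ncol(d$expression), 40)
  expect_equal(ncol(d$clinical), 45)
  expect_equal(rownames(d$genotype), rownames(d$expression))
  # genotype aggregates bounded by twice the mapped variant count
  nv <- table(d$variant_map$gene_symbol)[colnames(d$genotype)]
  expect_true(all(t(d$genotype) <= 2 * as.numeric(nv)))
  expect_true(all(d$genotype >= 0))

  d2 <- generate_cohort(cfg)
  expect_identical(d$genotype, d2$genotype)
  expect_identical(d$expression, d2$expression)
  expect_identical(d$clinical, d2$clinical)
})

test_that("generated moments match the manifest calibration targets", {
  d <- generate_cohort(synthetic_config(n_per_class = c(CN = 150, MCI = 150, AD = 150),
                                        n_genes = 50, effect_size = 0, seed = 32))
  mu <- d$manifest$expression_mean
  sg <- d$manifest$expression_sd
  n <- nrow(d$expression)
  for (j in seq(1, 50, by = 7)) {
    se <- sg[j] / sqrt(n)
    expect_lt(abs(mean(d$expression[, j]) - mu[j]), 3 * se)
    expect_lt(abs(sd(d$expression[, j]) - sg[j]), 3 * sg[j] / sqrt(2 * (n - 1)))
  }
  # with zero effect, genotype means match 2 * sum(MAF) per gene
  maf <- d$manifest$variant_mafs
  for (g in colnames(d$genotype)[1:5]) {
    m_exp <- 2 * sum(maf[d$variant_map$variant_id[d$variant_map$gene_symbol == g]])
    s_g <- sd(d$genotype[, g])
    expect_lt(abs(mean(d$genotype[, g]) - m_exp), 3 * s_g / sqrt(n) + 1e-9)
  }
  # cognitive gradient vanishes at zero effect: MMSE means equal across classes
  p_mmse <- kruskal_wallis_raw(split(d$clinical$MMSE[!is.na(d$clinical$MMSE)],
                                     d$labels[!is.na(d$clinical$MMSE)]))$p
  expect_gt(p_mmse, 0.001)

  # with the default effect, graded features separate strongly
  de <- generate_cohort(synthetic_config(n_per_class = c(CN = 60, MCI = 60, AD = 60),
                                         n_genes = 50, seed = 33))
  expect_true(mean(de$clinical$MMSE[de$labels == "CN"], na.rm = TRUE) >
              mean(de$clinical$MMSE[de$labels == "AD"], na.rm = TRUE))
  planted <- de$manifest$planted_expr[1]
  expect_lt(kruskal_wallis_raw(split(de$expression[, planted], de$labels))$p, 1e-6)
})

test_that("perturbation modifies exactly the drawn subjects within the range", {
  d <- generate_cohort(synthetic_config(n_per_class = c(CN = 212, MCI = 30, AD = 30),
                                        n_genes = 30, missingness = 0, seed = 34))
  gene <- colnames(d$expression)[5]
  spec <- list(feature = gene, modality = "expression",
               reduction = c(0.2, 0.3), fraction = 0.5, pool = "CN")
  dp <- perturb_features(d, list(spec), seed = 2)
  ratio <- dp$expression[, gene] / d$expression[, gene]
  changed <- which(abs(ratio - 1) > 1e-12)
  expect_length(changed, 106)                       # round(0.5 * 212)
  expect_true(all(d$labels[changed] == "CN"))
  expect_true(all(ratio[changed] >= 0.70 - 1e-12 & ratio[changed] <= 0.80 + 1e-12))
  expect_equal(dp$perturbation_log$n_modified, 106)

  # empty spec list leaves the dataset bitwise unchanged
  d0 <- perturb_features(d, list(), seed = 2)
  expect_identical(d0$expression, d$expression)
  expect_identical(d0$genotype, d$genotype)

  expect_warning(
    perturb_features(d, list(spec, spec), seed = 2), "overlapping")
  expect_error(
    perturb_features(d, list(list(feature = "nope", modality = "expression",
                                  reduction = c(0.2, 0.3))), seed = 1),
    "unknown expression gene")
})

test_that("KS preservation check matches a brute-force ECDF supremum scan", {
  x <- c(1, 2, 3, 4, 5)
  same <- ks_preservation_check(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_true(same$preserved)

  disj <- ks_preservation_check(1:50, 101:150)
  expect_equal(disj$statistic, 1)
  expect_false(disj$preserved)

  set.seed(36)
  a <- rnorm(500)
  b <- a * (1 + runif(500, -0.1, 0.1))
  res <- ks_preservation_check(a, b)
  grid <- sort(c(a, b))
  sup <- max(abs(vapply(grid, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
  expect_equal(res$statistic, sup, tolerance = 1e-12)
})

test_that("cohort files round-trip through the writers and readers", {
  d <- generate_cohort(synthetic_config(n_per_class = c(CN = 8, MCI = 8, AD = 8),
                                        n_genes = 15, seed = 37))
  dir <- withr::local_tempdir()
  write_cohort(d, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "genotype_calls.tsv", "variant_map.tsv", "expression.tsv", "clinical.csv",
    "labels.csv", "pathways.gmt", "relations.tsv", "manifest.json")))))
  d2 <- read_cohort(dir)
  expect_equal(unclass(d2$genotype), unclass(d$genotype),
               ignore_attr = "dropped_variants", tolerance = 1e-12)
  expect_equal(d2$expression, d$expression, tolerance = 1e-12)
  expect_equal(d2$labels, d$labels)
  expect_equal(nrow(d2$hierarchy$edges), nrow(d$hierarchy$edges))
  expect_equal(d2$manifest$planted_snp, d$manifest$planted_snp)
})

test_that("perturbing planted features does not hurt the planted-signal model", {
  d <- small_cohort(seed = 38, n = c(CN = 40, MCI = 40, AD = 30), n_genes = 40)
  specs <- list(
    list(feature = d$manifest$planted_snp[1], modality = "snp",
         reduction = c(0.2, 0.3), fraction = 0.5, pool = "CN"),
    list(feature = d$manifest$planted_expr[1], modality = "expression",
         reduction = c(0.2, 0.3), fraction = 0.5, pool = "CN"))
  res <- simulated_validation_run(d, specs, triadem_config(seed = 4, max_epochs = 30))
  expect_equal(nrow(res$ks_table), 2)               # one row per perturbed feature
  expect_gte(res$after$macro$AUC, res$before$macro$AUC - 0.05)
  # identical seeds with no perturbation reproduce identical metrics
  res0 <- simulated_validation_run(d, list(), triadem_config(seed = 4, max_epochs = 30))
  expect_identical(res0$before$confusion, res0$after$confusion)
  expect_equal(res0$delta$macro_AUC, 0)
})
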