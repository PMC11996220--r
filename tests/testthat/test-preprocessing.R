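test_that("additive codes aggregate per gene, with missing treated as no signal", {
  calls <- matrix(c(1, 2, 0), 1, 3,
                  dimnames = list("s1", c("v1", "v2", "v3")))
  map <- data.frame(variant_id = c("v1", "v2", "v3"),
                    gene_symbol = c("gA", "gA", "gA"))
  expect_equal(unname(encode_snps(calls, map)[1, "gA"]), 3)

  zero <- matrix(0, 2, 3, dimnames = list(c("s1", "s2"), c("v1", "v2", "v3")))
  expect_true(all(encode_snps(zero, map) == 0))

  withna <- calls; withna[1, 2] <- NA
  expect_equal(unname(encode_snps(withna, map)[1, "gA"]), 1)

  bad <- calls; bad[1, 1] <- 3
  expect_error(encode_snps(bad, map), "sample 's1', variant 'v1'")

  # unmapped variants are dropped and reported
  map2 <- map[1:2, ]
  g <- encode_snps(calls, map2)
  expect_equal(attr(g, "dropped_variants"), "v3")

  # random 20 x 50 call set against an explicit per-gene loop
  set.seed(1)
  calls50 <- matrix(sample(0:2, 20 * 50, TRUE), 20, 50,
                    dimnames = list(paste0("s", 1:20), paste0("v", 1:50)))
  map50 <- data.frame(variant_id = paste0("v", 1:50),
                      gene_symbol = paste0("g", rep(1:10, each = 5)))
  g50 <- encode_snps(calls50, map50)
  for (gene in unique(map50$gene_symbol)) {
    vs <- map50$variant_id[map50$gene_symbol == gene]
    expect_equal(unname(g50[, gene]), unname(rowSums(calls50[, vs])))
  }
  expect_equal(unname(encode_snps(calls50, map50, aggregate = "mean")[, "g1"]),
               unname(rowMeans(calls50[, map50$variant_id[map50$gene_symbol == "g1"]])))
})

test_that("PLINK text tables parse with line-numbered errors", {
  bim <- withr::local_tempfile(lines = c(
    "1 rs101 0 1000 A G", "2 rs102 0 2000 C T", "19 rs103 0 45000 G A"))
  fam <- withr::local_tempfile(lines = "F1 S1 0 0 1 2")
  p <- parse_plink_text(bim, fam)
  expect_equal(p$variants$variant_id, c("rs101", "rs102", "rs103"))
  expect_equal(p$variants$position, c(1000L, 2000L, 45000L))
  expect_equal(p$samples$sample_id, "S1")

  empty <- withr::local_tempfile(lines = character(0))
  p0 <- parse_plink_text(empty, empty)
  expect_equal(nrow(p0$variants), 0)
  expect_equal(nrow(p0$samples), 0)

  bad <- withr::local_tempfile(lines = c("1 rs1 0 10 A G", "1 rs2 0 20 A"))
  expect_error(parse_plink_text(bad, fam), "line 2")

  # generated .bim against its manifest
  ids <- sprintf("rs%04d", sample(1e4, 500))
  gen <- withr::local_tempfile(
    lines = sprintf("%d %s 0 %d A C", sample(22, 500, TRUE), ids, seq_len(500)))
  pg <- parse_plink_text(gen, fam)
  expect_equal(nrow(pg$variants), 500)
  expect_setequal(pg$variants$variant_id, ids)
})

test_that("sparse clinical features are dropped on training missingness", {
  set.seed(2)
  tab <- data.frame(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  tab$a[1:14] <- NA                     # 70% missing
  out <- drop_sparse_features(tab, max_missing = 0.60)
  expect_equal(names(out), c("b", "c"))
  expect_equal(attr(out, "dropped_features"), "a")

  # missingness measured on training rows only
  tab2 <- data.frame(a = c(rep(NA, 5), rnorm(15)))
  expect_error(drop_sparse_features(tab2, train_idx = 1:5), "all clinical")
  expect_equal(names(drop_sparse_features(tab2, train_idx = 6:20)), "a")

  # random missingness pattern equals a brute-force fraction filter
  tabr <- as.data.frame(matrix(rnorm(200), 20))
  for (j in 1:10) tabr[sample(20, sample(0:18, 1)), j] <- NA
  kept <- names(drop_sparse_features(tabr))
  frac <- vapply(tabr, function(x) mean(is.na(x)), numeric(1))
  expect_setequal(kept, names(frac)[frac < 0.60])
})

test_that("kNN imputation reproduces hand-computed and brute-force neighbours", {
  full <- data.frame(x = rnorm(6), y = rnorm(6))
  expect_equal(knn_impute(full, k = 5)$train, full)

  # 6-row toy: row 6 missing y; its 5 neighbours hold (1,1,1,3,4) -> mean 2
  toy <- data.frame(x = c(0, 0, 0, 0, 0, 0.001),
                    y = c(1, 1, 1, 3, 4, NA))
  imp <- knn_impute(toy, k = 5, weighted = FALSE)$train
  expect_equal(imp$y[6], 2)

  allna <- data.frame(x = c(1, NA), y = c(1, NA))
  rownames(allna) <- c("r1", "r2")
  expect_error(knn_impute(allna, k = 1), "r2")

  # random 50 x 8 with 10% missing against an all-pairs distance oracle
  set.seed(4)
  tab <- as.data.frame(matrix(rnorm(400), 50))
  mask <- matrix(runif(400) < 0.10, 50)
  mask[rowSums(mask) == 8, 1] <- FALSE
  tab[mask] <- NA
  imp <- knn_impute(tab, k = 5)$train
  mu <- vapply(tab, function(x) mean(x, na.rm = TRUE), numeric(1))
  sg <- vapply(tab, function(x) sd(x, na.rm = TRUE), numeric(1))
  z <- sweep(sweep(data.matrix(tab), 2, mu, "-"), 2, sg, "/")
  for (i in which(rowSums(mask) > 0)) {
    d <- sapply(seq_len(50), function(r) {
      obs <- !is.na(z[i, ]) & !is.na(z[r, ])
      if (!any(obs)) return(Inf)
      sqrt(sum((z[i, obs] - z[r, obs])^2) * 8 / sum(obs))
    })
    d[i] <- Inf
    for (j in which(mask[i, ])) {
      nb <- order(d)[1:5]
      ok <- !is.na(tab[nb, j])
      w <- (1 / pmax(d[nb], .Machine$double.eps))[ok]
      expect_equal(imp[i, j], sum(w * tab[nb[ok], j]) / sum(w))
    }
  }
})

test_that("stratified split hits 56/14/30 within one sample per class", {
  lab <- rep(c("CN", "MCI", "AD"), each = 100)
  sp <- split_stratified(lab, seed = 1)
  for (cl in c("CN", "MCI", "AD")) {
    counts <- table(sp[lab == cl])
    expect_equal(as.integer(counts[c("train", "validation", "test")]),
                 c(56L, 14L, 30L))
  }

  lab2 <- rep(c("CN", "MCI", "AD"), times = c(212, 317, 97))
  sp2 <- split_stratified(lab2, seed = 2)
  sizes <- table(sp2)
  expect_lte(abs(sizes[["train"]] - 350), 2)
  expect_lte(abs(sizes[["validation"]] - 88), 2)
  expect_lte(abs(sizes[["test"]] - 188), 2)
  # per-class proportions within one sample of the global fractions
  for (cl in c("CN", "MCI", "AD")) {
    n <- sum(lab2 == cl)
    expect_lte(abs(sum(sp2 == "test" & lab2 == cl) - 0.30 * n), 1)
    expect_lte(abs(sum(sp2 == "validation" & lab2 == cl) - 0.14 * n), 1)
  }
  expect_identical(sp2, split_stratified(lab2, seed = 2))
  expect_false(identical(sp2, split_stratified(lab2, seed = 3)))
  expect_error(split_stratified(c("CN", "CN", "MCI", "MCI", "AD")), "fewer than 3")
})

test_that("SMOTE equalises class counts with convex synthetic rows", {
  set.seed(5)
  x <- matrix(rnorm(30 * 4), 30)
  lab <- rep(c("CN", "MCI", "AD"), each = 10)
  same <- smote_balance(x, lab, seed = 1)
  expect_equal(nrow(same$x), 30)
  expect_false(any(same$synthetic))

  x2 <- matrix(rnorm(60 * 4), 60)
  lab2 <- rep(c("CN", "MCI", "AD"), times = c(30, 20, 10))
  bal <- smote_balance(x2, lab2, seed = 1)
  expect_equal(as.integer(table(bal$labels)), c(30L, 30L, 30L))

  # every synthetic row lies on a segment between two real same-class rows
  for (r in which(bal$synthetic)) {
    cl <- bal$labels[r]
    rows <- x2[lab2 == cl, , drop = FALSE]
    on_segment <- FALSE
    for (a in seq_len(nrow(rows))) for (b in seq_len(nrow(rows))) {
      if (a == b) next
      dir <- rows[b, ] - rows[a, ]
      tvals <- (bal$x[r, ] - rows[a, ]) / dir
      t1 <- tvals[is.finite(tvals)][1]
      if (!is.na(t1) && t1 >= 0 && t1 <= 1 &&
          max(abs(rows[a, ] + t1 * dir - bal$x[r, ])) < 1e-8) {
        on_segment <- TRUE; break
      }
    }
    expect_true(on_segment)
  }
  expect_warning(smote_balance(x2[c(1:30, 31:50, 51:54), ],
                               lab2[c(1:30, 31:50, 51:54)], seed = 1),
                 "k reduced")
})

test_that("min-max scaling fits on train and transfers unclipped", {
  tr <- cbind(a = c(2, 4, 6), b = c(5, 5, 5))
  out <- minmax_scale(tr, list(test = cbind(a = 8, b = 7)))
  expect_equal(unname(out$train[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(out$train[, "b"]), c(0, 0, 0))      # constant maps to 0
  expect_equal(unname(out$test[1, "a"]), 1.5)             # (8-2)/(6-2), unclipped
})

test_that("one-hot labels round-trip through argmax", {
  expect_equal(unname(one_hot_labels("AD")[1, ]), c(0, 0, 1))
  expect_equal(unname(one_hot_labels("CN")[1, ]), c(1, 0, 0))
  lab <- c("MCI", "AD", "CN", "CN", "MCI")
  oh <- one_hot_labels(lab)
  expect_true(all(rowSums(oh) == 1))
  expect_equal(c("CN", "MCI", "AD")[max.col(oh)], lab)
  expect_error(one_hot_labels("DEM"), "unknown label")
})

test_that("pipeline keeps blocks aligned and leaks nothing from held-out rows", {
  d <- small_cohort(seed = 8, effect = 1)
  pr <- preprocess_cohort(d$genotype, d$expression, d$clinical, d$labels,
                          categorical = d$manifest$categorical, seed = 4)
  # training features all within [0,1]; ranges recomputed from the train block
  expect_true(all(pr$train$x >= 0 & pr$train$x <= 1))
  # scaling ranges must be reproducible from training rows alone:
  # train maxima hit 1 and minima hit 0 for non-constant features
  nonconst <- apply(pr$train$x, 2, function(v) max(v) > min(v))
  expect_true(all(abs(apply(pr$train$x[, nonconst], 2, max) - 1) < 1e-12))
  expect_true(all(abs(apply(pr$train$x[, nonconst], 2, min)) < 1e-12))
  # every split contains all classes, fractions near 56/14/30
  for (s in c("train", "validation", "test")) {
    expect_setequal(unique(pr[[s]]$labels), c("CN", "MCI", "AD"))
  }
  # SMOTE balanced the training classes
  expect_equal(length(unique(table(pr$train$labels))), 1L)
  # block alignment: concatenated width equals the sum of the three blocks
  expect_equal(ncol(pr$train$x), sum(pr$widths))
  bl <- split_blocks(pr$test$x, pr$widths)
  expect_equal(ncol(bl$genotype), ncol(d$genotype))
  expect_equal(ncol(bl$expression), ncol(d$expression))
})
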