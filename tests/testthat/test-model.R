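# Layer-walk parameter count oracle, independent of count_parameters().
oracle_counts <- function(mask_nonzeros, C, h1 = 19, h2 = 8, k = 3,
                          dense_subnets = FALSE, subnet_dense_n = 0) {
  head_tr <- 2 * C + (C + 1) * h1 + (h1 + 1) * h2 + (h2 + 1) * k
  if (dense_subnets) {
    list(trainable = head_tr + subnet_dense_n, non_trainable = 2 * C)
  } else {
    list(trainable = head_tr, non_trainable = 2 * C + mask_nonzeros)
  }
}

test_that("masked forward pass equals the explicit matrix product", {
  m <- toy_masks()
  cfg <- triadem_config(seed = 1)
  model <- build_model(m, m, n_clinical = 2, cfg)
  x <- matrix(c(1, 0.5, 0.25, 1, 0.5, 0.25, 0.3, 0.7), 1)
  # subnetwork output = x . M1 . M2 . M3 under identity activation
  sub <- capture_activations(model, x, "snp", level = 3)
  expect_equal(unname(sub[1, 1]), 1.75)
  prod <- x[, 1:3, drop = FALSE] %*% m$masks[[1]] %*% m$masks[[2]] %*% m$masks[[3]]
  expect_equal(unname(sub), unname(prod))

  zero <- matrix(0, 1, 8)
  expect_true(all(capture_activations(model, zero, "expr", 3) == 0))

  probs <- predict(model, x)
  expect_equal(unname(rowSums(probs)), 1, tolerance = 1e-6)
  expect_error(build_model(m, m, 2, triadem_config(depth = 2)), "depth")
})

test_that("parameter counts equal a layer-walk enumeration", {
  m <- toy_masks()
  model <- build_model(m, m, n_clinical = 2, triadem_config())
  pc <- count_parameters(model)
  C <- 1 + 1 + 2                     # two 1-node subnetwork tops + clinical
  o <- oracle_counts(mask_nonzeros = 6 + 6, C = C)
  expect_equal(pc$trainable, o$trainable)
  expect_equal(pc$non_trainable, o$non_trainable)
  expect_equal(pc$total, pc$trainable + pc$non_trainable)
  expect_equal(pc$layer_count, 15)   # 3 inputs + 2x3 pathway layers + head

  # doubling clinical width adds 2 gamma/beta + 19 first-dense weights per column
  model4 <- build_model(m, m, n_clinical = 4, triadem_config())
  expect_equal(count_parameters(model4)$trainable - pc$trainable, 2 * 2 + 19 * 2)

  base <- build_unconstrained_baseline(m, m, 2, triadem_config())
  pb <- count_parameters(base)
  dense_n <- 2 * (3 * 2 + 2 * 1 + 1 * 1)     # full dense subnet weights
  ob <- oracle_counts(0, C, dense_subnets = TRUE, subnet_dense_n = dense_n)
  expect_equal(pb$trainable, ob$trainable)
  expect_gt(pb$trainable, pc$trainable)
})

test_that("training fits separable data, freezes masks, and follows the schedule", {
  fit <- small_fit()
  model <- fit$model

  # frozen-constraint invariance: weights bitwise equal to masks after training
  expect_identical(model$subnet$snp, fit$masks$masks)
  expect_identical(model$subnet$expr, fit$masks$masks)

  # learning-rate schedule: 0.008 * 0.96^floor(t/17) at probed steps
  lr <- attr(model$history, "lr_steps")
  expect_equal(lr[1], 0.008)                    # step 0
  expect_equal(lr[18], 0.008 * 0.96)            # step 17
  expect_equal(lr[35], 0.008 * 0.96^2)          # step 34

  # a linearly separable cohort is fit to training accuracy 1.0
  m <- toy_masks()
  set.seed(10)
  lab <- rep(c("CN", "MCI", "AD"), each = 20)
  x <- cbind(matrix(runif(60 * 6), 60), (match(lab, c("CN", "MCI", "AD")) - 1) / 2,
             runif(60))
  sep <- list(train = list(x = x, y = one_hot_labels(lab), labels = lab),
              validation = list(x = x, y = one_hot_labels(lab), labels = lab))
  sm <- build_model(m, m, 2, triadem_config(seed = 3, dropout_rate = 0.1))
  sm <- train_triadem(sm, sep)
  probs <- predict(sm, x)
  expect_equal(mean(c("CN", "MCI", "AD")[max.col(probs)] == lab), 1.0)

  # all-constant features: validation loss plateaus and early stopping fires
  xc <- matrix(0.5, 60, 8)
  con <- list(train = list(x = xc, y = one_hot_labels(lab), labels = lab),
              validation = list(x = xc, y = one_hot_labels(lab), labels = lab))
  cm <- train_triadem(build_model(m, m, 2, triadem_config(seed = 3)), con)
  expect_lt(nrow(cm$history), cm$cfg$max_epochs)
  expect_true(attr(cm$history, "stopped_early"))
})

test_that("training is deterministic under a fixed seed", {
  d <- small_cohort(seed = 21, n = c(CN = 20, MCI = 20, AD = 20), n_genes = 30)
  cfg <- triadem_config(seed = 5, max_epochs = 15)
  r1 <- run_pipeline(d, cfg)
  r2 <- run_pipeline(d, cfg)
  expect_identical(tail(r1$model$history$val_loss, 1),
                   tail(r2$model$history$val_loss, 1))
  expect_identical(r1$model$params, r2$model$params)
})

test_that("metric computation matches hand-counted contingencies", {
  lab <- rep("CN", 30)
  probs <- one_hot_labels(lab) + 0
  r <- metrics_report(lab, probs + matrix(c(0.0), 30, 3))
  expect_equal(r$accuracy, 1.0)

  # confusion rows CN(8,2,0), MCI(1,7,2), AD(0,1,9)
  truth <- rep(c("CN", "MCI", "AD"), each = 10)
  pred <- c(rep("CN", 8), rep("MCI", 2),
            "CN", rep("MCI", 7), rep("AD", 2),
            "MCI", rep("AD", 9))
  probs <- one_hot_labels(pred) * 0.9 + 0.05
  r <- metrics_report(truth, probs)
  ad <- r$per_class[r$per_class$class == "AD", ]
  expect_equal(ad$TP, 9); expect_equal(ad$FP, 2); expect_equal(ad$FN, 1)
  expect_equal(ad$precision, 9 / 11)
  expect_equal(ad$recall, 0.9)
  expect_equal(ad$F1, 2 * (9 / 11 * 0.9) / (9 / 11 + 0.9))
  # micro accuracy = trace / n; recall x support sums back to the trace
  expect_equal(r$accuracy, sum(diag(r$confusion)) / 30)
  support <- rowSums(r$confusion)
  expect_equal(sum(r$per_class$recall * support), sum(diag(r$confusion)))
})

test_that("one-vs-rest AUC is near 1/2 under uniform random scores", {
  set.seed(77)
  n <- 3000
  lab <- rep(c("CN", "MCI", "AD"), each = n / 3)
  scores <- matrix(runif(3 * n), n, 3, dimnames = list(NULL, c("CN", "MCI", "AD")))
  scores <- scores / rowSums(scores)
  r <- metrics_report(lab, scores)
  for (auc in r$per_class$AUC) expect_lt(abs(auc - 0.5), 0.05)
})

test_that("baseline and constrained models both learn a planted signal", {
  fit <- small_fit()
  expect_gt(fit$metrics$macro$AUC, 0.8)
  base <- run_pipeline(fit$cohort, triadem_config(seed = 2, max_epochs = 40),
                       constrained = FALSE, masks = fit$masks,
                       processed = fit$processed)
  expect_gt(base$metrics$macro$AUC, 0.8)
  # baseline subnetworks actually moved away from initialisation
  expect_false(identical(base$model$subnet$snp[[1]], fit$masks$masks[[1]]))
})
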