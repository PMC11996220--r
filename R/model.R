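# The constrained triple-input classifier.
#
# Two sparse subnetworks (genotype and expression) carry frozen binary
# weights equal to their connectivity masks, so a forward pass through a
# subnetwork under identity activation is the cumulative masked matrix
# product x %*% M1 %*% ... %*% ML. Their top-level pathway outputs are
# concatenated with the clinical block and passed through a trainable head:
# batch normalization -> dense(19, linear, L2) -> dropout -> dense(8, ReLU,
# L2) -> dense(3, softmax). Only the head (and batch-norm scale/shift)
# trains; the optimizer is Adam with a staircase exponential learning-rate
# schedule and early stopping on validation loss.

#' Model and training configuration with the published defaults
#'
#' @param depth Pathway levels per subnetwork (default 3).
#' @param subnetwork_activation `"identity"` (pathway node = sum of its
#'   constrained inputs, default) or `"tanh"`.
#' @param hidden1_size,hidden2_size Fusion head widths (19 linear, 8 ReLU).
#' @param dropout_rate Dropout between the two head layers (0.597).
#' @param l2 Kernel regularization coefficient on both head hidden layers.
#' @param learning_rate Initial Adam learning rate (0.008).
#' @param decay_rate,decay_steps Staircase exponential decay: the rate at
#'   update step t is `learning_rate * decay_rate^floor(t / decay_steps)`
#'   (0.96 every 17 steps).
#' @param batch_size Mini-batch size (32).
#' @param max_epochs Epoch cap (120).
#' @param patience Early-stopping patience on validation loss, with
#'   best-weight restoration (10).
#' @param bn_momentum Batch-norm moving-statistics momentum.
#' @param seed Integer seed for initialisation, shuffling and dropout.
#' @return A `TriademConfig` list.
#' @export
triadem_config <- function(depth = 3L, subnetwork_activation = c("identity", "tanh"),
                           hidden1_size = 19L, hidden2_size = 8L,
                           dropout_rate = 0.597, l2 = 0.01,
                           learning_rate = 0.008, decay_rate = 0.96,
                           decay_steps = 17L, batch_size = 32L,
                           max_epochs = 120L, patience = 10L,
                           bn_momentum = 0.99, seed = 1L) {
  subnetwork_activation <- match.arg(subnetwork_activation)
  stopifnot(dropout_rate >= 0, dropout_rate < 1, learning_rate > 0,
            depth >= 1L, decay_steps >= 1L)
  structure(list(depth = as.integer(depth),
                 subnetwork_activation = subnetwork_activation,
                 hidden1_size = as.integer(hidden1_size),
                 hidden2_size = as.integer(hidden2_size),
                 dropout_rate = dropout_rate, l2 = l2,
                 learning_rate = learning_rate, decay_rate = decay_rate,
                 decay_steps = as.integer(decay_steps),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 bn_momentum = bn_momentum, seed = as.integer(seed)),
            class = "TriademConfig")
}

# Glorot-uniform init, limit sqrt(6/(fan_in+fan_out)).
.glorot <- function(rng, n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(rng$runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Assemble the constrained triple-input model
#'
#' @param mask_snp,mask_expr `MaskStack`s for the genotype and expression
#'   subnetworks; both must have `cfg$depth` layers.
#' @param n_clinical Width of the clinical input block.
#' @param cfg A `TriademConfig`.
#' @return An untrained `TriademModel`.
#' @export
build_model <- function(mask_snp, mask_expr, n_clinical, cfg = triadem_config()) {
  stopifnot(inherits(mask_snp, "MaskStack"), inherits(mask_expr, "MaskStack"),
            n_clinical >= 1L)
  if (length(mask_snp$masks) != cfg$depth || length(mask_expr$masks) != cfg$depth) {
    stop("mask depth (", length(mask_snp$masks), "/", length(mask_expr$masks),
         ") does not match configured depth ", cfg$depth)
  }
  .new_model(list(snp = mask_snp$masks, expr = mask_expr$masks),
             mask_snp, mask_expr, n_clinical, cfg, trainable_subnets = FALSE)
}

#' Unconstrained dense baseline with the same layer shapes
#'
#' Identical architecture to [build_model()] but every subnetwork weight is
#' dense and trainable (initialised Glorot-uniform). Used only for
#' comparison runs against the constrained model.
#'
#' @inheritParams build_model
#' @return An untrained `TriademModel` with `trainable_subnets = TRUE`.
#' @export
build_unconstrained_baseline <- function(mask_snp, mask_expr, n_clinical,
                                         cfg = triadem_config()) {
  stopifnot(inherits(mask_snp, "MaskStack"), inherits(mask_expr, "MaskStack"))
  if (length(mask_snp$masks) != cfg$depth || length(mask_expr$masks) != cfg$depth) {
    stop("mask depth does not match configured depth ", cfg$depth)
  }
  rng <- .seeded_rng(cfg$seed + 7L)
  dense_like <- function(masks) lapply(masks, function(m) {
    w <- .glorot(rng, nrow(m), ncol(m)); dimnames(w) <- dimnames(m); w
  })
  .new_model(list(snp = dense_like(mask_snp$masks),
                  expr = dense_like(mask_expr$masks)),
             mask_snp, mask_expr, n_clinical, cfg, trainable_subnets = TRUE)
}

.new_model <- function(subnet_weights, mask_snp, mask_expr, n_clinical, cfg,
                       trainable_subnets) {
  top_snp <- ncol(mask_snp$masks[[cfg$depth]])
  top_expr <- ncol(mask_expr$masks[[cfg$depth]])
  C <- top_snp + top_expr + n_clinical
  rng <- .seeded_rng(cfg$seed)
  params <- list(
    gamma = rep(1, C), beta = rep(0, C),
    W1 = .glorot(rng, C, cfg$hidden1_size), b1 = rep(0, cfg$hidden1_size),
    W2 = .glorot(rng, cfg$hidden1_size, cfg$hidden2_size), b2 = rep(0, cfg$hidden2_size),
    W3 = .glorot(rng, cfg$hidden2_size, 3L), b3 = rep(0, 3L))
  structure(list(
    subnet = subnet_weights,
    mask_snp = mask_snp, mask_expr = mask_expr,
    widths = c(genotype = nrow(mask_snp$masks[[1]]),
               expression = nrow(mask_expr$masks[[1]]),
               clinical = as.integer(n_clinical)),
    concat_width = C, params = params,
    moving_mean = rep(0, C), moving_var = rep(0, C), bn_steps = 0L,
    cfg = cfg, trainable_subnets = trainable_subnets,
    trained = FALSE, history = NULL), class = "TriademModel")
}

# Forward pass through one subnetwork, keeping per-level activations.
.subnet_forward <- function(weights, x, activation) {
  acts <- vector("list", length(weights))
  h <- x
  for (l in seq_along(weights)) {
    h <- h %*% weights[[l]]
    if (activation == "tanh") h <- tanh(h)
    acts[[l]] <- h
  }
  list(out = h, acts = acts)
}

# Full forward pass. training=TRUE uses batch statistics for BN and applies
# inverted dropout with the supplied mask. Returns all caches needed for
# backprop.
.forward <- function(model, x, training = FALSE, drop_mask = NULL) {
  bl <- split_blocks(x, model$widths)
  act <- model$cfg$subnetwork_activation
  s1 <- .subnet_forward(model$subnet$snp, bl$genotype, act)
  s2 <- .subnet_forward(model$subnet$expr, bl$expression, act)
  z0 <- cbind(s1$out, s2$out, bl$clinical)
  eps <- 1e-3
  if (training) {
    mu <- colMeans(z0)
    va <- colMeans(sweep(z0, 2, mu, "-")^2)   # biased batch variance
  } else if (model$bn_steps > 0L) {
    # bias-corrected exponential moving averages of the batch statistics,
    # so inference normalisation is sane even after few update steps
    corr <- 1 - model$cfg$bn_momentum^model$bn_steps
    mu <- model$moving_mean / corr
    va <- model$moving_var / corr
  } else {
    mu <- rep(0, ncol(z0))
    va <- rep(1, ncol(z0))
  }
  xhat <- sweep(sweep(z0, 2, mu, "-"), 2, sqrt(va + eps), "/")
  z1 <- sweep(sweep(xhat, 2, model$params$gamma, "*"), 2, model$params$beta, "+")
  a1 <- sweep(z1 %*% model$params$W1, 2, model$params$b1, "+")
  d1 <- a1
  if (training && model$cfg$dropout_rate > 0) {
    d1 <- a1 * drop_mask / (1 - model$cfg$dropout_rate)
  }
  pre2 <- sweep(d1 %*% model$params$W2, 2, model$params$b2, "+")
  a2 <- pmax(pre2, 0)
  logits <- sweep(a2 %*% model$params$W3, 2, model$params$b3, "+")
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  colnames(probs) <- .CLASS_ORDER
  list(probs = probs, bl = bl, s1 = s1, s2 = s2, z0 = z0, mu = mu, va = va,
       eps = eps, xhat = xhat, z1 = z1, a1 = a1, d1 = d1, pre2 = pre2,
       a2 = a2)
}

#' Class-probability predictions
#' @param object A `TriademModel`.
#' @param newdata Concatenated feature matrix (genotype | expression | clinical).
#' @param ... Unused.
#' @return n x 3 softmax probability matrix (CN, MCI, AD).
#' @export
predict.TriademModel <- function(object, newdata, ...) {
  .forward(object, newdata, training = FALSE)$probs
}

#' Parameter counts by exhaustive layer walk
#'
#' Non-trainable parameters are the subnetwork weights (mask nonzeros for
#' the constrained model, all entries for the dense baseline counted as
#' trainable instead) plus the batch-norm moving statistics; trainable
#' parameters are batch-norm scale/shift and the three head dense layers.
#'
#' @param m A `TriademModel`.
#' @return List with `trainable`, `non_trainable`, `total`, `layer_count`,
#'   and a per-subnetwork breakdown `subnet_parameters`.
#' @export
count_parameters <- function(m) {
  stopifnot(inherits(m, "TriademModel"))
  subnet_n <- vapply(m$subnet, function(ws) sum(vapply(ws, function(w)
    if (m$trainable_subnets) length(w) else sum(w != 0), numeric(1))), numeric(1))
  C <- m$concat_width
  head_tr <- 2 * C +                                  # batch-norm gamma/beta
    (C + 1) * m$cfg$hidden1_size +
    (m$cfg$hidden1_size + 1) * m$cfg$hidden2_size +
    (m$cfg$hidden2_size + 1) * 3
  bn_moving <- 2 * C
  if (m$trainable_subnets) {
    trainable <- head_tr + sum(subnet_n)
    non_trainable <- bn_moving
  } else {
    trainable <- head_tr
    non_trainable <- bn_moving + sum(subnet_n)
  }
  # 3 inputs + depth layers per subnetwork + concat + BN + dense + dropout +
  # dense + dense
  layer_count <- 3L + 2L * m$cfg$depth + 6L
  list(trainable = trainable, non_trainable = non_trainable,
       total = trainable + non_trainable, layer_count = layer_count,
       subnet_parameters = subnet_n)
}

#' @export
print.TriademModel <- function(x, ...) {
  pc <- count_parameters(x)
  cat("TriademModel (", if (x$trainable_subnets) "unconstrained baseline" else "constrained",
      "): inputs ", paste(x$widths, collapse = "+"),
      " -> concat ", x$concat_width,
      "; trainable ", pc$trainable, ", non-trainable ", pc$non_trainable,
      ", layers ", pc$layer_count,
      if (x$trained) "; trained" else "; untrained", "\n", sep = "")
  invisible(x)
}

# categorical cross-entropy + L2 penalty on head hidden kernels
.loss <- function(model, probs, y) {
  ce <- -mean(rowSums(y * log(pmax(probs, 1e-12))))
  ce + model$cfg$l2 * (sum(model$params$W1^2) + sum(model$params$W2^2))
}

#' Train the model with Adam under the published schedule
#'
#' Mini-batch Adam on categorical cross-entropy with the staircase schedule
#' `lr(t) = learning_rate * decay_rate^floor(t / decay_steps)` over update
#' steps t, early stopping on validation loss with best-weight restoration,
#' and frozen subnetworks excluded from all updates. Deterministic given
#' `cfg$seed` (single-threaded BLAS assumed).
#'
#' @param model A `TriademModel`.
#' @param data A `ProcessedCohort` (uses its `train` and `validation` blocks),
#'   or a list with `train`/`validation` entries each holding `x` and `y`.
#' @return The fitted model; `$history` holds per-epoch losses/accuracies and
#'   the learning rate at every update step (`attr(history, "lr_steps")`).
#' @export
train_triadem <- function(model, data) {
  cfg <- model$cfg
  xt <- data$train$x; yt <- data$train$y
  xv <- data$validation$x; yv <- data$validation$y
  stopifnot(nrow(xt) == nrow(yt), ncol(xt) == sum(model$widths))
  rng <- .seeded_rng(cfg$seed + 13L)
  p <- model$params
  adam <- list(m = lapply(p, function(q) q * 0), v = lapply(p, function(q) q * 0))
  sub_adam <- NULL
  if (model$trainable_subnets) {
    zl <- lapply(model$subnet, function(ws) lapply(ws, function(w) w * 0))
    sub_adam <- list(m = zl, v = zl)
  }
  beta1 <- 0.9; beta2 <- 0.999; aeps <- 1e-7
  step <- 0L
  lr_steps <- numeric(0)
  hist <- data.frame(epoch = integer(0), loss = numeric(0), acc = numeric(0),
                     val_loss = numeric(0), val_acc = numeric(0), lr = numeric(0))
  best <- list(loss = Inf, params = p, moving_mean = model$moving_mean,
               moving_var = model$moving_var, bn_steps = model$bn_steps,
               subnet = model$subnet, epoch = 0L)
  wait <- 0L

  n <- nrow(xt)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- rng$sample_int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0; ep_correct <- 0
    for (b in batches) {
      xb <- xt[b, , drop = FALSE]; yb <- yt[b, , drop = FALSE]
      nb <- length(b)
      drop_mask <- NULL
      if (cfg$dropout_rate > 0) {
        drop_mask <- matrix(as.numeric(rng$runif(nb * cfg$hidden1_size) >= cfg$dropout_rate),
                            nb, cfg$hidden1_size)
      }
      fw <- .forward(model, xb, training = TRUE, drop_mask = drop_mask)
      if (!all(is.finite(fw$probs))) stop("NaN loss encountered at epoch ", epoch)
      ep_loss <- ep_loss + .loss(model, fw$probs, yb) * nb
      ep_correct <- ep_correct + sum(max.col(fw$probs) == max.col(yb))

      # ----- backprop -----
      g <- list()
      dlogits <- (fw$probs - yb) / nb
      g$W3 <- t(fw$a2) %*% dlogits
      g$b3 <- colSums(dlogits)
      da2 <- dlogits %*% t(p$W3)
      dpre2 <- da2 * (fw$pre2 > 0)
      g$W2 <- t(fw$d1) %*% dpre2 + 2 * cfg$l2 * p$W2
      g$b2 <- colSums(dpre2)
      dd1 <- dpre2 %*% t(p$W2)
      da1 <- dd1
      if (cfg$dropout_rate > 0) da1 <- dd1 * drop_mask / (1 - cfg$dropout_rate)
      g$W1 <- t(fw$z1) %*% da1 + 2 * cfg$l2 * p$W1
      g$b1 <- colSums(da1)
      dz1 <- da1 %*% t(p$W1)
      g$gamma <- colSums(dz1 * fw$xhat)
      g$beta <- colSums(dz1)

      sub_g <- NULL
      if (model$trainable_subnets) {
        # BN backward to its input, then through concat into the subnets
        sd_ <- sqrt(fw$va + fw$eps)
        dxhat <- sweep(dz1, 2, p$gamma, "*")
        xc <- sweep(fw$z0, 2, fw$mu, "-")
        dvar <- colSums(dxhat * xc) * (-0.5) * (fw$va + fw$eps)^(-1.5)
        dmu <- colSums(sweep(dxhat, 2, -1 / sd_, "*")) + dvar * colMeans(-2 * xc)
        dz0 <- sweep(dxhat, 2, sd_, "/") +
          sweep(xc, 2, 2 * dvar / nb, "*") +
          matrix(dmu / nb, nb, length(dmu), byrow = TRUE)
        w_snp <- ncol(fw$s1$out); w_expr <- ncol(fw$s2$out)
        sub_g <- list(
          snp = .subnet_backward(model$subnet$snp, fw$bl$genotype, fw$s1$acts,
                                 dz0[, seq_len(w_snp), drop = FALSE],
                                 cfg$subnetwork_activation),
          expr = .subnet_backward(model$subnet$expr, fw$bl$expression, fw$s2$acts,
                                  dz0[, w_snp + seq_len(w_expr), drop = FALSE],
                                  cfg$subnetwork_activation))
      }

      # ----- Adam update at the scheduled rate -----
      lr <- cfg$learning_rate * cfg$decay_rate^(step %/% cfg$decay_steps)
      lr_steps <- c(lr_steps, lr)
      step <- step + 1L
      t_ <- step
      for (nm in names(p)) {
        adam$m[[nm]] <- beta1 * adam$m[[nm]] + (1 - beta1) * g[[nm]]
        adam$v[[nm]] <- beta2 * adam$v[[nm]] + (1 - beta2) * g[[nm]]^2
        mhat <- adam$m[[nm]] / (1 - beta1^t_)
        vhat <- adam$v[[nm]] / (1 - beta2^t_)
        p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + aeps)
      }
      model$params <- p
      if (model$trainable_subnets) {
        for (s in names(sub_g)) for (l in seq_along(sub_g[[s]])) {
          sub_adam$m[[s]][[l]] <- beta1 * sub_adam$m[[s]][[l]] + (1 - beta1) * sub_g[[s]][[l]]
          sub_adam$v[[s]][[l]] <- beta2 * sub_adam$v[[s]][[l]] + (1 - beta2) * sub_g[[s]][[l]]^2
          mhat <- sub_adam$m[[s]][[l]] / (1 - beta1^t_)
          vhat <- sub_adam$v[[s]][[l]] / (1 - beta2^t_)
          model$subnet[[s]][[l]] <- model$subnet[[s]][[l]] - lr * mhat / (sqrt(vhat) + aeps)
        }
      }
      # BN moving statistics
      model$moving_mean <- cfg$bn_momentum * model$moving_mean + (1 - cfg$bn_momentum) * fw$mu
      model$moving_var <- cfg$bn_momentum * model$moving_var + (1 - cfg$bn_momentum) * fw$va
      model$bn_steps <- model$bn_steps + 1L
    }

    vp <- .forward(model, xv, training = FALSE)$probs
    val_loss <- .loss(model, vp, yv)
    hist <- rbind(hist, data.frame(
      epoch = epoch, loss = ep_loss / n,
      acc = ep_correct / n, val_loss = val_loss,
      val_acc = mean(max.col(vp) == max.col(yv)),
      lr = lr_steps[length(lr_steps)]))

    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, params = model$params,
                   moving_mean = model$moving_mean,
                   moving_var = model$moving_var, bn_steps = model$bn_steps,
                   subnet = model$subnet, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  # restore best weights
  model$params <- best$params
  model$moving_mean <- best$moving_mean
  model$moving_var <- best$moving_var
  model$bn_steps <- best$bn_steps
  model$subnet <- best$subnet
  model$trained <- TRUE
  attr(hist, "lr_steps") <- lr_steps
  attr(hist, "best_epoch") <- best$epoch
  attr(hist, "stopped_early") <- nrow(hist) < model$cfg$max_epochs
  model$history <- hist
  model
}

.subnet_backward <- function(weights, x, acts, dtop, activation) {
  L <- length(weights)
  grads <- vector("list", L)
  dh <- dtop
  for (l in rev(seq_len(L))) {
    if (activation == "tanh") dh <- dh * (1 - acts[[l]]^2)
    h_prev <- if (l == 1L) x else acts[[l - 1L]]
    grads[[l]] <- t(h_prev) %*% dh
    dh <- dh %*% t(weights[[l]])
  }
  grads
}

#' Evaluate a fitted model on a labelled block
#'
#' Per-class contingency counts use the one-vs-rest convention; precision is
#' TP/(TP+FP), recall TP/(TP+FN), F1 their harmonic mean, and AUC the
#' one-vs-rest area under the ROC curve from the softmax scores. Macro
#' averages run over classes present in the data; a class absent from the
#' block gets NA metrics and is excluded from the macro mean.
#'
#' @param model A fitted `TriademModel`.
#' @param x Concatenated feature matrix.
#' @param labels CN/MCI/AD labels.
#' @return A `MetricsReport`: list with `confusion` (rows = truth),
#'   `per_class` data.frame (TP/TN/FP/FN, accuracy, precision, recall, F1,
#'   AUC), `accuracy` (micro), and `macro` (averaged precision/recall/F1/AUC).
#' @export
evaluate_model <- function(model, x, labels) {
  metrics_report(labels, predict(model, x))
}

#' Metrics report from labels and class-probability scores
#'
#' @param labels True CN/MCI/AD labels.
#' @param probs n x 3 probability (or score) matrix in class order CN, MCI,
#'   AD; predicted class is the per-row argmax.
#' @return A `MetricsReport` (see [evaluate_model()]).
#' @export
metrics_report <- function(labels, probs) {
  truth <- factor(as.character(labels), levels = .CLASS_ORDER)
  pred <- factor(.CLASS_ORDER[max.col(probs)], levels = .CLASS_ORDER)
  confusion <- table(truth = truth, predicted = pred)
  n <- length(truth)
  per_class <- do.call(rbind, lapply(.CLASS_ORDER, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    tn <- n - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else NA_real_
    auc <- if (sum(truth == cl) > 0 && sum(truth != cl) > 0) {
      as.numeric(pROC::auc(pROC::roc(response = as.integer(truth == cl),
                                     predictor = probs[, cl], quiet = TRUE,
                                     direction = "<", levels = c(0, 1))))
    } else NA_real_
    data.frame(class = cl, TP = tp, TN = tn, FP = fp, FN = fn,
               accuracy = (tp + tn) / n, precision = prec, recall = rec,
               F1 = f1, AUC = auc)
  }))
  macro <- colMeans(per_class[, c("precision", "recall", "F1", "AUC")], na.rm = TRUE)
  structure(list(confusion = confusion, per_class = per_class,
                 accuracy = sum(diag(confusion)) / n,
                 macro = as.list(macro), n = n), class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat("MetricsReport on", x$n, "samples: accuracy",
      sprintf("%.3f", x$accuracy),
      "| macro F1", sprintf("%.3f", x$macro$F1),
      "| macro AUC", sprintf("%.3f", x$macro$AUC), "\n")
  print(x$confusion)
  invisible(x)
}

#' Write a metrics report as JSON and CSV
#' @param report A `MetricsReport`.
#' @param prefix Output path prefix.
#' @return Invisibly, the file paths.
#' @export
write_metrics <- function(report, prefix) {
  jpath <- paste0(prefix, "_metrics.json")
  cpath <- paste0(prefix, "_metrics.csv")
  jsonlite::write_json(list(accuracy = report$accuracy, macro = report$macro,
                            confusion = as.data.frame(report$confusion)),
                       jpath, auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$per_class, cpath, row.names = FALSE)
  invisible(c(jpath, cpath))
}
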