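# Intermediate pathway-node activation analysis.
#
# A pathway node's activation is the signed outcome of the forward pass
# truncated at its layer (under identity activation, the cumulative masked
# matrix product). Nodes whose activation distributions differ across the
# CN/MCI/AD groups are flagged with a Kruskal-Wallis test.

#' Capture pathway-node activations at one subnetwork level
#'
#' @param model A `TriademModel`.
#' @param x Concatenated feature matrix (genotype | expression | clinical).
#' @param subnetwork `"snp"` or `"expr"`.
#' @param level Pathway level in 1..depth.
#' @return Samples x nodes matrix of activations, node ids as colnames.
#' @export
capture_activations <- function(model, x, subnetwork = c("snp", "expr"), level = 1L) {
  subnetwork <- match.arg(subnetwork)
  stopifnot(inherits(model, "TriademModel"))
  if (level < 1L || level > model$cfg$depth) {
    stop("level must be in 1..", model$cfg$depth)
  }
  bl <- split_blocks(x, model$widths)
  h <- if (subnetwork == "snp") bl$genotype else bl$expression
  weights <- model$subnet[[if (subnetwork == "snp") "snp" else "expr"]]
  for (l in seq_len(level)) {
    h <- h %*% weights[[l]]
    if (model$cfg$subnetwork_activation == "tanh") h <- tanh(h)
  }
  h
}

#' Kruskal-Wallis test per node over class-grouped activation samples
#'
#' Rank-based H with tie correction (via [stats::kruskal.test()]), p from
#' the chi-square distribution with (groups - 1) degrees of freedom. Nodes
#' with constant values across all groups get H = 0, p = 1 and a degenerate
#' flag. Rows are sorted by p.
#'
#' @param activations Samples x nodes matrix.
#' @param groups Class label per sample (>= 2 groups with >= 2 observations).
#' @param alpha Significance level for the flag (default 0.05).
#' @param adjust Apply Benjamini-Hochberg correction to the p-values before
#'   flagging (off by default; the raw per-node p-values are what the
#'   activation analysis reports).
#' @return Data.frame (node, H, p, significant, degenerate) sorted by p.
#' @export
kruskal_wallis_nodes <- function(activations, groups, alpha = 0.05,
                                 adjust = FALSE) {
  groups <- as.factor(groups)
  stopifnot(nrow(activations) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("need >= 2 groups with >= 2 observations each")
  }
  res <- lapply(seq_len(ncol(activations)), function(j) {
    v <- activations[, j]
    if (length(unique(v)) == 1L) {
      return(data.frame(H = 0, p = 1, degenerate = TRUE))
    }
    kw <- stats::kruskal.test(v, groups)
    data.frame(H = unname(kw$statistic), p = unname(kw$p.value),
               degenerate = FALSE)
  })
  out <- do.call(rbind, res)
  out$node <- if (is.null(colnames(activations)))
    paste0("node", seq_len(ncol(activations))) else colnames(activations)
  p_used <- if (adjust) stats::p.adjust(out$p, "BH") else out$p
  out$significant <- p_used < alpha
  out <- out[order(out$p), c("node", "H", "p", "significant", "degenerate")]
  rownames(out) <- NULL
  out
}

#' Full activation report across subnetworks and levels
#'
#' Runs [capture_activations()] and [kruskal_wallis_nodes()] for every
#' requested (subnetwork, level) pair.
#'
#' @param model A fitted `TriademModel`.
#' @param x Concatenated feature matrix (typically the test split).
#' @param labels Class labels over rows of `x`.
#' @param subnetworks,levels Which pairs to probe (defaults: both
#'   subnetworks, all levels).
#' @param n_per_class Optional cap on randomly selected inputs per class
#'   (default uses all supplied samples).
#' @param alpha,adjust Passed to [kruskal_wallis_nodes()].
#' @param seed Seed for the per-class subsampling.
#' @return An `ActivationReport` data.frame (subnetwork, level, node, H, p,
#'   significant, degenerate).
#' @export
activation_report <- function(model, x, labels, subnetworks = c("snp", "expr"),
                              levels = seq_len(model$cfg$depth),
                              n_per_class = NULL, alpha = 0.05,
                              adjust = FALSE, seed = 1L) {
  labels <- as.character(labels)
  if (!is.null(n_per_class)) {
    rng <- .seeded_rng(seed)
    keep <- unlist(lapply(unique(labels), function(cl) {
      idx <- which(labels == cl)
      idx[rng$sample_int(length(idx), min(n_per_class, length(idx)))]
    }))
    x <- x[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  out <- do.call(rbind, lapply(subnetworks, function(s) {
    do.call(rbind, lapply(levels, function(l) {
      act <- capture_activations(model, x, s, l)
      kw <- kruskal_wallis_nodes(act, labels, alpha = alpha, adjust = adjust)
      cbind(subnetwork = s, level = l, kw)
    }))
  }))
  rownames(out) <- NULL
  class(out) <- c("ActivationReport", "data.frame")
  out
}

#' Kernel-density summary of class-grouped activation samples
#'
#' Gaussian kernel with Silverman's rule-of-thumb bandwidth, evaluated on a
#' shared grid spanning the pooled range of all classes.
#'
#' @param samples_by_class Named list of numeric vectors (>= 2 points each;
#'   a single-point class yields a degenerate spike and is flagged).
#' @param grid_size Number of grid points (default 128).
#' @return Long data.frame (class, x, density); classes flagged degenerate
#'   are listed in attribute `degenerate`.
#' @export
kde_summary <- function(samples_by_class, grid_size = 128L) {
  stopifnot(is.list(samples_by_class), length(samples_by_class) >= 1L)
  pooled <- unlist(samples_by_class)
  rng_ <- range(pooled)
  pad <- diff(rng_) * 0.1 + 1e-9
  from <- rng_[1] - pad; to <- rng_[2] + pad
  degenerate <- character(0)
  out <- do.call(rbind, lapply(names(samples_by_class), function(cl) {
    v <- samples_by_class[[cl]]
    if (length(v) < 2L || stats::sd(v) == 0) {
      degenerate <<- c(degenerate, cl)
      gx <- seq(from, to, length.out = grid_size)
      dens <- rep(0, grid_size)
      dens[which.min(abs(gx - v[1]))] <- 1 / (gx[2] - gx[1])  # unit-mass spike
      return(data.frame(class = cl, x = gx, density = dens))
    }
    d <- stats::density(v, bw = "nrd0", from = from, to = to, n = grid_size)
    data.frame(class = cl, x = d$x, density = d$y)
  }))
  attr(out, "degenerate") <- degenerate
  out
}
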