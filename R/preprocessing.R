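# Preprocessing: additive SNP encoding, PLINK text parsing, clinical table
# cleaning (sparse-feature drop, kNN imputation), stratified splitting,
# SMOTE balancing, min-max scaling and one-hot targets.
#
# All train-derived statistics (imputation neighbours, scaling ranges,
# SMOTE draws) are fitted on the training split only and applied unchanged
# to validation and test, so no information leaks across splits.

#' Aggregate additive variant codes into a per-gene genotype matrix
#'
#' Variant calls are additively coded (0 = homozygous dominant,
#' 1 = heterozygous, 2 = homozygous recessive). Each gene's value for a
#' sample is the sum of codes over the variants mapped to that gene; missing
#' codes contribute 0 and variants absent from the map are dropped (and
#' counted in the `dropped_variants` attribute).
#'
#' @param calls Numeric matrix, samples x variants, entries in {0,1,2,NA},
#'   with sample ids as rownames and variant ids as colnames.
#' @param variant_gene_map Data.frame with columns `variant_id`,
#'   `gene_symbol` (unique variant ids).
#' @param aggregate `"sum"` (additive aggregate, default) or `"mean"`.
#' @return A `GenotypeMatrix`: samples x genes numeric matrix with
#'   attributes `dropped_variants` (ids not in the map) and `n_variants`
#'   (mapped variant count per gene).
#' @export
encode_snps <- function(calls, variant_gene_map, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.matrix(calls), !is.null(colnames(calls)), !is.null(rownames(calls)))
  if (anyDuplicated(variant_gene_map$variant_id)) stop("variant ids in map are not unique")
  bad <- which(!(calls %in% c(0, 1, 2)) & !is.na(calls))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(calls))
    stop(sprintf("invalid additive code %s for sample '%s', variant '%s'",
                 format(calls[bad[1]]), rownames(calls)[i[1]], colnames(calls)[i[2]]))
  }
  map <- stats::setNames(as.character(variant_gene_map$gene_symbol),
                         as.character(variant_gene_map$variant_id))
  mapped <- colnames(calls) %in% names(map)
  dropped <- colnames(calls)[!mapped]
  calls <- calls[, mapped, drop = FALSE]
  calls[is.na(calls)] <- 0
  genes <- map[colnames(calls)]
  gene_order <- unique(genes)
  # sum columns per gene via indicator matrix: samples x variants %*% variants x genes
  ind <- outer(genes, gene_order, "==") * 1
  values <- calls %*% ind
  colnames(values) <- gene_order
  if (aggregate == "mean") values <- sweep(values, 2, colSums(ind), "/")
  structure(values,
            dropped_variants = dropped,
            n_variants = stats::setNames(colSums(ind), gene_order),
            class = c("GenotypeMatrix", "matrix", "array"))
}

#' Parse PLINK text variant (.bim) and sample (.fam) tables
#'
#' @param bim_path Path to a whitespace-delimited 6-column .bim file
#'   (chromosome, variant id, cM position, bp position, allele 1, allele 2).
#' @param fam_path Path to a 6-column .fam file (family id, individual id,
#'   father, mother, sex, phenotype).
#' @return List with `variants` (data.frame: variant_id, chromosome,
#'   position, allele1, allele2) and `samples` (data.frame: family_id,
#'   sample_id, sex, phenotype).
#' @export
parse_plink_text <- function(bim_path, fam_path) {
  read6 <- function(path, what) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(NULL)
    fields <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(fields)
    if (any(nf != 6L)) {
      stop(sprintf("%s line %d: expected 6 whitespace-delimited columns, got %d",
                   what, which(nf != 6L)[1], nf[nf != 6L][1]))
    }
    as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  }
  bim <- read6(bim_path, ".bim")
  fam <- read6(fam_path, ".fam")
  variants <- if (is.null(bim)) {
    data.frame(variant_id = character(0), chromosome = character(0),
               position = integer(0), allele1 = character(0), allele2 = character(0))
  } else {
    data.frame(variant_id = bim[[2]], chromosome = bim[[1]],
               position = as.integer(bim[[4]]), allele1 = bim[[5]],
               allele2 = bim[[6]])
  }
  samples <- if (is.null(fam)) {
    data.frame(family_id = character(0), sample_id = character(0),
               sex = integer(0), phenotype = character(0))
  } else {
    data.frame(family_id = fam[[1]], sample_id = fam[[2]],
               sex = as.integer(fam[[5]]), phenotype = fam[[6]])
  }
  list(variants = variants, samples = samples)
}

#' Drop clinical features with too much missing data
#'
#' Missingness is computed on training rows only; features whose missing
#' fraction reaches `max_missing` are removed from all rows.
#'
#' @param tab Data.frame of clinical features (may contain NA).
#' @param train_idx Row indices of the training samples.
#' @param max_missing Removal threshold on the training missing fraction
#'   (default 0.60, i.e. features are kept only when less than 60% missing).
#' @return The table without the sparse features; removed names in attribute
#'   `dropped_features`.
#' @export
drop_sparse_features <- function(tab, train_idx = seq_len(nrow(tab)),
                                 max_missing = 0.60) {
  frac <- vapply(tab[train_idx, , drop = FALSE],
                 function(x) mean(is.na(x)), numeric(1))
  drop <- names(frac)[frac >= max_missing]
  if (length(drop) == ncol(tab)) stop("all clinical features exceed the missingness cutoff")
  out <- tab[, setdiff(names(tab), drop), drop = FALSE]
  attr(out, "dropped_features") <- drop
  out
}

# Partial Euclidean distance between one row and a matrix of rows:
# squared differences over mutually observed features, rescaled by the
# fraction observed. Rows sharing no observed feature get Inf.
.partial_dist <- function(row, mat) {
  diff2 <- sweep(mat, 2, row, "-")^2
  obs <- !is.na(diff2)
  n_obs <- rowSums(obs)
  diff2[!obs] <- 0
  d2 <- rowSums(diff2) * ncol(mat) / pmax(n_obs, 1)
  d2[n_obs == 0] <- Inf
  sqrt(d2)
}

#' k-nearest-neighbour imputation fitted on the training table
#'
#' Each missing entry is replaced using the k nearest training rows under a
#' partial Euclidean distance (features missing in either row are ignored
#' and the sum rescaled by the fraction observed; continuous features are
#' standardised internally with training means/SDs). Continuous features
#' take the inverse-distance-weighted mean of the neighbours' values,
#' categorical features the mode. The neighbour pool is always the training
#' table, so validation/test imputation reuses the fitted model.
#'
#' @param train Data.frame of training-clinical rows.
#' @param apply_to List of further data.frames imputed against `train`
#'   (e.g. validation and test); may be empty.
#' @param k Number of neighbours (default 5).
#' @param categorical Character vector naming the categorical columns
#'   (imputed by mode); all other columns are treated as continuous.
#' @param weighted If `FALSE`, continuous imputations use the unweighted
#'   neighbour mean.
#' @return List of imputed tables: `train` first, then the `apply_to`
#'   tables in order.
#' @export
knn_impute <- function(train, apply_to = list(), k = 5L,
                       categorical = character(0), weighted = TRUE) {
  stopifnot(k >= 1L, k <= nrow(train) - 1L)
  all_missing <- rowSums(!is.na(train)) == 0
  if (any(all_missing)) {
    stop("training row(s) with all features missing: ",
         paste(utils::head(rownames(train)[all_missing], 3), collapse = ", "))
  }
  cont <- setdiff(names(train), categorical)
  mu <- vapply(train[cont], function(x) mean(x, na.rm = TRUE), numeric(1))
  sg <- vapply(train[cont], function(x) stats::sd(x, na.rm = TRUE), numeric(1))
  sg[!is.finite(sg) | sg == 0] <- 1
  standardise <- function(tab) {
    z <- data.matrix(tab)
    z[, cont] <- sweep(sweep(z[, cont, drop = FALSE], 2, mu, "-"), 2, sg, "/")
    z
  }
  ztrain <- standardise(train)

  impute_one <- function(tab, z, is_train) {
    for (i in seq_len(nrow(tab))) {
      miss <- which(is.na(tab[i, ]))
      if (!length(miss)) next
      d <- .partial_dist(z[i, ], ztrain)
      if (is_train) d[i] <- Inf            # a row is not its own neighbour
      ord <- order(d)[seq_len(k)]
      if (!all(is.finite(d[ord]))) {
        ord <- ord[is.finite(d[ord])]
        if (!length(ord)) stop("no usable neighbour for row ", i)
      }
      w <- if (weighted) 1 / pmax(d[ord], .Machine$double.eps) else rep(1, length(ord))
      for (j in miss) {
        nb <- train[ord, j]
        ok <- !is.na(nb)
        if (!any(ok)) { nb <- train[[j]]; ok <- !is.na(nb); wj <- rep(1, sum(ok)) }
        else wj <- w[ok]
        nb <- nb[ok]
        tab[i, j] <- if (names(tab)[j] %in% categorical) {
          agg <- tapply(wj, nb, sum)
          as.numeric(names(agg)[which.max(agg)])
        } else {
          sum(wj * nb) / sum(wj)
        }
      }
    }
    tab
  }
  out <- c(list(train = impute_one(train, ztrain, TRUE)),
           lapply(apply_to, function(tab) impute_one(tab, standardise(tab), FALSE)))
  out
}

#' Stratified train/validation/test assignment
#'
#' Realised as a stratified 70/30 test carve-out followed by a stratified
#' 80/20 validation carve-out of the 70, giving 56/14/30 with per-class
#' proportions within one sample of the global ones.
#'
#' @param labels Factor or character vector of class labels.
#' @param fractions Train/validation/test fractions summing to 1
#'   (default `c(0.56, 0.14, 0.30)`).
#' @param seed Integer seed; assignment is reproducible given the seed.
#' @return Character vector over samples with values `"train"`,
#'   `"validation"`, `"test"`.
#' @export
split_stratified <- function(labels, fractions = c(0.56, 0.14, 0.30), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3L)
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < 3L)) {
    stop("class with fewer than 3 samples: ",
         paste(names(counts)[counts < 3], collapse = ", "))
  }
  test_frac <- fractions[3]
  val_frac_of_rest <- fractions[2] / (fractions[1] + fractions[2])
  split <- rep("train", length(labels))
  rng <- .seeded_rng(seed)
  for (cl in names(counts)) {
    idx <- which(labels == cl)
    n <- length(idx)
    n_test <- round(n * test_frac)
    n_val <- round((n - n_test) * val_frac_of_rest)
    shuffled <- idx[rng$sample_int(n)]
    split[shuffled[seq_len(n_test)]] <- "test"
    split[shuffled[n_test + seq_len(n_val)]] <- "validation"
  }
  split
}

# Local RNG helper: isolates package randomness from the global stream.
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    s
  })
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    force(expr)
  }
  list(
    sample_int = function(n, size = n, replace = FALSE)
      with_state(sample.int(n, size, replace = replace)),
    runif = function(n, min = 0, max = 1) with_state(stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(stats::rnorm(n, mean, sd)),
    rbinom = function(n, size, prob) with_state(stats::rbinom(n, size, prob))
  )
}

#' SMOTE class balancing on a concatenated feature matrix
#'
#' Oversamples every minority class up to the majority count by drawing
#' synthetic rows on the segment between a random minority row and one of
#' its k nearest same-class neighbours. Applied to the single concatenated
#' training matrix (genotype | expression | clinical) so synthetic samples
#' stay aligned across modalities.
#'
#' @param x Numeric matrix, training samples x features (complete data).
#' @param labels Class labels over rows of `x`.
#' @param k_neighbors Neighbourhood size (default 5); reduced with a warning
#'   when a minority class is too small.
#' @param seed Integer seed.
#' @return List with balanced `x`, `labels`, and `synthetic` (logical flag
#'   per returned row).
#' @export
smote_balance <- function(x, labels, k_neighbors = 5L, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(labels), !anyNA(x))
  labels <- as.character(labels)
  counts <- table(labels)
  n_max <- max(counts)
  rng <- .seeded_rng(seed)
  new_x <- list(); new_lab <- character(0)
  for (cl in names(counts)) {
    need <- n_max - counts[[cl]]
    if (need == 0L) next
    idx <- which(labels == cl)
    k <- k_neighbors
    if (length(idx) <= k) {
      k <- length(idx) - 1L
      warning("class '", cl, "' has only ", length(idx),
              " rows; k reduced to ", k)
    }
    if (k < 1L) stop("class '", cl, "' too small for SMOTE")
    block <- x[idx, , drop = FALSE]
    d <- as.matrix(stats::dist(block))
    diag(d) <- Inf
    nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
    base <- rng$sample_int(length(idx), need, replace = TRUE)
    pick <- rng$sample_int(k, need, replace = TRUE)
    u <- rng$runif(need)
    synth <- block[base, , drop = FALSE] +
      u * (block[nn[cbind(base, pick)], , drop = FALSE] - block[base, , drop = FALSE])
    new_x[[cl]] <- synth
    new_lab <- c(new_lab, rep(cl, need))
  }
  n_orig <- nrow(x)
  if (length(new_x)) x <- rbind(x, do.call(rbind, new_x))
  rownames(x) <- NULL
  list(x = x, labels = c(labels, new_lab),
       synthetic = c(rep(FALSE, n_orig), rep(TRUE, nrow(x) - n_orig)))
}

#' Fit min-max scaling on training rows and apply it to other blocks
#'
#' Each feature is mapped by `(x - min) / (max - min)` with the range taken
#' from the training rows, so training values lie in `[0, 1]`; constant
#' features map to 0 and validation/test values may fall outside `[0, 1]`
#' (no clipping).
#'
#' @param train Numeric training matrix (samples x features).
#' @param apply_to List of further matrices scaled with the training ranges.
#' @return List with `train`, the scaled `apply_to` blocks, and `ranges`
#'   (per-feature min/max used).
#' @export
minmax_scale <- function(train, apply_to = list()) {
  mins <- apply(train, 2, min)
  maxs <- apply(train, 2, max)
  span <- maxs - mins
  scale_one <- function(m) {
    out <- sweep(m, 2, mins, "-")
    out <- sweep(out, 2, ifelse(span == 0, 1, span), "/")
    out[, span == 0] <- 0
    out
  }
  c(list(train = scale_one(train)), lapply(apply_to, scale_one),
    list(ranges = data.frame(feature = colnames(train), min = mins, max = maxs,
                             row.names = NULL)))
}

#' One-hot encode CN/MCI/AD labels
#'
#' @param labels Vector with values in {CN, MCI, AD}.
#' @return n x 3 indicator matrix with column order (CN, MCI, AD).
#' @export
one_hot_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), .CLASS_ORDER)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  out <- outer(labels, .CLASS_ORDER, "==") * 1
  colnames(out) <- .CLASS_ORDER
  out
}

# Class-code order used everywhere: CN=0, MCI=1, AD=2.
.CLASS_ORDER <- c("CN", "MCI", "AD")

#' Run the full preprocessing pipeline on a multimodal cohort
#'
#' Fixed order: encode (done upstream) -> drop sparse clinical features ->
#' kNN-impute clinical (fit on train) -> stratified split -> SMOTE on the
#' concatenated training block -> min-max scale (fit on train) -> one-hot
#' targets. Sample order stays aligned across the three blocks throughout.
#'
#' @param genotype Samples x genes numeric matrix (per-gene additive sums).
#' @param expression Samples x genes numeric matrix (no missing entries).
#' @param clinical Data.frame of clinical features (NAs allowed).
#' @param labels CN/MCI/AD labels over the shared sample order.
#' @param categorical Names of categorical clinical columns.
#' @param fractions Train/validation/test fractions.
#' @param k_impute,k_smote Neighbourhood sizes.
#' @param max_missing Clinical missingness cutoff.
#' @param seed Integer seed driving split and SMOTE.
#' @return A `ProcessedCohort`: per-split feature blocks (`x` concatenated,
#'   plus `genotype`/`expression`/`clinical` views), one-hot `y`, labels,
#'   block widths, scaling ranges and the fitted metadata.
#' @export
preprocess_cohort <- function(genotype, expression, clinical, labels,
                              categorical = character(0),
                              fractions = c(0.56, 0.14, 0.30),
                              k_impute = 5L, k_smote = 5L,
                              max_missing = 0.60, seed = 1L) {
  stopifnot(nrow(genotype) == nrow(expression),
            nrow(expression) == nrow(clinical),
            nrow(clinical) == length(labels))
  if (anyNA(expression)) stop("expression matrix contains missing entries")
  split <- split_stratified(labels, fractions, seed = seed)
  tr <- split == "train"; va <- split == "validation"; te <- split == "test"

  clinical <- drop_sparse_features(clinical, which(tr), max_missing)
  dropped <- attr(clinical, "dropped_features")
  categorical <- intersect(categorical, names(clinical))
  imp <- knn_impute(clinical[tr, , drop = FALSE],
                    list(validation = clinical[va, , drop = FALSE],
                         test = clinical[te, , drop = FALSE]),
                    k = k_impute, categorical = categorical)
  clin_mat <- function(tab) data.matrix(tab)

  widths <- c(genotype = ncol(genotype), expression = ncol(expression),
              clinical = ncol(clinical))
  concat <- function(sel, clin) {
    x <- cbind(genotype[sel, , drop = FALSE],
               expression[sel, , drop = FALSE],
               clin_mat(clin))
    colnames(x) <- c(paste0("snp:", colnames(genotype)),
                     paste0("expr:", colnames(expression)),
                     paste0("clin:", colnames(clin)))
    x
  }
  x_tr <- concat(tr, imp$train)
  x_va <- concat(va, imp$validation)
  x_te <- concat(te, imp$test)

  bal <- smote_balance(x_tr, labels[tr], k_neighbors = k_smote, seed = seed + 1L)
  sc <- minmax_scale(bal$x, list(validation = x_va, test = x_te))

  mk <- function(x, lab) {
    list(x = x, y = one_hot_labels(lab), labels = as.character(lab))
  }
  structure(list(
    train = mk(sc$train, bal$labels),
    validation = mk(sc$validation, labels[va]),
    test = mk(sc$test, labels[te]),
    widths = widths,
    feature_names = colnames(x_tr),
    modality = rep(c("snp", "expression", "clinical"), widths),
    split = split,
    ranges = sc$ranges,
    dropped_features = dropped,
    synthetic_rows = bal$synthetic,
    seed = seed), class = "ProcessedCohort")
}

#' Slice a concatenated feature block back into its three modalities
#' @param x Concatenated matrix.
#' @param widths Named widths as stored in a `ProcessedCohort`.
#' @return List of the three blocks.
#' @export
split_blocks <- function(x, widths) {
  i1 <- seq_len(widths[["genotype"]])
  i2 <- widths[["genotype"]] + seq_len(widths[["expression"]])
  i3 <- widths[["genotype"]] + widths[["expression"]] + seq_len(widths[["clinical"]])
  list(genotype = x[, i1, drop = FALSE],
       expression = x[, i2, drop = FALSE],
       clinical = x[, i3, drop = FALSE])
}
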