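# Shapley-value feature attributions.
#
# Model-agnostic marginal-contribution estimator: for each draw a random
# feature permutation and background row are sampled, features are switched
# from the background row to the explained sample in permutation order, and
# each feature is credited the change in model output when it switches (so
# the attribution of j is its average marginal contribution over coalitions
# drawn from the permutation distribution). With `exact = TRUE` every
# coalition is enumerated with its Shapley weight and averaged over the full
# background, which is the exact Shapley value of the model against that
# background.

# Evaluate the model/function on a batch of composite rows.
.shap_fn <- function(model) {
  if (is.function(model)) model else function(x) predict(model, x)
}

#' Shapley attributions per sample, feature and output class
#'
#' @param model A `TriademModel`, or any function mapping an n x p matrix to
#'   an n x k output matrix (class probabilities).
#' @param background Matrix of background rows (by convention drawn from the
#'   training split; 100 rows is the default elsewhere in the package).
#' @param targets Matrix of rows to explain.
#' @param budget Sampled (coalition, background-row) evaluations per feature
#'   (default 32); ignored when `exact = TRUE`.
#' @param seed Integer seed; estimates are deterministic given seed & budget.
#' @param exact Enumerate all 2^(p-1) coalitions per feature against the
#'   full background (exact Shapley; only feasible for small p).
#' @param modality Optional character vector tagging each feature
#'   (`snp`/`expression`/`clinical`).
#' @return An `AttributionSet`: `attributions` array (samples x features x
#'   classes), `base_values` (expected model output over the background),
#'   `residuals` (local-accuracy gap f(x) - base - sum(attributions), per
#'   sample x class), `feature_names`, `modality`, `budget`.
#' @export
shapley_attributions <- function(model, background, targets, budget = 32L,
                                 seed = 1L, exact = FALSE, modality = NULL) {
  f <- .shap_fn(model)
  stopifnot(is.matrix(background), is.matrix(targets),
            ncol(background) == ncol(targets))
  if (!exact && budget < 2L) stop("budget must be at least 2 to form coalitions")
  p <- ncol(targets)
  feature_names <- colnames(targets)
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(p))
  base_out <- f(background)
  k <- ncol(base_out)
  base_values <- colMeans(base_out)
  n <- nrow(targets)
  rng <- .seeded_rng(seed)
  attr_arr <- array(0, dim = c(n, p, k),
                    dimnames = list(rownames(targets), feature_names, colnames(base_out)))

  if (exact) {
    if (p > 20L) stop("exact enumeration infeasible for p = ", p)
    subsets <- lapply(0:(2^p - 1), function(m) which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0))
    wt <- function(s) factorial(s) * factorial(p - s - 1) / factorial(p)
    for (i in seq_len(n)) {
      x <- targets[i, ]
      # value of every coalition: mean over background of f(x_S, b_rest)
      v <- vapply(subsets, function(S) {
        z <- background
        if (length(S)) z[, S] <- matrix(x[S], nrow(z), length(S), byrow = TRUE)
        colMeans(f(z))
      }, numeric(k))
      vals <- if (is.matrix(v)) t(v) else matrix(v, ncol = 1L)
      key <- vapply(subsets, function(S) paste(S, collapse = ","), character(1))
      idx <- stats::setNames(seq_along(subsets), key)
      for (j in seq_len(p)) {
        contrib <- numeric(k)
        for (s in seq_along(subsets)) {
          S <- subsets[[s]]
          if (j %in% S) next
          Sj <- sort(c(S, j))
          contrib <- contrib + wt(length(S)) *
            (vals[idx[[paste(Sj, collapse = ",")]], ] - vals[s, ])
        }
        attr_arr[i, j, ] <- contrib
      }
    }
  } else {
    B <- nrow(background)
    for (i in seq_len(n)) {
      x <- targets[i, ]
      acc <- matrix(0, p, k)
      for (d in seq_len(budget)) {
        perm <- rng$sample_int(p)
        b <- background[rng$sample_int(B, 1L), ]
        pos <- integer(p); pos[perm] <- seq_len(p)
        take <- outer(0:p, pos, ">=")          # row r: first r-1 permuted features from x
        z <- take * matrix(x, p + 1L, p, byrow = TRUE) +
          (!take) * matrix(b, p + 1L, p, byrow = TRUE)
        out <- f(z)
        acc[perm, ] <- acc[perm, ] + (out[-1L, , drop = FALSE] -
                                        out[-(p + 1L), , drop = FALSE])
      }
      attr_arr[i, , ] <- acc / budget
    }
  }

  fx <- f(targets)
  residuals <- fx - matrix(base_values, n, k, byrow = TRUE) -
    apply(attr_arr, c(1, 3), sum)
  structure(list(attributions = attr_arr, base_values = base_values,
                 residuals = residuals, feature_names = feature_names,
                 modality = modality,
                 budget = if (exact) "exact" else budget,
                 n_background = nrow(background)),
            class = "AttributionSet")
}

#' Rank features by mean absolute attribution for one class
#'
#' @param a An `AttributionSet`.
#' @param class_label Output class (name or index).
#' @param modality Restrict to one modality tag (requires the set to carry
#'   modality tags); `NULL` ranks all features.
#' @param k Number of top features (default 20); if fewer are available all
#'   are returned with a warning.
#' @return Data.frame (feature, symbol, modality, mean_abs_attribution,
#'   frac_positive) in descending order, ties broken lexicographically.
#' @export
top_features <- function(a, class_label, modality = NULL, k = 20L) {
  stopifnot(inherits(a, "AttributionSet"))
  cls <- if (is.character(class_label)) {
    match(class_label, dimnames(a$attributions)[[3]])
  } else as.integer(class_label)
  if (is.na(cls)) stop("unknown class label")
  sel <- seq_along(a$feature_names)
  if (!is.null(modality)) {
    if (is.null(a$modality)) stop("attribution set carries no modality tags")
    sel <- which(a$modality == modality)
    if (!length(sel)) stop("no features with modality '", modality, "'")
  }
  vals <- a$attributions[, sel, cls, drop = FALSE]
  mean_abs <- apply(abs(vals), 2, mean)
  frac_pos <- apply(vals > 0, 2, mean)
  nm <- a$feature_names[sel]
  ord <- order(-mean_abs, nm)
  if (k > length(sel)) {
    warning("requested k = ", k, " but only ", length(sel),
            " features available; returning all")
    k <- length(sel)
  }
  ord <- ord[seq_len(k)]
  data.frame(feature = nm[ord],
             symbol = sub("^(snp|expr|clin):", "", nm[ord]),
             modality = if (is.null(a$modality)) NA_character_ else a$modality[sel][ord],
             mean_abs_attribution = unname(mean_abs[ord]),
             frac_positive = unname(frac_pos[ord]))
}

#' Export a ranked feature table as a plain-text gene list
#'
#' Writes one symbol per line, deduplicated with order preserved, for use
#' with external enrichment tools.
#'
#' @param ranked Data.frame from [top_features()] (uses its `symbol` column).
#' @param path Output file.
#' @return Invisibly, the written symbols.
#' @export
export_gene_list <- function(ranked, path) {
  if (!nrow(ranked)) {
    warning("empty ranked table; writing empty gene list")
    writeLines(character(0), path)
    return(invisible(character(0)))
  }
  symbols <- unique(as.character(ranked$symbol))
  writeLines(symbols, path)
  invisible(symbols)
}

#' Write an attribution set as a long-form table
#' @param a An `AttributionSet`.
#' @param path CSV output path (columns sample, feature, class, value).
#' @return Invisibly, `path`.
#' @export
write_attributions <- function(a, path) {
  dn <- dimnames(a$attributions)
  long <- expand.grid(sample = if (is.null(dn[[1]])) seq_len(dim(a$attributions)[1]) else dn[[1]],
                      feature = dn[[2]], class = dn[[3]],
                      stringsAsFactors = FALSE)
  long$value <- as.vector(a$attributions)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
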