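# Cohort characterisation: group summaries and the three significance tests
# used for the clinical tables (chi-square contingency for categorical
# proportions, one-way ANOVA reconstructed from summary moments for age of
# onset / education, Kruskal-Wallis for the remaining variables).

#' Pearson chi-square test on a contingency table of counts
#'
#' No continuity correction is applied (required to reproduce the published
#' sex-proportion p-value from the printed counts).
#'
#' @param counts r x c matrix of non-negative integer counts.
#' @return List (statistic, df, p).
#' @export
chi_square_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("contingency table has a zero marginal total")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' One-way ANOVA reconstructed from per-group means, SDs and sizes
#'
#' Between-group sum of squares is taken about the size-weighted grand mean,
#' within-group sum of squares is `sum((n_i - 1) * s_i^2)`; F = MSB/MSW with
#' p from the F distribution. Exactly equivalent to raw-data one-way ANOVA
#' whenever raw data matching the moments exist.
#'
#' @param means,sds,ns Per-group means, standard deviations (> 0) and sizes
#'   (>= 2).
#' @return List (F, df1, df2, p).
#' @export
anova_from_summary <- function(means, sds, ns) {
  stopifnot(length(means) == length(sds), length(sds) == length(ns))
  if (any(ns < 2)) stop("every group needs n >= 2")
  if (any(sds <= 0)) stop("every group needs SD > 0")
  k <- length(means)
  grand <- sum(ns * means) / sum(ns)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- k - 1
  df2 <- sum(ns) - k
  Fv <- (ssb / df1) / (ssw / df2)
  list(F = Fv, df1 = df1, df2 = df2,
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}

#' Kruskal-Wallis test on raw per-group values
#' @param values_by_group List of numeric vectors, one per group.
#' @return List (H, df, p).
#' @export
kruskal_wallis_raw <- function(values_by_group) {
  stopifnot(is.list(values_by_group), length(values_by_group) >= 2L)
  pooled <- unlist(values_by_group)
  if (length(unique(pooled)) == 1L) {
    return(list(H = 0, df = length(values_by_group) - 1, p = 1))
  }
  kw <- stats::kruskal.test(values_by_group)
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p = unname(kw$p.value))
}

#' Format a p-value to three significant figures with a floor
#' @param p Numeric p-value(s).
#' @return Character, `"<0.001"` below the threshold.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", formatC(signif(p, 3), format = "fg"))
}

#' Group summary table with per-feature significance tests
#'
#' One row per clinical feature: group sizes, mean +/- SD (continuous) or
#' per-group counts of the indicated level (categorical), and the p-value of
#' the mapped test. Continuous features may be tested with `"anova"` or
#' `"kruskal_wallis"`; categorical features with `"chi_square"` (the
#' contingency table is group x category over all levels).
#'
#' @param clinical Data.frame of features (no missing values).
#' @param labels Group labels (>= 2 groups required).
#' @param tests Named character vector, feature -> test name; features not
#'   named default to `"kruskal_wallis"`.
#' @return A `GroupSummary` data.frame (feature, test, one `<group>` column
#'   per group formatted to 3 dp, statistic, p, p_formatted).
#' @export
summarize_cohort <- function(clinical, labels, tests = character(0)) {
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) < 2L) stop("summary tests need >= 2 groups")
  known <- c("anova", "chi_square", "kruskal_wallis")
  bad <- setdiff(tests, known)
  if (length(bad)) stop("unknown test name(s): ", paste(bad, collapse = ", "))
  rows <- lapply(names(clinical), function(f) {
    test <- if (f %in% names(tests)) tests[[f]] else "kruskal_wallis"
    v <- clinical[[f]]
    by_g <- split(v, factor(labels, levels = groups))
    if (test == "chi_square") {
      tab <- table(factor(labels, levels = groups), v)
      res <- chi_square_from_counts(tab)
      cells <- vapply(by_g, function(x) paste0("n=", length(x)), character(1))
      stat <- res$statistic; p <- res$p
    } else if (test == "anova") {
      res <- anova_from_summary(vapply(by_g, mean, numeric(1)),
                                vapply(by_g, stats::sd, numeric(1)),
                                lengths(by_g))
      cells <- vapply(by_g, function(x)
        sprintf("%.3f ± %.3f", mean(x), stats::sd(x)), character(1))
      stat <- res$F; p <- res$p
    } else {
      res <- kruskal_wallis_raw(by_g)
      cells <- vapply(by_g, function(x)
        sprintf("%.3f ± %.3f", mean(x), stats::sd(x)), character(1))
      stat <- res$H; p <- res$p
    }
    out <- data.frame(feature = f, test = test, t(cells),
                      statistic = stat, p = p, p_formatted = format_p(p))
    names(out)[2 + seq_along(groups)] <- groups
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "group_n") <- table(factor(labels, levels = groups))
  class(out) <- c("GroupSummary", "data.frame")
  out
}

#' Render a GroupSummary as a markdown table
#' @param s A `GroupSummary`.
#' @param path Optional file to write to.
#' @return Character vector of markdown lines (invisibly if written).
#' @export
render_group_summary <- function(s, path = NULL) {
  groups <- setdiff(names(s), c("feature", "test", "statistic", "p", "p_formatted"))
  n <- attr(s, "group_n")
  header <- c(paste0("| Feature | ", paste(groups, collapse = " | "), " | P-value |"),
              paste0("|", paste(rep("---", length(groups) + 2), collapse = "|"), "|"),
              paste0("| Number of samples | ",
                     paste(n[groups], collapse = " | "), " | |"))
  body <- vapply(seq_len(nrow(s)), function(i) {
    paste0("| ", s$feature[i], " | ",
           paste(unlist(s[i, groups]), collapse = " | "),
           " | ", s$p_formatted[i], " |")
  }, character(1))
  lines <- c(header, body)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
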