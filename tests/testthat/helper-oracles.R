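# Independent brute-force oracles shared across test files. These never call
# the package paths they check.

# Exact Shapley values by full coalition enumeration with combinatorial
# weights; a coalition's value is the mean model output with non-members
# replaced by each background row in turn.
oracle_shapley <- function(f, background, x) {
  p <- length(x)
  value <- function(S) {
    z <- background
    if (length(S)) z[, S] <- matrix(x[S], nrow(z), length(S), byrow = TRUE)
    colMeans(f(z))
  }
  k <- ncol(f(background))
  out <- matrix(0, p, k)
  idx <- seq_len(p)
  for (j in idx) {
    others <- setdiff(idx, j)
    for (m in 0:(2^(p - 1) - 1)) {
      S <- others[which(bitwAnd(m, 2^(seq_len(p - 1) - 1)) > 0)]
      w <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
      out[j, ] <- out[j, ] + w * (value(c(S, j)) - value(S))
    }
  }
  out
}

# Small deterministic nonlinear test model: 2 outputs from 5 features.
toy_f <- function(x) {
  cbind(x[, 1] + 2 * x[, 2] * x[, 3], pmax(x[, 4], 0) - 0.5 * x[, 5])
}

# Kruskal-Wallis H by explicit ranking with tie correction.
oracle_kw <- function(groups_list) {
  v <- unlist(groups_list)
  g <- rep(seq_along(groups_list), lengths(groups_list))
  r <- rank(v)
  n <- length(v)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(x) length(x) * (mean(x) - (n + 1) / 2)^2))
  ties <- table(v)
  H <- H / (1 - sum(ties^3 - ties) / (n^3 - n))
  list(H = H, p = stats::pchisq(H, length(groups_list) - 1, lower.tail = FALSE))
}
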