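# Fixtures are built in code at test time; nothing is stored on disk.

# Toy hierarchy: level-1 pathways A (g1,g2) and B (g3), level-2 C, level-3 R.
toy_hierarchy_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  gmt <- file.path(dir, "toy.gmt")
  rel <- file.path(dir, "toy_rel.tsv")
  writeLines(c("A\tpathway A\tg1\tg2", "B\tpathway B\tg3"), gmt)
  writeLines(c("C\tA", "C\tB", "R\tC"), rel)
  list(gmt = gmt, rel = rel)
}

toy_masks <- function(genes = c("g1", "g2", "g3")) {
  f <- toy_hierarchy_files()
  build_masks(load_hierarchy(f$gmt, f$rel), genes, depth = 3L)
}

# Small trained pipeline shared across model/explain/activation tests.
small_cohort <- function(seed = 3, effect = 2, n = c(CN = 40, MCI = 50, AD = 30),
                         n_genes = 60) {
  generate_cohort(synthetic_config(n_per_class = n, n_genes = n_genes,
                                   effect_size = effect, seed = seed))
}

small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- small_cohort()
      cache <<- c(run_pipeline(d, triadem_config(seed = 2, max_epochs = 40)),
                  list(cohort = d))
    }
    cache
  }
})

# Independent BFS-from-roots distance oracle over a hierarchy's edge list.
oracle_root_distance <- function(h) {
  ids <- names(h$pathways)
  d <- stats::setNames(rep(Inf, length(ids)), ids)
  d[h$roots] <- 0
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(h$edges))) {
      p <- h$edges$parent[i]; ch <- h$edges$child[i]
      if (d[p] + 1 < d[ch]) { d[ch] <- d[p] + 1; changed <- TRUE }
    }
    if (!changed) break
  }
  d
}

# Descendant-closure gene sets by brute-force DAG traversal.
oracle_closure_genes <- function(h, id) {
  seen <- character(0); frontier <- id
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(h$edges$child[h$edges$parent %in% frontier], seen)
  }
  unique(unlist(h$membership[seen], use.names = FALSE))
}
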