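# Synthetic multimodal cohorts.
#
# The generator emulates the structure the classifier assumes: per-gene
# additive SNP aggregates (sums of binomial(2, MAF) variant draws, with MAF
# shifted by class for planted genes), Gaussian expression with class-shifted
# means for planted genes, and a 45-column clinical schema whose
# cognitive-score-like features are monotone in disease stage, with
# configurable missingness. It also implements the perturbation-based
# validation: multiplicatively reducing selected features for a fraction of
# subjects and re-running the identical pipeline.

#' Configuration for a synthetic cohort
#'
#' Defaults mirror the study conditions: class sizes 212 CN / 317 MCI /
#' 97 AD, 300 genes per omic (a desk-scale stand-in for the full 10,151-gene
#' inputs), 45 clinical columns, 10 planted genes per modality with a mean
#' shift of 2 pooled SDs per class step, minor-allele frequencies in
#' 0.05-0.5, 10% clinical missingness.
#'
#' @param n_per_class Named CN/MCI/AD sample counts.
#' @param n_genes Genes per omic block.
#' @param n_clinical Clinical feature count (>= 30; the schema is padded
#'   with effect-free laboratory columns).
#' @param n_planted Planted (class-associated) genes per modality.
#' @param effect_size Mean shift per class step for planted genes, in pooled
#'   SD units; clinical gradients scale as `effect_size / 2` SDs per step,
#'   so a zero effect size yields a completely signal-free cohort.
#' @param maf_range Minor-allele frequency range for variant draws.
#' @param missingness MCAR missingness fraction on the missingness-prone
#'   clinical columns.
#' @param variant_range Range of variants per gene (drawn uniformly).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `SyntheticCohortConfig` list.
#' @export
synthetic_config <- function(n_per_class = c(CN = 212L, MCI = 317L, AD = 97L),
                             n_genes = 300L, n_clinical = 45L,
                             n_planted = 10L, effect_size = 2.0,
                             maf_range = c(0.05, 0.5), missingness = 0.1,
                             variant_range = c(1L, 8L), seed = 1L) {
  stopifnot(all(n_per_class >= 3L), effect_size >= 0,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            missingness >= 0, missingness < 1,
            n_planted <= n_genes, n_clinical >= 30L)
  structure(list(n_per_class = n_per_class, n_genes = as.integer(n_genes),
                 n_clinical = as.integer(n_clinical),
                 n_planted = as.integer(n_planted),
                 effect_size = effect_size, maf_range = maf_range,
                 missingness = missingness,
                 variant_range = as.integer(variant_range),
                 seed = as.integer(seed)),
            class = "SyntheticCohortConfig")
}

#' Generate a random layered pathway hierarchy over a gene list
#'
#' Three tiers of pathways wired as a DAG: every gene belongs to at least
#' one tier-1 pathway (some to two), every tier-1 pathway has one or two
#' tier-2 parents, every tier-2 pathway one tier-3 parent. Tier-3 pathways
#' are the roots.
#'
#' @param genes Character vector of gene symbols.
#' @param n_l1,n_l2,n_l3 Pathway counts per tier (defaults scale with the
#'   gene count).
#' @param seed Integer seed.
#' @return A `PathwayHierarchy`.
#' @export
generate_hierarchy <- function(genes, n_l1 = max(8L, length(genes) %/% 6L),
                               n_l2 = max(4L, n_l1 %/% 3L),
                               n_l3 = max(2L, n_l2 %/% 2L), seed = 1L) {
  rng <- .seeded_rng(seed)
  l1 <- sprintf("P1_%03d", seq_len(n_l1))
  l2 <- sprintf("P2_%03d", seq_len(n_l2))
  l3 <- sprintf("P3_%03d", seq_len(n_l3))
  membership <- stats::setNames(vector("list", n_l1), l1)
  primary <- l1[rng$sample_int(n_l1, length(genes), replace = TRUE)]
  for (i in seq_along(genes)) {
    membership[[primary[i]]] <- c(membership[[primary[i]]], genes[i])
  }
  extra <- which(rng$runif(length(genes)) < 0.3)
  for (i in extra) {
    p <- l1[rng$sample_int(n_l1, 1)]
    membership[[p]] <- unique(c(membership[[p]], genes[i]))
  }
  empty <- names(membership)[lengths(membership) == 0]
  for (p in empty) membership[[p]] <- genes[rng$sample_int(length(genes), 1)]

  edges <- data.frame(parent = character(0), child = character(0))
  for (p in l1) {
    k <- 1L + (rng$runif(1) < 0.3)
    parents <- l2[rng$sample_int(n_l2, k)]
    edges <- rbind(edges, data.frame(parent = parents, child = p))
  }
  for (p in l2) {
    edges <- rbind(edges, data.frame(parent = l3[rng$sample_int(n_l3, 1)], child = p))
  }
  pathways <- stats::setNames(c(l1, l2, l3), c(l1, l2, l3))
  for (p in c(l2, l3)) membership[[p]] <- character(0)
  structure(list(pathways = pathways, membership = membership,
                 edges = unique(edges),
                 roots = setdiff(unique(edges$parent), unique(edges$child))),
            class = "PathwayHierarchy")
}

#' Write a hierarchy as a GMT file plus a relations TSV
#' @param h A `PathwayHierarchy`.
#' @param gmt_path,relations_path Output paths.
#' @return Invisibly, the paths.
#' @export
write_hierarchy <- function(h, gmt_path, relations_path) {
  # GMT lines need >= 3 fields, so only pathways with gene members are
  # written; membership-less pathways are reconstructed from the relations
  with_genes <- names(h$pathways)[lengths(h$membership[names(h$pathways)]) > 0]
  lines <- vapply(with_genes, function(id) {
    paste(c(id, h$pathways[[id]], h$membership[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, gmt_path)
  utils::write.table(h$edges, relations_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(gmt_path, relations_path))
}

# 45-column clinical schema: name, kind, base mean/sd, per-class-step shift
# direction (in SDs, scaled by the configured gradient), missingness-prone
# flag. Values are loosely modelled on the published cohort tables.
.clinical_schema <- function(n_clinical) {
  base <- data.frame(
    name = c("AGE", "PTGENDER", "PTEDUCAT", "PTETHCAT", "PTRACCAT", "PTMARRY",
             "APOE4",
             "MMSE", "CDRSB", "ADAS11", "ADAS13", "ADASQ4", "MOCA",
             "LDELTOTAL", "TRABSCOR", "FAQ",
             "RAVLT_immediate", "RAVLT_learning", "RAVLT_forgetting",
             "RAVLT_perc_forgetting", "mPACCdigit", "mPACCtrailsB",
             "EcogPtMem", "EcogPtTotal", "EcogSPMem", "EcogSPTotal",
             "Ventricles", "Hippocampus", "Entorhinal", "Fusiform",
             "MidTemp", "ICV", "WholeBrain",
             "FDG", "AV45", "PIB", "TAU", "PTAU", "ABETA"),
    kind = c("cont", "cat2", "cont", "cat2", "cat3", "cat3", "cat3",
             rep("cont", 19), rep("cont", 7), rep("cont", 6)),
    mean = c(73, NA, 16, NA, NA, NA, NA,
             28, 1.5, 9, 14, 4.5, 23, 8, 110, 3,
             37, 4.8, 4.4, 54, -5, -4.5, 2.1, 1.7, 2.1, 1.7,
             38000, 7000, 3600, 18000, 20000, 1520000, 1030000,
             1.25, 1.2, 1.5, 270, 27, 1000),
    sd = c(7, NA, 2.7, NA, NA, NA, NA,
           2, 1.5, 4.5, 5, 2.4, 3.2, 3.6, 60, 4,
           11, 2.5, 2.6, 31, 4.5, 4, 0.7, 0.5, 0.8, 0.6,
           22000, 1100, 680, 2600, 2900, 160000, 110000,
           0.13, 0.22, 0.35, 120, 12, 350),
    shift = c(0.1, NA, 0, NA, NA, NA, NA,
              -1, 1, 1, 1, 1, -1, -1, 0.8, 1,
              -1, -1, 0.3, 1, -1, -1, 0.8, 0.8, 1, 1,
              0.5, -1, -0.8, -0.7, -0.7, 0, -0.5,
              -1, 0.8, 0.5, 0.8, 0.8, -0.8),
    miss = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
             FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
             FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
             FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
             FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
             TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
  n_fill <- n_clinical - nrow(base)
  if (n_fill > 0) {
    base <- rbind(base, data.frame(
      name = sprintf("LAB%02d", seq_len(n_fill)), kind = "cont",
      mean = 10, sd = 2, shift = 0, miss = FALSE))
  } else if (n_fill < 0) {
    base <- base[seq_len(n_clinical), , drop = FALSE]
  }
  base
}

#' Generate a multimodal synthetic cohort
#'
#' @param cfg A `SyntheticCohortConfig`.
#' @param hierarchy Optional `PathwayHierarchy` over the cohort's genes; one
#'   is generated (seeded from `cfg$seed`) when omitted.
#' @return A `CohortDataset`: sample ids, `genotype` (per-gene additive
#'   aggregates), `expression`, `clinical` (data.frame with NAs), `labels`,
#'   the variant-level `calls` and `variant_map` behind the genotype block,
#'   the `hierarchy`, and a `manifest` recording planted features,
#'   categorical columns and the config.
#' @export
generate_cohort <- function(cfg = synthetic_config(), hierarchy = NULL) {
  stopifnot(inherits(cfg, "SyntheticCohortConfig"))
  rng <- .seeded_rng(cfg$seed)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  if (is.null(hierarchy)) hierarchy <- generate_hierarchy(genes, seed = cfg$seed + 101L)
  labels <- rep(names(cfg$n_per_class), cfg$n_per_class)
  n <- length(labels)
  samples <- sprintf("S%04d", seq_len(n))
  class_idx <- match(labels, .CLASS_ORDER) - 1L   # 0,1,2

  planted_snp <- genes[rng$sample_int(cfg$n_genes, cfg$n_planted)]
  planted_expr <- genes[rng$sample_int(cfg$n_genes, cfg$n_planted)]

  # ---- genotype: binomial variant draws aggregated per gene ----
  n_var <- cfg$variant_range[1] +
    rng$sample_int(cfg$variant_range[2] - cfg$variant_range[1] + 1L,
                   cfg$n_genes, replace = TRUE) - 1L
  variant_map <- data.frame(
    variant_id = unlist(lapply(seq_len(cfg$n_genes), function(g)
      sprintf("rs%d_%d", g, seq_len(n_var[g])))),
    gene_symbol = rep(genes, n_var))
  mafs <- rng$runif(nrow(variant_map), cfg$maf_range[1], cfg$maf_range[2])
  calls <- matrix(0L, n, nrow(variant_map),
                  dimnames = list(samples, variant_map$variant_id))
  gene_of <- variant_map$gene_symbol
  for (g in seq_len(cfg$n_genes)) {
    vidx <- which(gene_of == genes[g])
    k <- length(vidx)
    # per-step MAF shift that moves the gene aggregate by effect_size
    # pooled SDs per class step (clamped to keep MAFs valid)
    delta <- if (genes[g] %in% planted_snp) {
      sd_gene <- sqrt(sum(2 * mafs[vidx] * (1 - mafs[vidx])))
      cfg$effect_size * sd_gene / (2 * k)
    } else 0
    for (ci in 0:2) {
      rows <- which(class_idx == ci)
      if (!length(rows)) next
      m <- pmin(pmax(mafs[vidx] + ci * delta, 0.01), 0.97)
      draws <- rng$rbinom(length(rows) * k, 2L, rep(m, each = length(rows)))
      calls[rows, vidx] <- matrix(draws, length(rows), k)
    }
  }
  genotype <- encode_snps(calls, variant_map)

  # ---- expression: Gaussian, class-shifted means for planted genes ----
  mu_e <- rng$runif(cfg$n_genes, 5, 9)
  sd_e <- rng$runif(cfg$n_genes, 0.4, 1.2)
  expression <- matrix(rng$rnorm(n * cfg$n_genes), n, cfg$n_genes,
                       dimnames = list(samples, genes))
  expression <- sweep(expression, 2, sd_e, "*")
  expression <- sweep(expression, 2, mu_e, "+")
  sel <- match(planted_expr, genes)
  for (g in sel) {
    expression[, g] <- expression[, g] + class_idx * cfg$effect_size * sd_e[g]
  }

  # ---- clinical: 45-column schema with monotone stage gradients ----
  schema <- .clinical_schema(cfg$n_clinical)
  grad <- cfg$effect_size / 2    # SDs per class step for graded features
  clinical <- as.data.frame(stats::setNames(
    lapply(seq_len(nrow(schema)), function(i) {
      s <- schema[i, ]
      if (s$kind == "cont") {
        v <- rng$rnorm(n, s$mean, s$sd) + class_idx * s$shift * grad * s$sd
        round(v, 3)
      } else if (s$name == "APOE4") {
        p <- pmin(pmax(0.15 + 0.12 * class_idx * grad, 0.02), 0.9)
        rng$rbinom(n, 2L, p)
      } else if (s$name == "PTGENDER") {
        p <- pmin(pmax(0.5 - 0.06 * class_idx * grad, 0.05), 0.95)
        rng$rbinom(n, 1L, p)
      } else {
        nlev <- if (s$kind == "cat3") 3L else 2L
        rng$sample_int(nlev, n, replace = TRUE) - 1L
      }
    }), schema$name), row.names = samples)
  if (cfg$missingness > 0) {
    for (j in which(schema$miss)) {
      hit <- rng$runif(n) < cfg$missingness
      clinical[hit, j] <- NA
    }
  }

  structure(list(samples = samples, genotype = genotype,
                 expression = expression, clinical = clinical,
                 labels = labels, calls = calls, variant_map = variant_map,
                 hierarchy = hierarchy,
                 manifest = list(
                   config = unclass(cfg),
                   expression_mean = mu_e, expression_sd = sd_e,
                   variant_mafs = stats::setNames(mafs, variant_map$variant_id),
                   planted_snp = planted_snp, planted_expr = planted_expr,
                   clinical_graded = schema$name[!is.na(schema$shift) & schema$shift != 0],
                   categorical = schema$name[schema$kind != "cont"])),
            class = "CohortDataset")
}

#' @export
print.CohortDataset <- function(x, ...) {
  cat("CohortDataset:", length(x$samples), "samples (",
      paste(names(table(x$labels)), table(x$labels), collapse = ", "), ");",
      ncol(x$genotype), "SNP-aggregate genes,", ncol(x$expression),
      "expression genes,", ncol(x$clinical), "clinical features\n")
  invisible(x)
}

#' Build the connectivity masks for a cohort's gene list
#' @param d A `CohortDataset`.
#' @param depth Pathway levels (default 3).
#' @return A `MaskStack` (shared by both omics blocks, which carry the same
#'   gene axis).
#' @export
cohort_masks <- function(d, depth = 3L) {
  build_masks(d$hierarchy, colnames(d$genotype), depth = depth)
}

#' Multiplicatively perturb selected features for a fraction of subjects
#'
#' Each spec names a feature and modality, a multiplicative reduction range,
#' an affected-subject fraction and a subject pool (default the CN class).
#' Exactly `round(fraction * pool size)` subjects are drawn without
#' replacement and each selected value is multiplied by `1 - u` with `u`
#' drawn per subject uniformly in the range. Overlapping specs on one
#' feature are applied sequentially with a warning.
#'
#' @param d A `CohortDataset`.
#' @param specs List of specs: `list(feature=, modality=, reduction=c(lo,hi),
#'   fraction=0.5, pool="CN")`; modality in snp/expression/clinical, pool a
#'   class label or `"all"`.
#' @param seed Integer seed for subject and factor draws.
#' @return The perturbed `CohortDataset` with a `perturbation_log`
#'   data.frame attached.
#' @export
perturb_features <- function(d, specs, seed = 1L) {
  stopifnot(inherits(d, "CohortDataset"))
  rng <- .seeded_rng(seed)
  keys <- vapply(specs, function(s) paste(s$modality, s$feature), character(1))
  if (anyDuplicated(keys)) {
    warning("overlapping perturbation specs on: ",
            paste(unique(keys[duplicated(keys)]), collapse = ", "),
            "; applied sequentially")
  }
  log <- data.frame()
  for (s in specs) {
    modality <- match.arg(s$modality, c("snp", "expression", "clinical"))
    reduction <- s$reduction
    stopifnot(length(reduction) == 2L, reduction[1] > 0, reduction[2] < 1,
              reduction[1] <= reduction[2])
    fraction <- if (is.null(s$fraction)) 0.5 else s$fraction
    pool <- if (is.null(s$pool)) "CN" else s$pool
    idx <- if (identical(pool, "all")) seq_along(d$labels) else which(d$labels == pool)
    if (!length(idx)) stop("empty subject pool '", pool, "'")
    n_sel <- round(fraction * length(idx))
    sel <- idx[rng$sample_int(length(idx), n_sel)]
    u <- rng$runif(n_sel, reduction[1], reduction[2])
    get_col <- function() switch(modality,
      snp = d$genotype[sel, s$feature],
      expression = d$expression[sel, s$feature],
      clinical = d$clinical[sel, s$feature])
    if (modality == "snp") {
      if (!s$feature %in% colnames(d$genotype)) stop("unknown SNP gene: ", s$feature)
      d$genotype[sel, s$feature] <- d$genotype[sel, s$feature] * (1 - u)
    } else if (modality == "expression") {
      if (!s$feature %in% colnames(d$expression)) stop("unknown expression gene: ", s$feature)
      d$expression[sel, s$feature] <- d$expression[sel, s$feature] * (1 - u)
    } else {
      if (!s$feature %in% names(d$clinical)) stop("unknown clinical feature: ", s$feature)
      d$clinical[sel, s$feature] <- d$clinical[sel, s$feature] * (1 - u)
    }
    log <- rbind(log, data.frame(feature = s$feature, modality = modality,
                                 pool = pool, n_modified = n_sel,
                                 mean_factor = mean(1 - u)))
  }
  d$perturbation_log <- log
  d
}

#' Two-sample Kolmogorov-Smirnov preservation check
#'
#' @param original,perturbed Numeric vectors (>= 2 observations each).
#' @param alpha Preservation threshold on the p-value (default 0.05).
#' @return List (statistic, p, preserved): `preserved` is `TRUE` when the
#'   perturbed sample is not distinguishable from the original at `alpha`.
#' @export
ks_preservation_check <- function(original, perturbed, alpha = 0.05) {
  stopifnot(length(original) >= 2L, length(perturbed) >= 2L)
  kt <- suppressWarnings(stats::ks.test(original, perturbed))
  list(statistic = unname(kt$statistic), p = unname(kt$p.value),
       preserved = kt$p.value >= alpha)
}

#' Preprocess, build, train and evaluate on one cohort
#'
#' Convenience wrapper running the fixed pipeline: masks -> preprocessing
#' (split/SMOTE/scale seeded from `cfg$seed`) -> model build -> training ->
#' test-split evaluation.
#'
#' @param d A `CohortDataset`.
#' @param cfg A `TriademConfig`.
#' @param constrained Build the mask-constrained model (default) or the
#'   dense unconstrained baseline.
#' @param masks Optional precomputed `MaskStack` (built from the cohort's
#'   hierarchy when omitted).
#' @param processed Optional precomputed `ProcessedCohort`.
#' @return List (model, processed, masks, metrics) with `metrics` the
#'   test-split `MetricsReport`.
#' @export
run_pipeline <- function(d, cfg = triadem_config(), constrained = TRUE,
                         masks = NULL, processed = NULL) {
  if (is.null(masks)) masks <- cohort_masks(d, cfg$depth)
  if (is.null(processed)) {
    processed <- preprocess_cohort(d$genotype, d$expression, d$clinical,
                                   d$labels,
                                   categorical = d$manifest$categorical,
                                   seed = cfg$seed)
  }
  n_clin <- processed$widths[["clinical"]]
  model <- if (constrained) build_model(masks, masks, n_clin, cfg)
           else build_unconstrained_baseline(masks, masks, n_clin, cfg)
  model <- train_triadem(model, processed)
  metrics <- evaluate_model(model, processed$test$x, processed$test$labels)
  list(model = model, processed = processed, masks = masks, metrics = metrics)
}

#' Perturbation-based validation: identical pipeline before and after
#'
#' Trains and evaluates on the original and the perturbed cohort with
#' identical seeds and splits, and reports the metric deltas plus a
#' Kolmogorov-Smirnov preservation table for every perturbed feature.
#'
#' @param d A `CohortDataset`.
#' @param specs Perturbation specs as for [perturb_features()].
#' @param cfg A `TriademConfig` (the shared seed lives here).
#' @param perturb_seed Seed for the perturbation draws.
#' @return List (before, after, ks_table, delta) where `delta` holds the
#'   after-minus-before accuracy, macro F1 and macro AUC.
#' @export
simulated_validation_run <- function(d, specs, cfg = triadem_config(),
                                     perturb_seed = 1L) {
  masks <- cohort_masks(d, cfg$depth)
  before <- run_pipeline(d, cfg, masks = masks)
  d2 <- perturb_features(d, specs, seed = perturb_seed)
  after <- run_pipeline(d2, cfg, masks = masks)
  ks_table <- do.call(rbind, lapply(specs, function(s) {
    orig <- switch(s$modality, snp = d$genotype[, s$feature],
                   expression = d$expression[, s$feature],
                   clinical = d$clinical[[s$feature]])
    pert <- switch(s$modality, snp = d2$genotype[, s$feature],
                   expression = d2$expression[, s$feature],
                   clinical = d2$clinical[[s$feature]])
    ks <- ks_preservation_check(orig[!is.na(orig)], pert[!is.na(pert)])
    data.frame(feature = s$feature, modality = s$modality,
               statistic = ks$statistic, p = ks$p, preserved = ks$preserved)
  }))
  delta <- list(
    accuracy = after$metrics$accuracy - before$metrics$accuracy,
    macro_F1 = after$metrics$macro$F1 - before$metrics$macro$F1,
    macro_AUC = after$metrics$macro$AUC - before$metrics$macro$AUC)
  list(before = before$metrics, after = after$metrics,
       ks_table = ks_table, delta = delta,
       perturbation_log = d2$perturbation_log)
}

#' Write a cohort's pipeline input files to a directory
#'
#' Emits every format the pipeline reads: variant-level calls TSV plus the
#' variant-to-gene map, expression TSV, clinical CSV, labels CSV, the
#' hierarchy (GMT + relations TSV) and a manifest JSON with the config echo
#' and planted features (used by tests as ground truth).
#'
#' @param d A `CohortDataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(d, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f, ...) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, ...)
  w(d$calls, "genotype_calls.tsv", col.names = NA)
  w(d$variant_map, "variant_map.tsv", row.names = FALSE)
  w(d$expression, "expression.tsv", col.names = NA)
  utils::write.csv(d$clinical, file.path(dir, "clinical.csv"), row.names = TRUE)
  utils::write.csv(data.frame(sample = d$samples, label = d$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  write_hierarchy(d$hierarchy, file.path(dir, "pathways.gmt"),
                  file.path(dir, "relations.tsv"))
  jsonlite::write_json(d$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir Directory path.
#' @return A `CohortDataset`.
#' @export
read_cohort <- function(dir) {
  calls <- as.matrix(utils::read.table(file.path(dir, "genotype_calls.tsv"),
                                       sep = "\t", header = TRUE, row.names = 1,
                                       check.names = FALSE))
  variant_map <- utils::read.table(file.path(dir, "variant_map.tsv"),
                                   sep = "\t", header = TRUE,
                                   colClasses = "character")
  expression <- as.matrix(utils::read.table(file.path(dir, "expression.tsv"),
                                            sep = "\t", header = TRUE,
                                            row.names = 1, check.names = FALSE))
  clinical <- utils::read.csv(file.path(dir, "clinical.csv"), row.names = 1)
  lab <- utils::read.csv(file.path(dir, "labels.csv"))
  hierarchy <- load_hierarchy(file.path(dir, "pathways.gmt"),
                              file.path(dir, "relations.tsv"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  structure(list(samples = lab$sample, genotype = encode_snps(calls, variant_map),
                 expression = expression, clinical = clinical,
                 labels = lab$label, calls = calls, variant_map = variant_map,
                 hierarchy = hierarchy, manifest = manifest),
            class = "CohortDataset")
}
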