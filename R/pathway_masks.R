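# Pathway hierarchy parsing and binary connectivity masks.
#
# The two omics subnetworks are constrained by a gene -> pathway -> pathway
# hierarchy (Reactome-style): gene-set memberships come from a GMT file and
# pathway parent-child relations from a two-column TSV. These are turned into
# a stack of binary matrices (the MaskStack) that fixes which connections
# exist in a subnetwork.

#' Load a pathway hierarchy from a GMT file and a relations table
#'
#' Reads gene-set memberships from a GMT file (tab-separated: pathway id,
#' description, then gene symbols) and directed parent-child pathway
#' relations from a two-column TSV (parent, child). Pathways referenced only
#' in the relations file are retained with empty membership.
#'
#' @param gmt_path Path to the GMT gene-set file.
#' @param relations_path Path to the parent-child relations TSV (no header).
#' @param case_fold If `TRUE`, gene symbols are upper-cased on read; by
#'   default symbols are matched case-sensitively after whitespace trimming.
#' @return A `PathwayHierarchy` object: a list with `pathways` (named
#'   character vector, id -> display name), `membership` (named list,
#'   id -> character vector of gene symbols), `edges` (data.frame with
#'   columns `parent`, `child`) and `roots` (pathway ids that appear as a
#'   parent but never as a child).
#' @export
load_hierarchy <- function(gmt_path, relations_path, case_fold = FALSE) {
  lines <- readLines(gmt_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pathways <- character(0)
  membership <- list()
  for (i in seq_along(lines)) {
    fields <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1]])
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(fields)))
    }
    id <- fields[[1]]
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (case_fold) genes <- toupper(genes)
    pathways[[id]] <- fields[[2]]
    membership[[id]] <- unique(genes)
  }

  rel <- tryCatch(
    utils::read.table(relations_path, sep = "\t", header = FALSE,
                      col.names = c("parent", "child"),
                      colClasses = "character", quote = ""),
    error = function(e) data.frame(parent = character(0), child = character(0),
                                   stringsAsFactors = FALSE)
  )
  rel$parent <- trimws(rel$parent)
  rel$child <- trimws(rel$child)
  rel <- unique(rel[nzchar(rel$parent) & nzchar(rel$child), , drop = FALSE])
  rownames(rel) <- NULL
  if (any(rel$parent == rel$child)) {
    stop("self-loop in pathway relations: ",
         paste(rel$parent[rel$parent == rel$child], collapse = ", "))
  }

  # pathways seen only in relations get an empty membership entry
  extra <- setdiff(unique(c(rel$parent, rel$child)), names(pathways))
  for (id in extra) {
    pathways[[id]] <- id
    membership[[id]] <- character(0)
  }

  h <- structure(
    list(pathways = pathways, membership = membership, edges = rel,
         roots = setdiff(unique(rel$parent), unique(rel$child))),
    class = "PathwayHierarchy")
  .check_acyclic(h)
  h
}

# Kahn topological check; stops on a cycle.
.check_acyclic <- function(h) {
  rel <- h$edges
  if (nrow(rel) == 0L) return(invisible(TRUE))
  nodes <- unique(c(rel$parent, rel$child))
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(rel$child)
  indeg[names(tab)] <- as.integer(tab)
  out <- split(rel$child, rel$parent)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (w in out[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (seen < length(nodes)) {
    stop("cycle detected in pathway relations (",
         length(nodes) - seen, " pathways on cycles)")
  }
  invisible(TRUE)
}

#' Assign a layer level to every pathway
#'
#' Levels run 1..`depth`, with level `depth` the most general (root-adjacent)
#' pathways and level 1 the most specific, gene-adjacent ones. The rule is
#' `level = depth - min(d, depth - 1)` where `d` is the breadth-first
#' distance from the nearest root, so pathways deeper than the cut collapse
#' onto level 1. Pathways unreachable from any root (including all pathways
#' when the relations table is empty) are placed at level 1 and listed in a
#' warning.
#'
#' @param h A `PathwayHierarchy`.
#' @param depth Number of pathway layers (default 3).
#' @return Named integer vector, pathway id -> level in 1..depth.
#' @export
assign_levels <- function(h, depth = 3L) {
  stopifnot(inherits(h, "PathwayHierarchy"), depth >= 1L)
  ids <- names(h$pathways)
  dist <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  out <- split(h$edges$child, h$edges$parent)
  queue <- intersect(h$roots, ids)
  dist[queue] <- 0L
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (w in out[[v]]) {
      if (is.na(dist[[w]])) {
        dist[[w]] <- dist[[v]] + 1L
        queue <- c(queue, w)
      }
    }
  }
  unreachable <- ids[is.na(dist)]
  if (length(unreachable)) {
    warning(length(unreachable),
            " pathway(s) unreachable from any root assigned to level 1: ",
            paste(utils::head(unreachable, 5), collapse = ", "),
            if (length(unreachable) > 5) ", ..." else "")
    dist[unreachable] <- depth - 1L   # forces level 1
  }
  lev <- depth - pmin(dist, depth - 1L)
  storage.mode(lev) <- "integer"
  lev
}

#' Build the layered binary connectivity masks for one subnetwork
#'
#' Produces the `MaskStack`: `masks[[1]]` is genes x level-1 pathways, with a
#' 1 where the gene is annotated to the pathway or to any of its descendants
#' (memberships are up-propagated through the descendant closure);
#' `masks[[l]]` for l > 1 is level-(l-1) x level-l with a 1 where the level-l
#' pathway is a parent of the level-(l-1) pathway. Level-1 pathways that end
#' up with no connected gene are dropped, and upper-level pathways left with
#' no incoming connection are pruned in turn.
#'
#' @param h A `PathwayHierarchy`.
#' @param gene_list Ordered, unique gene symbols defining the input axis.
#'   Genes with no annotation keep an all-zero row so the input width always
#'   equals `length(gene_list)`.
#' @param depth Number of pathway layers (default 3).
#' @return A `MaskStack`: list with `gene_order`, `level_orders` (list of
#'   pathway-id vectors, one per level) and `masks` (list of 0/1 matrices).
#' @export
build_masks <- function(h, gene_list, depth = 3L) {
  stopifnot(inherits(h, "PathwayHierarchy"))
  gene_list <- trimws(gene_list)
  if (length(gene_list) == 0L) stop("gene_list is empty")
  if (anyDuplicated(gene_list)) {
    stop("duplicate genes in gene_list: ",
         paste(unique(gene_list[duplicated(gene_list)]), collapse = ", "))
  }
  lev <- suppressWarnings(assign_levels(h, depth))
  ids_by_level <- split(names(lev), lev)

  # descendant closure memberships (union of own + all descendants' genes)
  out <- split(h$edges$child, h$edges$parent)
  closure_genes <- function(id) {
    seen <- character(0); stack <- id
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (v %in% seen) next
      seen <- c(seen, v)
      stack <- c(stack, setdiff(out[[v]], seen))
    }
    unique(unlist(h$membership[seen], use.names = FALSE))
  }

  l1 <- ids_by_level[["1"]]
  if (is.null(l1) || !length(l1)) stop("no pathways at level 1: empty constraint layer")
  m0 <- matrix(0, nrow = length(gene_list), ncol = length(l1),
               dimnames = list(gene_list, l1))
  for (p in l1) {
    g <- intersect(closure_genes(p), gene_list)
    m0[g, p] <- 1
  }
  keep <- colSums(m0) > 0
  if (!any(keep)) stop("empty constraint: no gene in gene_list is annotated to any pathway")
  m0 <- m0[, keep, drop = FALSE]

  level_orders <- list(colnames(m0))
  masks <- list(m0)
  if (depth >= 2L) {
    parent_of <- split(h$edges$parent, h$edges$child)
    for (l in 2:depth) {
      lower <- level_orders[[l - 1L]]
      upper <- ids_by_level[[as.character(l)]]
      if (is.null(upper) || !length(upper)) {
        stop("no pathways at level ", l, ": hierarchy too shallow for depth ", depth)
      }
      m <- matrix(0, nrow = length(lower), ncol = length(upper),
                  dimnames = list(lower, upper))
      for (p in lower) {
        q <- intersect(parent_of[[p]], upper)
        m[p, q] <- 1
      }
      keep <- colSums(m) > 0
      if (!any(keep)) stop("no pathway at level ", l, " receives any connection")
      m <- m[, keep, drop = FALSE]
      level_orders[[l]] <- colnames(m)
      masks[[l]] <- m
    }
  }
  structure(list(gene_order = gene_list, level_orders = level_orders,
                 masks = masks),
            class = "MaskStack")
}

#' Per-level node and connection counts of a MaskStack
#'
#' @param m A `MaskStack`.
#' @return A data.frame with one row per layer (level 0 = genes) giving node
#'   counts and incoming constrained connections; the total connection count
#'   is in attribute `total_connections`.
#' @export
mask_stats <- function(m) {
  stopifnot(inherits(m, "MaskStack"))
  nz <- vapply(m$masks, function(x) sum(x != 0), numeric(1))
  df <- data.frame(
    level = 0:length(m$masks),
    n_nodes = c(length(m$gene_order),
                vapply(m$level_orders, length, integer(1))),
    incoming_connections = c(0, nz))
  attr(df, "total_connections") <- sum(nz)
  df
}

#' @export
print.MaskStack <- function(x, ...) {
  st <- mask_stats(x)
  cat("MaskStack:", length(x$masks), "constrained layer(s);",
      length(x$gene_order), "genes ->",
      paste(st$n_nodes[-1], collapse = " -> "), "pathway nodes;",
      attr(st, "total_connections"), "connections\n")
  invisible(x)
}

#' Write a MaskStack as a sparse edge list plus node-order sidecar
#'
#' The edge list is a TSV with columns `level`, `row_id`, `col_id`, one row
#' per nonzero mask entry; node orders go to a JSON sidecar so the stack can
#' be reconstructed exactly.
#'
#' @param m A `MaskStack`.
#' @param prefix Output path prefix; writes `<prefix>_edges.tsv` and
#'   `<prefix>_nodes.json`.
#' @return Invisibly, the two file paths.
#' @export
write_mask_stack <- function(m, prefix) {
  stopifnot(inherits(m, "MaskStack"))
  edges <- do.call(rbind, lapply(seq_along(m$masks), function(l) {
    idx <- which(m$masks[[l]] != 0, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(level = l,
               row_id = rownames(m$masks[[l]])[idx[, 1]],
               col_id = colnames(m$masks[[l]])[idx[, 2]])
  }))
  edge_path <- paste0(prefix, "_edges.tsv")
  node_path <- paste0(prefix, "_nodes.json")
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(gene_order = m$gene_order,
                            level_orders = m$level_orders),
                       node_path)
  invisible(c(edge_path, node_path))
}

#' Read a MaskStack written by [write_mask_stack()]
#' @param prefix Path prefix used when writing.
#' @return A `MaskStack`.
#' @export
read_mask_stack <- function(prefix) {
  edges <- utils::read.table(paste0(prefix, "_edges.tsv"), sep = "\t",
                             header = TRUE, colClasses = c("integer", "character", "character"))
  nodes <- jsonlite::read_json(paste0(prefix, "_nodes.json"), simplifyVector = TRUE)
  level_orders <- as.list(nodes$level_orders)
  masks <- vector("list", length(level_orders))
  rows <- nodes$gene_order
  for (l in seq_along(level_orders)) {
    cols <- level_orders[[l]]
    m <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
    e <- edges[edges$level == l, , drop = FALSE]
    if (nrow(e)) m[cbind(e$row_id, e$col_id)] <- 1
    masks[[l]] <- m
    rows <- cols
  }
  structure(list(gene_order = nodes$gene_order, level_orders = level_orders,
                 masks = masks),
            class = "MaskStack")
}

#' Write each mask of a stack as a dense 0/1 TSV matrix
#' @param m A `MaskStack`.
#' @param prefix Output prefix; writes `<prefix>_mask<level>.tsv` per level.
#' @return Invisibly, the file paths.
#' @export
write_mask_dense <- function(m, prefix) {
  stopifnot(inherits(m, "MaskStack"))
  paths <- vapply(seq_along(m$masks), function(l) {
    p <- paste0(prefix, "_mask", l, ".tsv")
    utils::write.table(m$masks[[l]], p, sep = "\t", quote = FALSE,
                       col.names = NA)
    p
  }, character(1))
  invisible(paths)
}
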