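#' Build a cladogram of means
#'
#' Arranges the features of a processed taxa table as the leaves of the
#' taxonomy tree and computes, bottom-up, every internal node's per-sample
#' value as the unweighted mean of its direct children. Multiple kingdoms
#' yield a forest. A feature whose full path coincides with an internal
#' node (an unresolved taxon whose finer relatives are also observed) is
#' attached as a direct leaf child of that node and enters its mean with
#' unit weight.
#'
#' @param table a processed [taxa_table()] (`value_kind != "raw"`).
#' @return object of class `cladogram`: list with `paths` (canonical
#'   taxonomy strings), `depth`, `parent` (index, `NA` for roots),
#'   `is_leaf`, and `values` (nodes x samples matrix).
#' @export
build_cladogram <- function(table) {
  stopifnot(inherits(table, "taxa_table"))
  if (table$value_kind == "raw")
    stop("build_cladogram() expects a processed (non-raw) table")
  leaf_paths <- colnames(table$values)
  if (anyDuplicated(leaf_paths))
    stop("two features share the full path ",
         leaf_paths[duplicated(leaf_paths)][1L])
  split_paths <- strsplit(leaf_paths, ";", fixed = TRUE)
  internal <- unique(unlist(lapply(split_paths, function(p) {
    d <- length(p)
    if (d <= 1L) return(character(0L))
    vapply(seq_len(d - 1L), function(k) paste(p[seq_len(k)], collapse = ";"),
           character(1L))
  })))
  # node table: internals first, then leaves; path-sorted for determinism
  internal <- sort(internal)
  leaf_order <- order(leaf_paths)
  paths <- c(internal, leaf_paths[leaf_order])
  is_leaf <- c(rep(FALSE, length(internal)),
               rep(TRUE, length(leaf_paths)))
  depth <- path_depth(paths)
  n_int <- length(internal)
  int_index <- stats::setNames(seq_len(n_int), internal)
  parent <- rep(NA_integer_, length(paths))
  for (i in seq_along(paths)) {
    if (is_leaf[i] && !is.na(int_index[paths[i]])) {
      parent[i] <- int_index[[paths[i]]]      # unresolved-leaf collision
    } else {
      pp <- path_parent(paths[i])
      if (!is.na(pp)) parent[i] <- int_index[[pp]]
    }
  }
  values <- matrix(NA_real_, nrow = length(paths), ncol = nrow(table$values),
                   dimnames = list(NULL, rownames(table$values)))
  values[is_leaf, ] <- t(table$values[, leaf_paths[leaf_order],
                                      drop = FALSE])
  for (i in order(depth[seq_len(n_int)], decreasing = TRUE)) {
    kids <- which(parent == i)
    values[i, ] <- colMeans(values[kids, , drop = FALSE])
  }
  structure(list(paths = paths, depth = depth, parent = parent,
                 is_leaf = is_leaf, values = values,
                 sample_ids = rownames(table$values),
                 max_depth = max(depth)),
            class = "cladogram")
}

#' @export
print.cladogram <- function(x, ...) {
  cat("Cladogram of means:", length(x$paths), "nodes (",
      sum(x$is_leaf), "leaves ),", length(x$sample_ids), "samples, depth",
      max(x$depth), "\n")
  invisible(x)
}

#' Nodes of a cladogram at a taxonomy depth
#'
#' @param clad a [build_cladogram()] result.
#' @param depth taxonomy depth (1 = kingdom).
#' @param leaves_only if `TRUE`, restrict to leaf nodes.
#' @return integer node indices in path-sorted order.
#' @export
nodes_at_depth <- function(clad, depth, leaves_only = FALSE) {
  stopifnot(inherits(clad, "cladogram"))
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1L ||
      depth > clad$max_depth)
    stop("depth must be in 1..", clad$max_depth)
  idx <- which(clad$depth == as.integer(depth) &
               (!leaves_only | clad$is_leaf))
  idx[order(clad$paths[idx], clad$is_leaf[idx])]
}

clado_children <- function(clad, node) which(clad$parent == node)

#' Cladogram node values in long format
#'
#' @param clad a cladogram.
#' @return data.frame with `node_path`, `depth`, `is_leaf`, `sample_id`,
#'   `value`.
#' @export
clado_values <- function(clad) {
  stopifnot(inherits(clad, "cladogram"))
  n <- length(clad$paths)
  s <- length(clad$sample_ids)
  data.frame(node_path = rep(clad$paths, each = s),
             depth = rep(clad$depth, each = s),
             is_leaf = rep(clad$is_leaf, each = s),
             sample_id = rep(clad$sample_ids, times = n),
             value = as.vector(t(clad$values)),
             stringsAsFactors = FALSE)
}

#' Export the cladogram topology as Newick
#'
#' Node labels are the last rank name (non-alphanumeric characters
#' replaced by `_`); the string is one tree per kingdom, semicolon
#' terminated.
#'
#' @param clad a cladogram.
#' @return character vector, one Newick string per root.
#' @export
clado_newick <- function(clad) {
  stopifnot(inherits(clad, "cladogram"))
  lab <- function(i) {
    parts <- strsplit(clad$paths[i], ";", fixed = TRUE)[[1L]]
    gsub("[^A-Za-z0-9_.]", "_", parts[length(parts)])
  }
  rec <- function(i) {
    kids <- clado_children(clad, i)
    if (length(kids) == 0L) return(lab(i))
    paste0("(", paste(vapply(kids, rec, character(1L)), collapse = ","),
           ")", lab(i))
  }
  roots <- which(is.na(clad$parent))
  vapply(roots, function(r) paste0(rec(r), ";"), character(1L))
}
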