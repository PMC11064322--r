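node_label_test <- function(values, labels) {
  y <- labels$values
  if (labels$kind == "binary") {
    mann_whitney(values[y == 1], values[y == 0])
  } else {
    spearman_test(values, y)
  }
}

#' A priori scan: is the label microbially explainable?
#'
#' Applies the nested label-effect test ([nested_label_test()]) at depths
#' 1, 2, ... until the first significant depth (p < `alpha`) or the
#' deepest level of the cladogram. A label with no significant depth is
#' deemed not microbially explainable and the per-taxon analysis is
#' skipped entirely.
#'
#' @param clad a [build_cladogram()] result.
#' @param labels a [label_vector()].
#' @param alpha significance level in (0, 1), default 0.05.
#' @return list with `per_depth_p` (named by depth, one entry per depth
#'   actually tested), `first_significant_depth` (`NA` if none) and
#'   `explainable`.
#' @export
apriori_scan <- function(clad, labels, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  per_depth <- numeric(0L)
  first_sig <- NA_integer_
  for (d in seq_len(clad$max_depth)) {
    p <- nested_label_test(clad, labels, d)$p_value
    per_depth[as.character(d)] <- p
    if (p < alpha) {
      first_sig <- d
      break
    }
  }
  list(per_depth_p = per_depth, first_significant_depth = first_sig,
       explainable = !is.na(first_sig))
}

#' Sister multiple-measurement correction
#'
#' Among the children of one significant mother, the most significant
#' child (minimum p, ties broken lexicographically by name) is kept if its
#' raw p is below `alpha`; a Benjamini-Hochberg adjustment is applied to
#' all remaining children, and a remaining child survives only if both its
#' raw and adjusted p are below `alpha`.
#'
#' @param child_p named numeric vector of raw child p-values.
#' @param alpha significance level.
#' @return character vector of surviving child names.
#' @export
sister_correct <- function(child_p, alpha = 0.05) {
  if (length(child_p) == 0L) stop("child_p must be non-empty")
  if (is.null(names(child_p)) || anyDuplicated(names(child_p)))
    stop("child_p must be uniquely named")
  if (anyNA(child_p) || any(child_p < 0 | child_p > 1))
    stop("p-values must lie in [0, 1]")
  ord <- order(child_p, names(child_p))
  best <- ord[1L]
  survivors <- character(0L)
  if (child_p[best] < alpha) survivors <- names(child_p)[best]
  rest <- setdiff(seq_along(child_p), best)
  if (length(rest) > 0L) {
    adj <- adjust_pvalues(child_p[rest], "bh")
    keep <- child_p[rest] < alpha & adj < alpha
    survivors <- c(survivors, names(child_p)[rest][keep])
  }
  survivors
}

empty_taxa <- function() {
  data.frame(path = character(0L), depth = integer(0L),
             p_value = numeric(0L), adjusted_p = numeric(0L),
             direction = integer(0L), source = character(0L),
             stringsAsFactors = FALSE)
}

taxa_row <- function(clad, node, out, adjusted_p, source) {
  data.frame(path = clad$paths[node], depth = clad$depth[node],
             p_value = out$p_value, adjusted_p = adjusted_p,
             direction = out$direction, source = source,
             stringsAsFactors = FALSE)
}

#' Trajectory test along the cladogram
#'
#' Tests every node at `start_level` (Mann-Whitney for binary labels,
#' Spearman for continuous), corrects across that level only, then
#' descends: children of each significant node are tested at the raw
#' `alpha` threshold subject to the sister correction
#' ([sister_correct()]), and the descent recurses into survivors. Every
#' visited significant node is reported; no further level-wide correction
#' is applied below the start level.
#'
#' @param clad a [build_cladogram()] result.
#' @param labels a joined [label_vector()].
#' @param alpha significance level.
#' @param start_level taxonomy level at which the corrected scan starts.
#' @param first_level_correction `"bonferroni"` (default) or `"bh"`.
#' @return data.frame of significant taxa (`path`, `depth`, `p_value`,
#'   `adjusted_p`, `direction`, `source = "trajectory"`).
#' @export
trajectory_test <- function(clad, labels, alpha = 0.05, start_level = 1L,
                            first_level_correction = c("bonferroni", "bh")) {
  first_level_correction <- match.arg(first_level_correction)
  if (start_level < 1L || start_level > clad$max_depth)
    stop("start_level must be in 1..", clad$max_depth)
  top <- nodes_at_depth(clad, start_level)
  if (length(top) == 0L) return(empty_taxa())
  outs <- lapply(top, function(i) node_label_test(clad$values[i, ], labels))
  p <- vapply(outs, `[[`, numeric(1L), "p_value")
  adj <- adjust_pvalues(p, first_level_correction)
  rows <- list()
  stack <- list()
  for (k in seq_along(top)) {
    if (adj[k] < alpha) {
      rows[[length(rows) + 1L]] <- taxa_row(clad, top[k], outs[[k]], adj[k],
                                            "trajectory")
      stack[[length(stack) + 1L]] <- top[k]
    }
  }
  while (length(stack) > 0L) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    kids <- clado_children(clad, node)
    if (length(kids) == 0L) next
    kid_outs <- lapply(kids, function(i)
      node_label_test(clad$values[i, ], labels))
    kid_p <- vapply(kid_outs, `[[`, numeric(1L), "p_value")
    # unresolved-leaf children can repeat the mother's path; disambiguate
    kid_names <- ifelse(clad$is_leaf[kids] &
                          clad$paths[kids] == clad$paths[node],
                        paste0(clad$paths[kids], ";"), clad$paths[kids])
    names(kid_p) <- kid_names
    surv <- sister_correct(kid_p, alpha)
    for (j in seq_along(kids)) {
      if (kid_names[j] %in% surv) {
        rows[[length(rows) + 1L]] <- taxa_row(clad, kids[j], kid_outs[[j]],
                                              NA_real_, "trajectory")
        stack[[length(stack) + 1L]] <- kids[j]
      }
    }
  }
  if (length(rows) == 0L) return(empty_taxa())
  do.call(rbind, rows)
}

#' Leaf rescue test
#'
#' Tests every leaf of the cladogram against the label and applies a
#' Bonferroni (default) or Benjamini-Hochberg correction across the
#' number of leaves; survivors are reported even when they lack a
#' significant ancestor chain.
#'
#' @param clad a [build_cladogram()] result.
#' @param labels a joined [label_vector()].
#' @param alpha significance level.
#' @param leaf_correction `"bonferroni"` (default) or `"bh"`.
#' @return data.frame of significant taxa with `source = "leaf"`.
#' @export
leaf_test <- function(clad, labels, alpha = 0.05,
                      leaf_correction = c("bonferroni", "bh")) {
  leaf_correction <- match.arg(leaf_correction)
  leaves <- which(clad$is_leaf)
  if (length(leaves) == 0L) stop("cladogram has no leaves")
  leaves <- leaves[order(clad$paths[leaves])]
  outs <- lapply(leaves, function(i)
    node_label_test(clad$values[i, ], labels))
  p <- vapply(outs, `[[`, numeric(1L), "p_value")
  adj <- adjust_pvalues(p, leaf_correction)
  keep <- which(adj < alpha)
  if (length(keep) == 0L) return(empty_taxa())
  do.call(rbind, lapply(keep, function(k)
    taxa_row(clad, leaves[k], outs[[k]], adj[k], "leaf")))
}

#' Hierarchical differential abundance analysis
#'
#' The full procedure: preprocess a raw taxa table (normalization and
#' taxonomy-level merging), build the cladogram of means, gate on the a
#' priori nested test ([apriori_scan()]); if the label is microbially
#' explainable, run the trajectory test from the coarsest taxonomy level,
#' escalating the start level (1, 2, 3) until at least one taxon is
#' found, then add the leaf rescue test and take the union of both taxon
#' sets (taxa found by both are flagged `"both"`).
#'
#' Tables whose `value_kind` is not `"raw"` are taken as already
#' processed and fed to the cladogram unchanged.
#'
#' @param x a [taxa_table()] (or a samples-by-features numeric matrix with
#'   taxonomy-string column names, coerced with `value_kind = "raw"`).
#' @param y a [label_vector()] (or a named vector coerced to one).
#' @param taxonomy_level,merge_method,normalization,epsilon,variance_criterion
#'   preprocessing controls, see [preprocess_taxa()].
#' @param alpha significance level, default 0.05.
#' @param start_level `"auto"` (escalate 1..3) or a fixed level 1..3;
#'   fixing the level disables escalation.
#' @param first_level_correction correction across the start level,
#'   `"bonferroni"` (default) or `"bh"`.
#' @param leaf_correction correction across leaves, `"bonferroni"`
#'   (default) or `"bh"`.
#' @return object of class `cladoda`: list with `taxa` (data.frame:
#'   `path`, `depth`, `p_value`, `adjusted_p`, `direction`, `source`),
#'   `apriori`, `used_start_level`, `config`, `cladogram`, `table`
#'   (processed), `labels`, `call`.
#' @examples
#' sim <- simulate_regime("zzm", mu = 1, n_per_class = 40, seed = 1)
#' fit <- cladoda(sim$table, sim$labels)
#' fit
#' @export
cladoda <- function(x, y,
                    taxonomy_level = 7L,
                    merge_method = c("sub_pca", "mean", "sum"),
                    normalization = c("log", "relative"),
                    epsilon = 0.1,
                    variance_criterion = "cumulative",
                    alpha = 0.05,
                    start_level = "auto",
                    first_level_correction = c("bonferroni", "bh"),
                    leaf_correction = c("bonferroni", "bh")) {
  merge_method <- match.arg(merge_method)
  normalization <- match.arg(normalization)
  first_level_correction <- match.arg(first_level_correction)
  leaf_correction <- match.arg(leaf_correction)
  if (!(identical(start_level, "auto") ||
        (is.numeric(start_level) && start_level %in% 1:3)))
    stop("start_level must be 'auto' or a level in 1..3")
  stopifnot(alpha > 0, alpha < 1)
  if (!inherits(x, "taxa_table")) x <- taxa_table(x)
  if (!inherits(y, "label_vector")) y <- label_vector(y)
  joined <- join_samples(x, y)
  x <- joined$table
  y <- joined$labels
  processed <- if (x$value_kind == "raw") {
    preprocess_taxa(x, taxonomy_level, merge_method, normalization,
                    epsilon, variance_criterion)
  } else {
    x
  }
  clad <- build_cladogram(processed)
  config <- list(taxonomy_level = taxonomy_level,
                 merge_method = merge_method,
                 normalization = normalization, epsilon = epsilon,
                 alpha = alpha, start_level = start_level,
                 first_level_correction = first_level_correction,
                 leaf_correction = leaf_correction,
                 label_kind = y$kind)
  apriori <- apriori_scan(clad, y, alpha)
  if (!apriori$explainable) {
    return(structure(list(taxa = empty_taxa(), apriori = apriori,
                          used_start_level = NA_integer_, config = config,
                          cladogram = clad, table = processed, labels = y,
                          call = match.call()),
                     class = "cladoda"))
  }
  levels_to_try <- if (identical(start_level, "auto")) {
    seq_len(min(3L, clad$max_depth))
  } else {
    as.integer(start_level)
  }
  traj <- empty_taxa()
  used <- levels_to_try[length(levels_to_try)]
  for (L in levels_to_try) {
    traj <- trajectory_test(clad, y, alpha, L, first_level_correction)
    used <- L
    if (nrow(traj) > 0L) break
  }
  rescue <- leaf_test(clad, y, alpha, leaf_correction)
  taxa <- merge_taxon_sets(traj, rescue)
  structure(list(taxa = taxa, apriori = apriori, used_start_level = used,
                 config = config, cladogram = clad, table = processed,
                 labels = y, call = match.call()),
            class = "cladoda")
}

merge_taxon_sets <- function(traj, rescue) {
  if (nrow(traj) == 0L && nrow(rescue) == 0L) return(empty_taxa())
  key <- function(df) paste(df$path, df$depth)
  both <- intersect(key(traj), key(rescue))
  if (length(both) > 0L) {
    hit <- key(traj) %in% both
    traj$source[hit] <- "both"
    traj$adjusted_p[hit] <- rescue$adjusted_p[match(key(traj)[hit],
                                                    key(rescue))]
    rescue <- rescue[!key(rescue) %in% both, , drop = FALSE]
  }
  out <- rbind(traj, rescue)
  out <- out[order(out$depth, out$path), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.cladoda <- function(x, ...) {
  cat("Hierarchical differential abundance fit\n")
  ap <- x$apriori
  cat("A priori nested test:",
      if (ap$explainable)
        paste0("label microbially explainable (first significant depth ",
               ap$first_significant_depth, ", p = ",
               signif(ap$per_depth_p[length(ap$per_depth_p)], 3L), ")")
      else "label NOT microbially explainable", "\n")
  if (ap$explainable)
    cat("Trajectory start level:", x$used_start_level, "\n")
  cat("Significant taxa:", nrow(x$taxa),
      "( trajectory:", sum(x$taxa$source == "trajectory"),
      ", leaf:", sum(x$taxa$source == "leaf"),
      ", both:", sum(x$taxa$source == "both"), ")\n")
  invisible(x)
}

#' @export
summary.cladoda <- function(object, ...) {
  structure(list(fit = object), class = "summary.cladoda")
}

#' @export
print.summary.cladoda <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nA priori p-values by depth:\n")
  print(signif(f$apriori$per_depth_p, 4L))
  if (nrow(f$taxa) > 0L) {
    cat("\nSignificant taxa:\n")
    df <- f$taxa
    df$p_value <- signif(df$p_value, 3L)
    df$adjusted_p <- signif(df$adjusted_p, 3L)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.cladoda <- function(x, ...) x$taxa

#' Plot a differential abundance fit
#'
#' Displays every cladogram node by taxonomy depth and significance
#' (-log10 p), colored by direction (blue positive, red negative, grey
#' non-significant) with plotting symbols by discovery source.
#'
#' @param x a [cladoda()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cladoda <- function(x, ...) {
  pd <- cladogram_plot_data(x)
  pch_map <- c(both = 19L, mimic_only = 1L, leaf_only = 15L, none = 46L)
  col_map <- c("-1" = "firebrick", "0" = "grey60", "1" = "steelblue")
  d <- path_depth(pd$path)
  jit <- (seq_len(nrow(pd)) %% 9L - 4L) / 20
  graphics::plot(d + jit, pd$size,
                 col = col_map[as.character(pd$color_sign)],
                 pch = pch_map[pd$shape],
                 xlab = "taxonomy depth", ylab = "-log10(p)", ...)
  invisible(pd)
}

#' Write fit results to a directory
#'
#' Writes `results.tsv` (one row per significant taxon) and
#' `summary.json` (a priori p-values, start level, configuration echo,
#' counts by source).
#'
#' @param fit a [cladoda()] fit.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cladoda <- function(fit, dir) {
  stopifnot(inherits(fit, "cladoda"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(fit$taxa, file.path(dir, "results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summ <- list(apriori_p = as.list(fit$apriori$per_depth_p),
               first_significant_depth =
                 fit$apriori$first_significant_depth,
               explainable = fit$apriori$explainable,
               used_start_level = fit$used_start_level,
               config = fit$config,
               n_taxa = nrow(fit$taxa),
               n_by_source = as.list(table(fit$taxa$source)))
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(dir)
}
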