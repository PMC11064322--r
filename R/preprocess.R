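#' Normalize a raw taxa table
#'
#' `"log"` applies an element-wise base-10 log after adding a small
#' pseudo-abundance `epsilon` (so a zero count maps to `log10(epsilon)`);
#' `"relative"` divides each sample row by its total.
#'
#' @param table a raw [taxa_table()].
#' @param mode `"log"` (default) or `"relative"`.
#' @param epsilon positive pseudo-abundance for log mode (default 0.1).
#' @return a [taxa_table()] with `value_kind` `"log_processed"` or
#'   `"relative"`.
#' @export
normalize_taxa <- function(table, mode = c("log", "relative"),
                           epsilon = 0.1) {
  stopifnot(inherits(table, "taxa_table"))
  mode <- match.arg(mode)
  if (table$value_kind != "raw")
    stop("normalize_taxa() expects a raw table, got ", table$value_kind)
  out <- table
  if (mode == "log") {
    if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
      stop("epsilon must be a positive number")
    out$values <- log10(table$values + epsilon)
    out$value_kind <- "log_processed"
  } else {
    totals <- rowSums(table$values)
    if (any(totals == 0))
      stop("all-zero sample row(s): ",
           paste(rownames(table$values)[totals == 0], collapse = ", "))
    out$values <- table$values / totals
    out$value_kind <- "relative"
  }
  out
}

#' Merge features at a taxonomy level
#'
#' Features sharing the same rank-path prefix up to `level` (features
#' shallower than `level` form their own group) are merged by one of:
#' `"mean"`/`"sum"` — element-wise across the group; `"sub_pca"` — the
#' group's columns are standardized to z-scores and replaced by the
#' minimal set of leading principal components whose cumulative explained
#' variance exceeds half the group variance (per-component criterion
#' available via `variance_criterion = "individual"`). Component features
#' are named `<prefix>__pcK`; each component's sign is fixed so that it
#' correlates non-negatively with the group's mean standardized abundance.
#'
#' @param table a [taxa_table()]; must already be normalized for
#'   `"sub_pca"`.
#' @param level taxonomy level 1 (kingdom) to 7 (species).
#' @param method `"sub_pca"` (default), `"mean"` or `"sum"`.
#' @param variance_criterion `"cumulative"` (default) or `"individual"`
#'   reading of the more-than-half-the-variance rule for sub-PCA.
#' @return a [taxa_table()] of merged features.
#' @export
collapse_taxonomy <- function(table, level = 7L,
                              method = c("sub_pca", "mean", "sum"),
                              variance_criterion = c("cumulative",
                                                     "individual")) {
  stopifnot(inherits(table, "taxa_table"))
  method <- match.arg(method)
  variance_criterion <- match.arg(variance_criterion)
  if (!is.numeric(level) || length(level) != 1L || level < 1L || level > 7L)
    stop("level must be in 1..7")
  level <- as.integer(level)
  depths <- path_depth(colnames(table$values))
  if (level > max(depths))
    stop("level ", level, " exceeds the deepest feature (depth ",
         max(depths), ")")
  if (method == "sub_pca" && table$value_kind == "raw")
    stop("sub_pca merging requires a normalized table")
  prefix <- vapply(strsplit(colnames(table$values), ";", fixed = TRUE),
                   function(p) paste(utils::head(p, level), collapse = ";"),
                   character(1L))
  groups <- split(seq_along(prefix), prefix)
  cols <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    block <- table$values[, idx, drop = FALSE]
    if (method == "mean") {
      cols[[g]] <- rowMeans(block)
    } else if (method == "sum") {
      cols[[g]] <- rowSums(block)
    } else {
      pcs <- sub_pca_components(block, variance_criterion)
      colnames(pcs) <- paste0(g, "__pc", seq_len(ncol(pcs)))
      cols[[g]] <- pcs
    }
  }
  if (method == "sub_pca") {
    m <- do.call(cbind, cols[sort(names(cols))])
  } else {
    m <- do.call(cbind, cols[sort(names(cols))])
    colnames(m) <- sort(names(cols))
  }
  rownames(m) <- rownames(table$values)
  out <- table
  out$values <- m
  if (method == "sub_pca") out$value_kind <- "log_processed"
  out
}

# z-score the group's columns, run PCA, keep the minimal leading set of
# components passing the variance rule, fix signs against the group mean.
sub_pca_components <- function(block, variance_criterion) {
  n <- nrow(block)
  z <- scale(block)
  # constant columns: zero after centering (zero-variance guard)
  z[, attr(z, "scaled:scale") == 0] <- 0
  z <- matrix(as.numeric(z), nrow = n, dimnames = dimnames(block))
  if (ncol(z) == 1L) return(z[, 1L, drop = FALSE])
  pc <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  frac <- ev / sum(ev)
  k <- if (variance_criterion == "cumulative") {
    which(cumsum(frac) > 0.5)[1L]
  } else {
    max(1L, sum(frac > 0.5))
  }
  k <- min(max(k, 1L), ncol(z))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  ref <- rowMeans(z)
  for (j in seq_len(k)) {
    s <- suppressWarnings(stats::cor(scores[, j], ref))
    if (is.na(s) || abs(s) < 1e-12) {
      load <- pc$rotation[, j]
      s <- load[which(abs(load) > 1e-12)[1L]]
    }
    if (s < 0) scores[, j] <- -scores[, j]
  }
  scores
}

#' Standard preprocessing pipeline
#'
#' Normalizes a raw table and merges it at a taxonomy level, in that
#' order. Defaults match the recommended configuration: base-10 log with
#' epsilon 0.1, species-level (7) sub-PCA merging. The `"relative-mean"`
#' variant is `normalization = "relative", merge_method = "mean"`.
#'
#' @param table raw [taxa_table()].
#' @param taxonomy_level 1..7, default 7.
#' @param merge_method `"sub_pca"`, `"mean"` or `"sum"`.
#' @param normalization `"log"` or `"relative"`.
#' @param epsilon pseudo-abundance for log normalization.
#' @param variance_criterion sub-PCA variance rule, see
#'   [collapse_taxonomy()].
#' @return processed [taxa_table()].
#' @export
preprocess_taxa <- function(table, taxonomy_level = 7L,
                            merge_method = c("sub_pca", "mean", "sum"),
                            normalization = c("log", "relative"),
                            epsilon = 0.1,
                            variance_criterion = "cumulative") {
  merge_method <- match.arg(merge_method)
  normalization <- match.arg(normalization)
  table <- normalize_taxa(table, normalization, epsilon)
  collapse_taxonomy(table, taxonomy_level, merge_method, variance_criterion)
}
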