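#' Cladogram plot data
#'
#' One row per cladogram node: `size` is `-log10(p)` for significant taxa
#' and 0 otherwise, `color_sign` the direction of the test (+1 blue, -1
#' red, 0 grey/non-significant), `shape` the discovery source (`"both"`,
#' `"mimic_only"` for trajectory-only, `"leaf_only"`, `"none"`), `family`
#' the rank-5 name where the node is at least family-deep.
#'
#' @param fit a [cladoda()] fit.
#' @return data.frame `path`, `depth`, `size`, `color_sign`, `shape`,
#'   `family`.
#' @export
cladogram_plot_data <- function(fit) {
  stopifnot(inherits(fit, "cladoda"))
  clad <- fit$cladogram
  key <- paste(clad$paths, clad$depth)
  tkey <- paste(fit$taxa$path, fit$taxa$depth)
  idx <- match(key, tkey)
  size <- ifelse(is.na(idx), 0, -log10(fit$taxa$p_value[idx]))
  color <- ifelse(is.na(idx), 0L, fit$taxa$direction[idx])
  shape <- ifelse(is.na(idx), "none",
                  c(trajectory = "mimic_only", leaf = "leaf_only",
                    both = "both")[fit$taxa$source[idx]])
  fam <- vapply(strsplit(clad$paths, ";", fixed = TRUE),
                function(p) if (length(p) >= 5L) p[5L] else NA_character_,
                character(1L))
  data.frame(path = clad$paths, depth = clad$depth, size = size,
             color_sign = as.integer(color), shape = shape, family = fam,
             stringsAsFactors = FALSE)
}

#' Interaction network among significant taxa
#'
#' Pairwise Spearman correlations between the (processed) per-sample
#' value vectors of all significant taxa; an edge is emitted when the
#' absolute correlation exceeds `scc_threshold` and its p-value is below
#' 0.05.
#'
#' @param fit a [cladoda()] fit.
#' @param scc_threshold minimum absolute Spearman correlation,
#'   default 0.3.
#' @return data.frame `a`, `b` (taxon paths, `a < b`), `scc`, `p_value`,
#'   `sign`; zero rows (with a warning) when fewer than 2 significant
#'   taxa exist.
#' @export
interaction_network <- function(fit, scc_threshold = 0.3) {
  stopifnot(inherits(fit, "cladoda"))
  empty <- data.frame(a = character(0L), b = character(0L),
                      scc = numeric(0L), p_value = numeric(0L),
                      sign = integer(0L), stringsAsFactors = FALSE)
  if (nrow(fit$taxa) < 2L) {
    warning("fewer than 2 significant taxa; empty network")
    return(empty)
  }
  clad <- fit$cladogram
  key <- paste(clad$paths, clad$depth)
  idx <- match(paste(fit$taxa$path, fit$taxa$depth), key)
  vals <- clad$values[idx, , drop = FALSE]
  rownames(vals) <- fit$taxa$path
  n <- nrow(vals)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ct <- tryCatch(spearman_test(vals[i, ], vals[j, ]),
                     error = function(e) NULL)
      if (is.null(ct)) next
      if (abs(ct$statistic) > scc_threshold && ct$p_value < 0.05) {
        a <- rownames(vals)[i]
        b <- rownames(vals)[j]
        if (b < a) { tmp <- a; a <- b; b <- tmp }
        rows[[length(rows) + 1L]] <-
          data.frame(a = a, b = b, scc = ct$statistic,
                     p_value = ct$p_value, sign = ct$direction,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Counts of positive and negative associations per family
#'
#' For every taxonomic family with at least one significant descendant
#' (nodes at family depth or deeper, grouped by their rank-5 name),
#' counts the significant descendants by association direction.
#'
#' @param fit a [cladoda()] fit.
#' @return data.frame `family`, `n_positive`, `n_negative`.
#' @export
family_relation_counts <- function(fit) {
  stopifnot(inherits(fit, "cladoda"))
  taxa <- fit$taxa[fit$taxa$depth >= 5L, , drop = FALSE]
  if (nrow(taxa) == 0L)
    return(data.frame(family = character(0L), n_positive = integer(0L),
                      n_negative = integer(0L), stringsAsFactors = FALSE))
  fam <- vapply(strsplit(taxa$path, ";", fixed = TRUE), `[`, character(1L),
                5L)
  pos <- tapply(taxa$direction > 0, fam, sum)
  neg <- tapply(taxa$direction < 0, fam, sum)
  out <- data.frame(family = names(pos),
                    n_positive = as.integer(pos),
                    n_negative = as.integer(neg),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$family), , drop = FALSE]
}
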