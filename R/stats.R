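test_outcome <- function(statistic, p_value, direction, method) {
  structure(list(statistic = unname(statistic),
                 p_value = min(max(unname(p_value), 0), 1),
                 direction = as.integer(direction), method = method),
            class = "test_outcome")
}

#' @export
print.test_outcome <- function(x, ...) {
  cat(x$method, ": statistic =", signif(x$statistic, 4L),
      ", p =", signif(x$p_value, 4L), ", direction =", x$direction, "\n")
  invisible(x)
}

#' Two-sided Mann-Whitney test with direction
#'
#' Exact null distribution when the smaller group has at most 8
#' observations and the pooled sample is tie-free; otherwise the normal
#' approximation with tie and continuity corrections. The direction is the
#' sign of `U_x - nm/2`: +1 when `x` (the positive class) tends to rank
#' higher.
#'
#' @param x,y numeric vectors (positive-class values first).
#' @return a `test_outcome` with `method` `"mw_exact"` or `"mw_normal"`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L)
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 8L && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE,
                                            alternative = "two.sided"))
  u <- unname(wt$statistic)
  centred <- u - length(x) * length(y) / 2
  test_outcome(u, wt$p.value, sign(centred),
               if (exact) "mw_exact" else "mw_normal")
}

#' Spearman correlation test
#'
#' Average-rank ties; two-sided p via the t approximation.
#'
#' @param x,y numeric vectors of equal length (at least 3), non-constant.
#' @return a `test_outcome` with `method = "spearman"` and the statistic
#'   equal to rho.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  rho <- unname(ct$estimate)
  test_outcome(rho, ct$p.value, sign(rho), "spearman")
}

#' Multiple-testing adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method `"bonferroni"` or `"bh"` (Benjamini-Hochberg step-up).
#' @return adjusted p-values, same order as input.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (length(p) == 0L) return(numeric(0L))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = c(bonferroni = "bonferroni", bh = "BH")[method])
}

#' Nested label-effect test over cladogram levels
#'
#' Stacks one observation per (sample, node) over all nodes at depths
#' 1..`depth` and compares, by a partial F-test, the null fixed-effects
#' model `value ~ node` against the full model
#' `value ~ node + label + label:node` (the label enters as a 0/1 factor
#' for binary labels or as a continuous covariate). With a single kingdom
#' at depth 1 this reduces to a one-way ANOVA of the kingdom values by
#' label.
#'
#' @param clad a [build_cladogram()] result.
#' @param labels a [label_vector()] covering the cladogram samples.
#' @param depth deepest taxonomy level to stack (>= 1).
#' @return a `test_outcome` with `method = "nested_f"`; the statistic is
#'   the partial F and the direction is 0 (the test is omnibus).
#' @export
nested_label_test <- function(clad, labels, depth) {
  stopifnot(inherits(clad, "cladogram"), inherits(labels, "label_vector"))
  if (depth < 1L || depth > clad$max_depth)
    stop("depth must be in 1..", clad$max_depth)
  if (!all(clad$sample_ids %in% names(labels$values)))
    stop("labels are missing cladogram samples; join first")
  y <- labels$values[clad$sample_ids]
  if (labels$kind == "binary" && min(table(y)) < 2L)
    stop("need at least 2 samples per binary class")
  nodes <- which(clad$depth <= as.integer(depth))
  vals <- clad$values[nodes, , drop = FALSE]
  k <- nrow(vals)
  n <- ncol(vals)
  # closed-form partial F; identical to stacking the observations and
  # comparing lm(value ~ node) with lm(value ~ node + label + label:node)
  # (the full model fits one label effect per node), see the test suite
  # for the lm oracle.
  rss0 <- sum((vals - rowMeans(vals))^2)
  if (rss0 < 1e-20)
    stop("degenerate response: no residual variance under the null model")
  if (labels$kind == "binary") {
    i0 <- y == 0
    i1 <- y == 1
    rss1 <- sum((vals[, i0, drop = FALSE] -
                   rowMeans(vals[, i0, drop = FALSE]))^2) +
      sum((vals[, i1, drop = FALSE] -
             rowMeans(vals[, i1, drop = FALSE]))^2)
  } else {
    yc <- y - mean(y)
    syy <- sum(yc^2)
    if (syy == 0) stop("continuous label is constant")
    vc <- vals - rowMeans(vals)
    slope <- as.vector(vc %*% yc) / syy
    rss1 <- sum(vc^2) - syy * sum(slope^2)
  }
  df0 <- k * n - k
  df1 <- k * n - 2L * k
  if (df1 <= 0L) stop("too few samples for the nested model")
  f <- ((rss0 - rss1) / k) / (rss1 / df1)
  p <- stats::pf(f, k, df1, lower.tail = FALSE)
  test_outcome(f, p, 0L, "nested_f")
}
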