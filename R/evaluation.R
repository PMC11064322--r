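#' RSP score
#'
#' Ground-truth-free quality score trading real positives (significant
#' taxa under the true labels, RP) against shuffled positives (mean
#' significant taxa under permuted labels, SP):
#' `RSP(beta) = (beta*RP - SP) / (beta*RP + SP)`, with `beta` in (0, 1]
#' weighting the willingness to trade real discoveries for shuffled ones
#' (`beta = 0.05`: forgo 20 RP to avoid 1 SP). Defined as 0 when
#' `beta*RP + SP = 0` (nothing found either way).
#'
#' @param rp,sp non-negative counts.
#' @param beta confidence weight in (0, 1].
#' @return the score, in \[-1, 1\].
#' @examples
#' rsp_score(20, 1, 0.05)  # exactly 0
#' @export
rsp_score <- function(rp, sp, beta) {
  if (any(beta <= 0 | beta > 1)) stop("beta must lie in (0, 1]")
  if (any(rp < 0) || any(sp < 0)) stop("rp and sp must be non-negative")
  num <- beta * rp - sp
  den <- beta * rp + sp
  ifelse(den == 0, 0, num / den)
}

#' RSP curve over a beta grid
#'
#' @param rp real-positive count.
#' @param sp shuffled-positive count (mean over shuffles).
#' @param betas beta grid, default 100 points on (0.01, 1).
#' @return data.frame `beta`, `rsp`, `rp`, `sp`.
#' @export
rsp_curve <- function(rp, sp, betas = seq(0.01, 1, length.out = 100L)) {
  data.frame(beta = betas, rsp = rsp_score(rp, sp, betas), rp = rp, sp = sp)
}

#' Estimate shuffled positives by label permutation
#'
#' Permutes the labels `n_shuffles` times with a seeded generator, reruns
#' the full analysis ([cladoda()]) each time and returns the mean
#' significant-taxon count, together with the per-shuffle counts (so RSP
#' can also be averaged per shuffle instead of over the mean SP).
#'
#' @param x taxa table, `y` labels (as for [cladoda()]).
#' @param y labels.
#' @param n_shuffles number of permutations, default 10.
#' @param seed integer seed driving the permutations.
#' @param ... further arguments passed to [cladoda()].
#' @return list with `sp` (mean count), `per_shuffle` (integer vector),
#'   `n_shuffles`, `seed`.
#' @export
estimate_sp <- function(x, y, n_shuffles = 10L, seed = 1L, ...) {
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1")
  if (!inherits(y, "label_vector")) y <- label_vector(y)
  counts <- integer(n_shuffles)
  with_seed(seed, {
    for (s in seq_len(n_shuffles)) {
      ys <- y
      ys$values <- stats::setNames(sample(y$values), names(y$values))
      fit <- cladoda(x, ys, ...)
      counts[s] <- nrow(fit$taxa)
    }
  })
  list(sp = mean(counts), per_shuffle = counts, n_shuffles = n_shuffles,
       seed = seed)
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

#' Confusion metrics against a known truth
#'
#' Set-overlap counts between predicted and true taxon sets.
#' `f1 = 2tp / (2tp + fp + fn)`; with empty truth, `f1` is 1 when the
#' prediction is empty too and 0 otherwise. The false-positive rate is
#' only computed when a `universe` of testable taxa is supplied.
#' `strip_components` removes a trailing `__pcK` component suffix before
#' matching, so sub-PCA features can be scored against taxonomy truth.
#'
#' @param predicted,truth character vectors of taxon paths.
#' @param universe optional character vector of all testable taxa.
#' @param strip_components drop `__pcK` suffixes before matching.
#' @return list `tp`, `fp`, `fn`, `tpr`, `fpr` (or `NA`), `f1`.
#' @export
confusion_metrics <- function(predicted, truth, universe = NULL,
                              strip_components = FALSE) {
  if (strip_components) {
    predicted <- strip_pc_suffix(predicted)
    truth <- strip_pc_suffix(truth)
    if (!is.null(universe)) universe <- strip_pc_suffix(universe)
  }
  predicted <- unique(predicted)
  truth <- unique(truth)
  tp <- length(intersect(predicted, truth))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  tpr <- if (length(truth) > 0L) tp / length(truth) else NA_real_
  fpr <- if (!is.null(universe)) {
    negatives <- setdiff(unique(universe), truth)
    if (length(negatives) > 0L)
      length(intersect(predicted, negatives)) / length(negatives)
    else NA_real_
  } else {
    NA_real_
  }
  f1 <- if (length(truth) == 0L && length(predicted) == 0L) {
    1
  } else if (2 * tp + fp + fn == 0) {
    0
  } else {
    2 * tp / (2 * tp + fp + fn)
  }
  list(tp = tp, fp = fp, fn = fn, tpr = tpr, fpr = fpr, f1 = f1)
}

#' @rdname confusion_metrics
#' @param paths character vector of feature paths.
#' @export
strip_pc_suffix <- function(paths) sub("__pc[0-9]+$", "", paths)

#' Per-taxon between-class separation statistic
#'
#' For a binary label, `s = |M0 - M1| / |V0 - V1|^0.5` where `M`/`V` are
#' the per-class means and variances. The printed denominator (the root
#' of the absolute *difference* of variances) is used as stated;
#' `denominator = "sum"` gives the conventional pooled form
#' `(V0 + V1)^0.5`. When `|V0 - V1|` falls below `1e-16` the denominator
#' is guarded at `1e-8`.
#'
#' @param values per-sample numeric vector.
#' @param labels a binary [label_vector()] covering the samples.
#' @param denominator `"difference"` (as printed) or `"sum"`.
#' @return list `s`, `m0`, `m1`, `v0`, `v1`.
#' @export
sister_statistic <- function(values, labels,
                             denominator = c("difference", "sum")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(labels, "label_vector"))
  if (labels$kind != "binary") stop("sister statistic needs binary labels")
  y <- labels$values
  if (!is.null(names(values))) values <- values[names(y)]
  if (length(values) != length(y))
    stop("values and labels must cover the same samples")
  g0 <- values[y == 0]
  g1 <- values[y == 1]
  if (length(g0) < 2L || length(g1) < 2L)
    stop("each class needs at least 2 samples (variance undefined)")
  m0 <- mean(g0); m1 <- mean(g1)
  v0 <- stats::var(g0); v1 <- stats::var(g1)
  den2 <- if (denominator == "difference") abs(v0 - v1) else v0 + v1
  den <- if (den2 < 1e-16) 1e-8 else sqrt(den2)
  list(s = abs(m0 - m1) / den, m0 = m0, m1 = m1, v0 = v0, v1 = v1)
}

#' Sister-pair correlation of label separation
#'
#' Computes the separation statistic ([sister_statistic()]) for every
#' cladogram node and the Spearman correlation over all unordered sister
#' pairs (nodes sharing a mother, at all depths; within a pair the
#' lexicographically smaller path contributes the first coordinate).
#' A strong positive correlation indicates that sister taxa relate to the
#' label similarly, the structural assumption behind trajectory testing.
#'
#' @param clad a [build_cladogram()] result.
#' @param labels a binary [label_vector()].
#' @param denominator passed to [sister_statistic()].
#' @return list `scc`, `p_value`, `n_pairs`.
#' @export
sister_correlation <- function(clad, labels,
                               denominator = "difference") {
  stopifnot(inherits(clad, "cladogram"))
  s <- vapply(seq_along(clad$paths), function(i)
    sister_statistic(clad$values[i, ], labels, denominator)$s,
    numeric(1L))
  sa <- numeric(0L)
  sb <- numeric(0L)
  for (m in which(!clad$is_leaf)) {
    kids <- clado_children(clad, m)
    if (length(kids) < 2L) next
    kids <- kids[order(clad$paths[kids], clad$is_leaf[kids])]
    pairs <- utils::combn(kids, 2L)
    sa <- c(sa, s[pairs[1L, ]])
    sb <- c(sb, s[pairs[2L, ]])
  }
  if (length(sa) < 3L)
    stop("insufficient sister pairs (need >= 3, have ", length(sa), ")")
  out <- spearman_test(sa, sb)
  list(scc = out$statistic, p_value = out$p_value, n_pairs = length(sa))
}
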