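#' Simulate the hierarchical Gaussian regimes
#'
#' Each triplet consists of three daughter taxa under a shared mother;
#' per sample, daughter j is drawn `N(shift_j * label, 1)` so the
#' negative class is always standard normal. Regimes: `"zzz"` — shifts
#' (0, 0, 0), a pure null; `"zzm"` — shifts (mu, 0, 0), one associated
#' daughter; `"zma"` — shifts (mu, alpha_coef * mu, 0), two associated
#' daughters of possibly opposite sign. The mother's value in the built
#' cladogram is exactly the mean of its three daughters.
#'
#' @param regime `"zzz"`, `"zzm"` or `"zma"`.
#' @param mu planted effect size (ignored for `"zzz"`).
#' @param alpha_coef relative effect of the second daughter (`"zma"`
#'   only).
#' @param n_per_class samples per class (total `2 * n_per_class`).
#' @param n_triplets number of mother/daughter triplets, default 10.
#' @param seed integer seed.
#' @return object of class `sim_dataset`: list with `table` (a processed
#'   [taxa_table()], depth-3 taxonomy), `labels` (binary
#'   [label_vector()]), `truth` (list: `leaf` — planted daughters;
#'   `trajectory` — planted daughters plus all their ancestors) and
#'   `config`.
#' @export
simulate_regime <- function(regime = c("zzz", "zzm", "zma"), mu = 0,
                            alpha_coef = NULL, n_per_class = 50L,
                            n_triplets = 10L, seed = 1L) {
  regime <- match.arg(regime)
  if (n_per_class < 2L) stop("n_per_class must be >= 2")
  if (n_triplets < 1L) stop("n_triplets must be >= 1")
  if (regime != "zzz" && (!is.numeric(mu) || mu < 0))
    stop("mu must be a non-negative number")
  if (regime == "zma" && is.null(alpha_coef))
    stop("regime 'zma' requires alpha_coef")
  shifts <- switch(regime,
                   zzz = c(0, 0, 0),
                   zzm = c(mu, 0, 0),
                   zma = c(mu, alpha_coef * mu, 0))
  n <- 2L * n_per_class
  sample_ids <- c(sprintf("pos_%03d", seq_len(n_per_class)),
                  sprintf("neg_%03d", seq_len(n_per_class)))
  y <- stats::setNames(rep(c(1, 0), each = n_per_class), sample_ids)
  paths <- character(0L)
  with_seed(seed, {
    m <- matrix(NA_real_, nrow = n, ncol = 3L * n_triplets)
    col <- 0L
    for (t in seq_len(n_triplets)) {
      for (j in 1:3) {
        col <- col + 1L
        m[, col] <- stats::rnorm(n, mean = shifts[j] * y, sd = 1)
        paths[col] <- sprintf("sim_k;trip_%02d;d%d", t, j)
      }
    }
  })
  rownames(m) <- sample_ids
  colnames(m) <- paths
  table <- taxa_table(m, value_kind = "log_processed", dialect = "bare")
  planted <- paths[rep(abs(shifts) > 0, times = n_triplets)]
  ancestors <- unique(unlist(lapply(strsplit(planted, ";", fixed = TRUE),
                                    function(p) c(p[1L],
                                                  paste(p[1:2],
                                                        collapse = ";")))))
  labels <- label_vector(y)
  structure(list(table = table, labels = labels,
                 truth = list(leaf = planted,
                              trajectory = sort(c(planted, ancestors))),
                 config = list(regime = regime, mu = mu,
                               alpha_coef = alpha_coef,
                               n_per_class = n_per_class,
                               n_triplets = n_triplets, seed = seed)),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated dataset (", x$config$regime %||% "spikein", "):",
      nrow(x$table$values), "samples x", ncol(x$table$values),
      "features;", length(x$truth$leaf), "planted leaf taxa\n")
  invisible(x)
}

#' Simulate a zero-inflated, taxonomy-structured microbiome table
#'
#' Generates a synthetic 7-level taxonomy (6 species per genus, 2 genera
#' per family, 2 families per order, 3 orders per class, 2 classes per
#' phylum), draws baseline counts as a zero-inflated log-normal (zero
#' with probability `sparsity`, otherwise `round(lognormal(mean_log,
#' dispersion))`), labels each sample positive with probability 1/2, and
#' multiplies the counts of all species of `n_up` randomly chosen genera
#' by `spike_factor` in positive samples and of `n_down` further genera
#' in negative samples. This is a synthetic stand-in for the spike-in
#' protocol applied to real cohorts: taxonomy structure, sparsity and
#' heavy tails are emulated; real-data compositionality and inter-taxon
#' correlations are not.
#'
#' @param n_samples,n_features table dimensions (features = species-level
#'   leaves), defaults 200 x 300.
#' @param n_up,n_down number of genera spiked in the positive / negative
#'   class, defaults 10 and 10.
#' @param spike_factor multiplicative spike, default 1.2 (a 20% increase).
#' @param sparsity zero probability, default 0.05.
#' @param dispersion log-normal sdlog, default 0.5.
#' @param mean_log log-normal meanlog, default 2.5.
#' @param seed integer seed.
#' @return a `sim_dataset`: raw [taxa_table()], binary labels, `truth`
#'   (list: `leaf` — spiked species; `taxa` — the spiked genera;
#'   `trajectory` — species, genera and all their ancestors; `up`/`down`
#'   — spiked genera by direction) and `config`.
#' @export
simulate_microbiome <- function(n_samples = 200L, n_features = 300L,
                                n_up = 10L, n_down = 10L,
                                spike_factor = 1.2, sparsity = 0.05,
                                dispersion = 0.5, mean_log = 2.5,
                                seed = 1L) {
  if (spike_factor <= 1) stop("spike_factor must exceed 1")
  if (sparsity < 0 || sparsity >= 1) stop("sparsity must lie in [0, 1)")
  n_genera <- ceiling(n_features / 6L)
  if (n_up + n_down > n_genera)
    stop("n_up + n_down exceeds the ", n_genera, " available genera")
  genus_of <- ceiling(seq_len(n_features) / 6L)
  fam_of <- ceiling(genus_of / 2L)
  ord_of <- ceiling(fam_of / 2L)
  cls_of <- ceiling(ord_of / 3L)
  phy_of <- ceiling(cls_of / 2L)
  paths <- sprintf("Bacteria;p%02d;c%02d;o%02d;f%02d;g%03d;s%03d",
                   phy_of, cls_of, ord_of, fam_of, genus_of,
                   seq_len(n_features))
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  with_seed(seed, {
    y <- stats::rbinom(n_samples, 1L, 0.5)
    while (length(unique(y)) < 2L) y <- stats::rbinom(n_samples, 1L, 0.5)
    m <- matrix(stats::rlnorm(n_samples * n_features, meanlog = mean_log,
                              sdlog = dispersion),
                nrow = n_samples, ncol = n_features)
    m <- round(m)
    zeros <- matrix(stats::runif(n_samples * n_features) < sparsity,
                    nrow = n_samples)
    m[zeros] <- 0
    spiked <- sample(seq_len(n_genera), n_up + n_down)
  })
  up <- spiked[seq_len(n_up)]
  down <- if (n_down > 0L) spiked[n_up + seq_len(n_down)] else integer(0L)
  m[y == 1L, genus_of %in% up] <- m[y == 1L, genus_of %in% up] * spike_factor
  m[y == 0L, genus_of %in% down] <-
    m[y == 0L, genus_of %in% down] * spike_factor
  rownames(m) <- sample_ids
  colnames(m) <- paths
  table <- taxa_table(m, value_kind = "raw", dialect = "bare")
  genus_path <- function(g)
    unique(vapply(strsplit(paths[genus_of == g], ";", fixed = TRUE),
                  function(p) paste(p[1:6], collapse = ";"), character(1L)))
  up_paths <- vapply(up, genus_path, character(1L))
  down_paths <- vapply(down, genus_path, character(1L))
  leaf_truth <- paths[genus_of %in% c(up, down)]
  anc <- unique(unlist(lapply(strsplit(c(up_paths, down_paths), ";",
                                       fixed = TRUE),
                              function(p) vapply(seq_len(length(p) - 1L),
                                                 function(k)
                                                   paste(p[seq_len(k)],
                                                         collapse = ";"),
                                                 character(1L)))))
  labels <- label_vector(stats::setNames(y, sample_ids))
  structure(list(table = table, labels = labels,
                 truth = list(leaf = leaf_truth,
                              taxa = c(up_paths, down_paths),
                              trajectory = sort(unique(c(leaf_truth,
                                                         up_paths,
                                                         down_paths,
                                                         anc))),
                              up = up_paths, down = down_paths),
                 config = list(n_samples = n_samples,
                               n_features = n_features, n_up = n_up,
                               n_down = n_down,
                               spike_factor = spike_factor,
                               sparsity = sparsity,
                               dispersion = dispersion,
                               mean_log = mean_log, seed = seed)),
            class = "sim_dataset")
}
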