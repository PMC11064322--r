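# Small builders used across the suite. Everything is generated in code;
# no stored fixtures.

make_table <- function(values, paths, samples = NULL,
                       value_kind = "log_processed") {
  m <- matrix(values, ncol = length(paths))
  rownames(m) <- samples %||% sprintf("s%02d", seq_len(nrow(m)))
  colnames(m) <- paths
  taxa_table(m, value_kind = value_kind, dialect = "bare")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# depth-1 forest: k kingdom-level leaves with iid N(0,1) values;
# used for exact calibration of the nested label test
flat_kingdom_table <- function(k = 4L, n = 60L) {
  m <- matrix(rnorm(n * k), nrow = n)
  rownames(m) <- sprintf("s%03d", seq_len(n))
  colnames(m) <- sprintf("king%02d", seq_len(k))
  taxa_table(m, value_kind = "log_processed", dialect = "bare")
}

binary_labels <- function(n, n_pos = n %/% 2, ids = sprintf("s%03d",
                                                            seq_len(n))) {
  label_vector(setNames(rep(c(1, 0), c(n_pos, n - n_pos)), ids))
}

# a 1-kingdom / 2-phylum / 2-species-per-phylum tree where phylum A's
# species are shifted in the positive class
shifted_tree_table <- function(n_per_class = 100L, shift = 2) {
  n <- 2L * n_per_class
  y <- rep(c(1, 0), each = n_per_class)
  paths <- c("Bac;phyA;spA1", "Bac;phyA;spA2", "Bac;phyB;spB1",
             "Bac;phyB;spB2")
  m <- sapply(seq_along(paths), function(j)
    rnorm(n, mean = if (j <= 2) shift * y else 0))
  rownames(m) <- sprintf("s%03d", seq_len(n))
  colnames(m) <- paths
  list(table = taxa_table(m, value_kind = "log_processed",
                          dialect = "bare"),
       labels = label_vector(setNames(y, rownames(m))))
}

path_d <- function(p) length(strsplit(p, ";", fixed = TRUE)[[1]])

# brute-force Mann-Whitney oracle: enumerate every assignment of the
# pooled values to group x, two-sided p from the symmetric exact null
mw_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  idx <- utils::combn(length(pooled), n)
  u_all <- apply(idx, 2L, function(i) sum(r[i]) - n * (n + 1) / 2)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  centre <- n * length(y) / 2
  mean(abs(u_all - centre) >= abs(u_obs - centre))
}

# literal Benjamini-Hochberg step-up oracle
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  adj
}
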