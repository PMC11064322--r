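test_that("Mann-Whitney matches hand-enumerated exact cases with direction", {
  out <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$p_value, 0.1)   # P(U <= 0) = 1/20, doubled
  expect_equal(out$direction, -1L)
  expect_equal(out$method, "mw_exact")

  mirror <- mann_whitney(c(5, 6, 7), c(1, 2, 3))
  expect_equal(mirror$p_value, 0.1)
  expect_equal(mirror$direction, 1L)

  sym <- mann_whitney(c(1, 2), c(1, 2))
  expect_equal(sym$p_value, 1)
  expect_equal(sym$direction, 0L)

  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney equals brute-force enumeration (tie-free, n,m <= 6)", {
  set.seed(101)
  for (n in 1:6) {
    for (m in n:6) {
      for (rep in 1:2) {
        x <- rnorm(n)
        y <- rnorm(m)
        out <- mann_whitney(x, y)
        expect_equal(out$method, "mw_exact")
        expect_equal(out$p_value, mw_enum_p(x, y),
                     info = sprintf("n=%d m=%d rep=%d", n, m, rep))
      }
    }
  }
})

test_that("Mann-Whitney is antisymmetric in its arguments", {
  set.seed(5)
  for (rep in 1:20) {
    x <- rnorm(sample(2:12, 1))
    y <- rnorm(sample(2:12, 1)) + rnorm(1)
    a <- mann_whitney(x, y)
    b <- mann_whitney(y, x)
    expect_equal(a$p_value, b$p_value)
    expect_equal(a$direction, -b$direction)
  }
})

test_that("large or tied samples take the corrected normal approximation", {
  set.seed(9)
  x <- rnorm(30)
  y <- rnorm(40)
  out <- mann_whitney(x, y)
  expect_equal(out$method, "mw_normal")
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                      correct = TRUE))
  expect_equal(out$p_value, ref$p.value)
  tied <- mann_whitney(c(1, 1, 2, 3), c(1, 2, 2, 4))
  expect_equal(tied$method, "mw_normal")
})

test_that("Spearman test reports rho, t-approximate p and direction", {
  up <- spearman_test(1:10, (1:10)^2)
  expect_equal(up$statistic, 1)
  expect_equal(up$direction, 1L)
  down <- spearman_test(1:10, -(1:10)^3)
  expect_equal(down$statistic, -1)
  expect_equal(down$direction, -1L)
  expect_error(spearman_test(rep(1, 5), 1:5), "zero variance")
  expect_error(spearman_test(1:4, 1:3), "equal length")

  set.seed(2)
  x <- rnorm(25)
  y <- 0.3 * x + rnorm(25)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                   exact = FALSE))
  got <- spearman_test(x, y)
  expect_equal(got$statistic, unname(ref$estimate))
  expect_equal(got$p_value, ref$p.value)
})

test_that("p-value adjustment matches hand cases and the literal BH oracle", {
  expect_equal(adjust_pvalues(c(0.01, 0.04), "bonferroni"), c(0.02, 0.08))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bh"),
               c(0.03, 0.03, 0.03))
  expect_identical(adjust_pvalues(numeric(0), "bh"), numeric(0))
  expect_error(adjust_pvalues(c(0.5, 1.2), "bh"), "0, 1")

  set.seed(77)
  for (rep in 1:1000) {
    p <- runif(sample(1:12, 1))
    expect_equal(adjust_pvalues(p, "bh"), bh_stepup(p))
  }
})

test_that("BH adjustment is monotone non-decreasing in sorted order", {
  set.seed(8)
  for (rep in 1:50) {
    p <- runif(sample(2:30, 1))
    adj <- adjust_pvalues(p, "bh")
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    expect_true(all(adj >= p - 1e-15))
  }
})

test_that("nested label test agrees with the stacked-lm partial F oracle", {
  set.seed(31)
  sim <- simulate_regime("zzm", mu = 0.4, n_per_class = 15, n_triplets = 3,
                         seed = 4)
  clad <- build_cladogram(sim$table)
  y <- sim$labels$values[clad$sample_ids]
  for (d in 1:3) {
    got <- nested_label_test(clad, sim$labels, d)
    nodes <- which(clad$depth <= d)
    dat <- data.frame(value = as.vector(t(clad$values[nodes, ,
                                                      drop = FALSE])),
                      node = factor(rep(clad$paths[nodes],
                                        each = length(clad$sample_ids))),
                      label = factor(rep(y, times = length(nodes))))
    if (nlevels(dat$node) > 1L) {
      fit0 <- lm(value ~ node, dat)
      fit1 <- lm(value ~ node + label + label:node, dat)
    } else {
      fit0 <- lm(value ~ 1, dat)
      fit1 <- lm(value ~ label, dat)
    }
    an <- anova(fit0, fit1)
    expect_equal(got$statistic, an$F[2], tolerance = 1e-10)
    expect_equal(got$p_value, an$`Pr(>F)`[2], tolerance = 1e-10)
  }

  # continuous labels: per-node regression oracle
  cont <- label_vector(setNames(rnorm(length(clad$sample_ids)),
                                clad$sample_ids))
  got <- nested_label_test(clad, cont, 2)
  nodes <- which(clad$depth <= 2)
  dat <- data.frame(value = as.vector(t(clad$values[nodes, ,
                                                    drop = FALSE])),
                    node = factor(rep(clad$paths[nodes],
                                      each = length(clad$sample_ids))),
                    label = rep(cont$values[clad$sample_ids],
                                times = length(nodes)))
  an <- anova(lm(value ~ node, dat),
              lm(value ~ node + label + label:node, dat))
  expect_equal(got$statistic, an$F[2], tolerance = 1e-10)
  expect_equal(got$p_value, an$`Pr(>F)`[2], tolerance = 1e-10)
})

test_that("nested label test finds a strong kingdom effect and rejects degenerate input", {
  set.seed(40)
  n <- 40
  y <- rep(c(1, 0), each = n / 2)
  m <- matrix(y + rnorm(n, sd = 0.1), ncol = 1,
              dimnames = list(sprintf("s%03d", 1:n), "King"))
  tt <- taxa_table(m, value_kind = "log_processed", dialect = "bare")
  clad <- build_cladogram(tt)
  lab <- label_vector(setNames(y, rownames(m)))
  out <- nested_label_test(clad, lab, 1)
  expect_lt(out$p_value, 1e-6)

  const <- taxa_table(matrix(1, nrow = n, ncol = 1,
                             dimnames = list(rownames(m), "King")),
                      value_kind = "log_processed", dialect = "bare")
  expect_error(nested_label_test(build_cladogram(const), lab, 1),
               "degenerate")
})

test_that("joint mother-and-daughter significance is far rarer than alpha", {
  # under the pure-null triplet regime the mother is the mean of its three
  # daughters (corr 1/sqrt(3)), so requiring both tests at alpha gives a
  # joint rate well below alpha, close in magnitude to alpha^2
  set.seed(55)
  n <- 25
  reps <- 4000
  hits <- 0L
  y <- rep(c(1, 0), each = n)
  for (r in seq_len(reps)) {
    z <- matrix(rnorm(3 * 2 * n), nrow = 3)
    mo <- colMeans(z)
    pm <- mann_whitney(mo[y == 1], mo[y == 0])$p_value
    if (pm < 0.05 &&
        mann_whitney(z[1, y == 1], z[1, y == 0])$p_value < 0.05)
      hits <- hits + 1L
  }
  rate <- hits / reps
  expect_lt(rate, 0.05 / 3)
  expect_gt(rate, 0.0025 / 3)
})
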