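test_that("sister correction keeps the best child and BH-screens the rest", {
  expect_equal(sister_correct(c(a = 0.01, b = 0.04, c = 0.2), 0.05), "a")
  # BH over (0.04, 0.2) -> (0.08, 0.2), both >= 0.05
  expect_setequal(sister_correct(c(a = 0.001, b = 0.002), 0.05),
                  c("a", "b"))  # single-value BH identity
  expect_equal(sister_correct(c(a = 0.01, b = 0.3), 0.05), "a")
  expect_equal(sister_correct(c(a = 0.5), 0.05), character(0))
  # ties on the minimum broken lexicographically
  expect_equal(sister_correct(c(b = 0.01, a = 0.01), 0.5)[1], "a")
  expect_error(sister_correct(numeric(0)), "non-empty")
  expect_error(sister_correct(c(a = 1.2)), "0, 1")
})

test_that("a priori scan stops at the first significant depth", {
  sim <- simulate_regime("zzm", mu = 1.5, n_per_class = 40, seed = 2)
  clad <- build_cladogram(sim$table)
  ap <- apriori_scan(clad, sim$labels, 0.05)
  expect_true(ap$explainable)
  expect_equal(ap$first_significant_depth, 1L)
  expect_length(ap$per_depth_p, 1L)  # only one depth computed

  null <- simulate_regime("zzz", n_per_class = 20, n_triplets = 2,
                          seed = 8)
  clad0 <- build_cladogram(null$table)
  ap0 <- apriori_scan(clad0, null$labels, 1e-6)  # absurdly strict alpha
  expect_false(ap0$explainable)
  expect_length(ap0$per_depth_p, 3L)  # scanned every depth
  expect_true(is.na(ap0$first_significant_depth))
})

test_that("trajectory descends only through significant ancestors", {
  set.seed(61)
  fx <- shifted_tree_table(n_per_class = 100, shift = 2)
  clad <- build_cladogram(fx$table)
  taxa <- trajectory_test(clad, fx$labels, alpha = 0.05, start_level = 1)
  expect_true("Bac" %in% taxa$path)
  expect_true("Bac;phyA" %in% taxa$path)
  expect_true(any(grepl("^Bac;phyA;", taxa$path)))
  expect_false("Bac;phyB" %in% taxa$path)
  expect_false(any(grepl("^Bac;phyB;", taxa$path)))  # descent stopped
  expect_true(all(taxa$source == "trajectory"))
  expect_true(all(taxa$direction[grepl("phyA", taxa$path)] == 1L))
})

test_that("null labels rarely produce any trajectory taxon", {
  set.seed(71)
  hits <- 0L
  for (rep in 1:40) {
    fx <- shifted_tree_table(n_per_class = 25, shift = 0)
    clad <- build_cladogram(fx$table)
    taxa <- trajectory_test(clad, fx$labels, 0.05, 1)
    if (nrow(taxa) > 0) hits <- hits + 1L
  }
  expect_lte(hits / 40, 0.15)  # bounded by the level-1 alpha plus noise
})

test_that("leaf rescue applies the Bonferroni arithmetic across leaves", {
  set.seed(83)
  n <- 60
  y <- rep(c(1, 0), each = n / 2)
  m <- matrix(rnorm(n * 100), nrow = n)
  m[, 1] <- m[, 1] + 1.8 * y  # one strongly shifted leaf
  rownames(m) <- sprintf("s%03d", 1:n)
  colnames(m) <- sprintf("K;P%02d;sp%03d", rep(1:10, each = 10), 1:100)
  tt <- taxa_table(m, value_kind = "log_processed", dialect = "bare")
  clad <- build_cladogram(tt)
  lab <- label_vector(setNames(y, rownames(m)))
  res <- leaf_test(clad, lab, 0.05, "bonferroni")
  expect_true("K;P01;sp001" %in% res$path)
  raw <- mann_whitney(m[y == 1, 1], m[y == 0, 1])$p_value
  expect_equal(res$adjusted_p[res$path == "K;P01;sp001"],
               min(1, raw * 100))
  expect_true(all(res$source == "leaf"))

  # a best raw p of ~0.03 cannot survive Bonferroni across 100 leaves
  m2 <- m
  m2[, 1] <- rnorm(n)
  tt2 <- taxa_table(m2, value_kind = "log_processed", dialect = "bare")
  res2 <- leaf_test(build_cladogram(tt2), lab, 0.05)
  expect_lte(nrow(res2), 1L)  # overwhelmingly empty under the null
})

test_that("the full fit unions trajectory and leaf discoveries", {
  set.seed(93)
  fx <- shifted_tree_table(n_per_class = 100, shift = 2)
  fit <- cladoda(fx$table, fx$labels)
  expect_s3_class(fit, "cladoda")
  expect_true(fit$apriori$explainable)
  expect_equal(fit$used_start_level, 1L)
  # strongly shifted species are found by both branches -> source "both"
  both <- fit$taxa[fit$taxa$path %in% c("Bac;phyA;spA1", "Bac;phyA;spA2"), ]
  expect_true(all(both$source == "both"))
  expect_false(any(duplicated(paste(fit$taxa$path, fit$taxa$depth))))
})

test_that("an unexplainable label yields an empty result and no testing", {
  set.seed(97)
  null <- simulate_regime("zzz", n_per_class = 30, seed = 12)
  fit <- cladoda(null$table, null$labels, alpha = 1e-8)
  expect_false(fit$apriori$explainable)
  expect_equal(nrow(fit$taxa), 0L)
  expect_true(is.na(fit$used_start_level))
})

test_that("escalation moves the start level when level 1 is silent", {
  # two kingdoms with opposite label effects cancel at no level-1 node;
  # phyla inside each kingdom carry clean signal
  set.seed(103)
  n <- 120
  y <- rep(c(1, 0), each = n / 2)
  eff <- 1.5 * y
  m <- cbind("Ka;p1;s1" = rnorm(n) + eff, "Ka;p2;s1" = rnorm(n) - eff,
             "Kb;p1;s1" = rnorm(n) + eff, "Kb;p2;s1" = rnorm(n) - eff)
  rownames(m) <- sprintf("s%03d", 1:n)
  tt <- taxa_table(m, value_kind = "log_processed", dialect = "bare")
  lab <- label_vector(setNames(y, rownames(m)))
  fit <- cladoda(tt, lab)
  expect_true(fit$apriori$explainable)
  expect_equal(fit$used_start_level, 2L)
  expect_true(all(c("Ka;p1", "Ka;p2") %in% fit$taxa$path))

  # pinning the start level disables escalation
  fit1 <- cladoda(tt, lab, start_level = 1)
  expect_equal(fit1$used_start_level, 1L)
  expect_false(any(fit1$taxa$source == "trajectory"))
})

test_that("every trajectory taxon has a fully significant ancestor chain", {
  for (seed in c(3, 14, 15)) {
    sim <- simulate_regime("zzm", mu = 0.8, n_per_class = 60, seed = seed)
    fit <- cladoda(sim$table, sim$labels)
    traj <- fit$taxa[fit$taxa$source %in% c("trajectory", "both"), ]
    if (nrow(traj) == 0) next
    keys <- paste(traj$path, traj$depth)
    for (i in seq_len(nrow(traj))) {
      if (traj$depth[i] <= fit$used_start_level) next
      parts <- strsplit(traj$path[i], ";", fixed = TRUE)[[1]]
      for (d in seq(fit$used_start_level, traj$depth[i] - 1)) {
        anc <- paste(parts[seq_len(d)], collapse = ";")
        expect_true(paste(anc, d) %in% keys,
                    info = paste("missing ancestor", anc, "of",
                                 traj$path[i]))
      }
    }
  }
})

test_that("identical inputs give identical fits (determinism)", {
  sim <- simulate_microbiome(n_samples = 60, n_features = 60, n_up = 3,
                             n_down = 3, seed = 5)
  f1 <- cladoda(sim$table, sim$labels)
  f2 <- cladoda(sim$table, sim$labels)
  expect_identical(f1$taxa, f2$taxa)
  expect_identical(f1$apriori, f2$apriori)
})

test_that("adding pure-noise deep features never unseats trajectory ancestors", {
  set.seed(113)
  fx <- shifted_tree_table(n_per_class = 80, shift = 1.5)
  base_fit <- trajectory_test(build_cladogram(fx$table), fx$labels, 0.05, 1)
  # graft noise species under the existing null phylum (level-1 pool and
  # phylum-A's sister pool sizes are unchanged)
  extra <- matrix(rnorm(nrow(fx$table$values) * 3),
                  ncol = 3,
                  dimnames = list(rownames(fx$table$values),
                                  sprintf("Bac;phyB;noise%d", 1:3)))
  tt2 <- taxa_table(cbind(fx$table$values, extra),
                    value_kind = "log_processed", dialect = "bare")
  aug_fit <- trajectory_test(build_cladogram(tt2), fx$labels, 0.05, 1)
  anc <- intersect(c("Bac", "Bac;phyA"), base_fit$path)
  expect_true(all(anc %in% aug_fit$path))
})
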