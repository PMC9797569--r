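test_that("spearman_with_p reproduces closed-form and oracle values", {
  r <- spearman_with_p(1:25, 1:25, min_pairs = 20)
  expect_equal(r$rho, 1)
  expect_equal(r$p, 0)

  # no ties: 1 - 6*sum(d^2)/(n(n^2-1)) with sum(d^2) = 4 gives 0.8
  r <- spearman_with_p(1:5, c(1, 3, 2, 5, 4), min_pairs = 3)
  expect_equal(r$rho, 0.8)

  # tied data matches the brute-force average-rank oracle
  set.seed(7)
  for (i in 1:25) {
    x <- sample(1:4, 8, replace = TRUE)
    y <- sample(1:4, 8, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(spearman_with_p(x, y, min_pairs = 3)$rho,
                 oracle_spearman_rho(x, y), tolerance = 1e-12)
  }
})

test_that("spearman flags short or constant inputs instead of returning 0", {
  r <- spearman_with_p(c(1:5, rep(NA, 20)), c(1:5, rep(NA, 20)))
  expect_false(r$ok)
  expect_match(r$reason, "min_pairs")
  expect_true(is.na(r$rho))

  r <- spearman_with_p(rep(1, 30), rnorm(30))
  expect_false(r$ok)
  expect_match(r$reason, "constant")
})

test_that("bh_adjust follows the step-up formula and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(11)
  for (i in 1:20) {
    p <- runif(50)^2
    q <- bh_adjust(p)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    # monotone in p
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
    # invariant to input order
    perm <- sample(50)
    expect_equal(bh_adjust(p[perm]), q[perm])
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("codependency_map recovers a planted module and ranks by rho", {
  ge <- simulate_gene_effect(n_genes = 60, n_lines = 500, n_modules = 3,
                             module_size = 8, loading = 0.8,
                             essential_fraction = 0, seed = 101)
  truth <- ge$truth$module_assignments
  query <- names(truth)[truth == 2L & !is.na(truth)][1]
  partners <- setdiff(names(truth)[truth == 2L & !is.na(truth)], query)
  res <- codependency_map(ge$gem, query)
  expect_false(query %in% res$gene)
  expect_true(all(diff(res$rho) <= 1e-15))  # sorted by rho descending
  called <- res$gene[res$class == "codependent"]
  expect_true(all(partners %in% called))
  # module partners occupy the top of the ranking
  expect_setequal(res$gene[seq_along(partners)], partners)
  expect_error(codependency_map(ge$gem, "NOT_A_GENE"), "NOT_A_GENE")
})

test_that("a duplicated query profile ranks first with rho 1", {
  set.seed(3)
  vals <- matrix(rnorm(40 * 30), 40, 30)
  vals[2, ] <- vals[1, ]
  gem <- make_gem(vals)
  res <- codependency_map(gem, "g001")
  expect_identical(res$gene[1], "g002")
  expect_equal(res$rho[1], 1)
  expect_identical(res$class[1], "codependent")
})

test_that("co-dependency is symmetric and invariant to line permutation", {
  set.seed(5)
  vals <- matrix(rnorm(10 * 60), 10, 60)
  gem <- make_gem(vals)
  ab <- spearman_with_p(vals[1, ], vals[2, ])
  ba <- spearman_with_p(vals[2, ], vals[1, ])
  expect_equal(ab$rho, ba$rho)
  perm <- sample(60)
  gem2 <- make_gem(vals[, perm])
  r1 <- codependency_map(gem, "g001")
  r2 <- codependency_map(gem2, "g001")
  expect_equal(r1$rho, r2$rho)
  expect_equal(r1$q, r2$q)
})

test_that("essentiality thresholds are strict and profiles complete", {
  vals <- rbind(rep(-2, 10), rep(-0.5, 10), c(rep(-0.7, 6), rep(0.2, 4)))
  dimnames(vals) <- list(c("dead", "edge", "mixed"), paste0("c", 1:10))
  prof <- essentiality_profile(gene_effect_matrix(vals))$profile
  expect_true(prof$is_essential[prof$gene == "dead"])
  expect_equal(prof$frac_strong_kill[prof$gene == "dead"], 1)
  # median exactly at -0.5 is NOT essential ("lower than" is strict)
  expect_false(prof$is_essential[prof$gene == "edge"])
  expect_equal(prof$frac_essential_lines[prof$gene == "edge"], 0)
  expect_equal(prof$frac_essential_lines[prof$gene == "mixed"], 0.6)
  expect_true(all(prof$frac_strong_kill <= prof$frac_essential_lines))
  expect_setequal(prof$rank_by_median, 1:3)
})

test_that("planted essential genes are classified essential in replicates", {
  for (s in 1:20) {
    ge <- simulate_gene_effect(n_genes = 50, n_lines = 40,
                               essential_fraction = 0.2, seed = 7000 + s)
    prof <- essentiality_profile(ge$gem)$profile
    called <- prof$gene[prof$is_essential]
    expect_setequal(called, ge$truth$essential_genes)
  }
})

test_that("per-lineage summaries respect the minimum line count", {
  ge <- simulate_gene_effect(n_genes = 10, n_lines = 23, n_lineages = 4,
                             seed = 9)
  # 23 lines round-robin over 4 lineages: sizes 6,6,6,5 -> all kept at min 5
  prof <- essentiality_profile(ge$gem, min_lines = 5)
  expect_setequal(unique(prof$by_lineage$lineage),
                  sprintf("lineage%02d", 1:4))
  prof6 <- essentiality_profile(ge$gem, min_lines = 6)
  expect_false("lineage04" %in% prof6$by_lineage$lineage)
  expect_true(all(prof$by_lineage$q1 <= prof$by_lineage$median_effect))
})

test_that("top_k_overlap partitions the union and handles short lists", {
  ge <- simulate_gene_effect(n_genes = 80, n_lines = 200, n_modules = 2,
                             module_size = 10, loading = 0.7, seed = 21)
  truth <- ge$truth$module_assignments
  qa <- names(truth)[truth == 1L & !is.na(truth)][1]
  qb <- names(truth)[truth == 2L & !is.na(truth)][1]
  ra <- codependency_map(ge$gem, qa)
  rb <- codependency_map(ge$gem, qb)
  same <- top_k_overlap(ra, ra, k = 15)
  expect_equal(same$count_shared, 15)
  expect_equal(same$count_A_only, 0)

  ov <- top_k_overlap(ra, rb, k = 9)
  expect_equal(ov$count_shared + ov$count_A_only, 9)
  expect_equal(ov$count_shared + ov$count_B_only, 9)
  # k beyond the positive set falls back to all positive-rho genes
  big <- top_k_overlap(ra, rb, k = 10000)
  expect_lte(big$k_A, sum(ra$rho > 0, na.rm = TRUE))
})

test_that("disjoint-module top-k overlap matches the hypergeometric null", {
  # two queries with unrelated profiles: E[shared] = k^2 / G among background
  shared <- numeric(40)
  for (s in seq_along(shared)) {
    ge <- simulate_gene_effect(n_genes = 102, n_lines = 60, seed = 3000 + s)
    ra <- codependency_map(ge$gem, "G0001", min_pairs = 20)
    rb <- codependency_map(ge$gem, "G0002", min_pairs = 20)
    shared[s] <- top_k_overlap(ra, rb, k = 25)$count_shared
  }
  # G = 100 shared universe, k = 25 -> expectation 6.25
  expect_gt(mean(shared), 6.25 - 2)
  expect_lt(mean(shared), 6.25 + 2)
})

test_that("correlation clustering separates planted blocks deterministically", {
  # block-diagonal 2-block correlation matrix splits at the top
  M <- matrix(0, 6, 6, dimnames = list(paste0("x", 1:6), paste0("x", 1:6)))
  M[1:3, 1:3] <- 0.9; M[4:6, 4:6] <- 0.9; diag(M) <- 1
  cm <- cluster_correlation_matrix(M)
  top2 <- cut_clusters(cm, 2)
  expect_length(unique(top2[c("x1", "x2", "x3")]), 1)
  expect_length(unique(top2[c("x4", "x5", "x6")]), 1)
  expect_false(top2[["x1"]] == top2[["x4"]])

  # identity matrix: all merges at the same height
  I6 <- diag(6); dimnames(I6) <- dimnames(M)
  ci <- cluster_correlation_matrix(I6)
  expect_equal(ci$hclust$height, rep(1, 5))

  expect_error(cluster_correlation_matrix(matrix(c(1, 0.5, 0.2, 1), 2, 2)),
               "asymmetric")
})

test_that("planted modules are recovered by clustering with Rand >= 0.95", {
  ge <- simulate_gene_effect(n_genes = 40, n_lines = 300, n_modules = 3,
                             module_size = 10, loading = 0.8, seed = 33)
  truth <- ge$truth$module_assignments
  mod_genes <- names(truth)[!is.na(truth)]
  M <- cor(t(ge$gem$values[mod_genes, ]), method = "spearman")
  cm <- cluster_correlation_matrix(M)
  cl <- cut_clusters(cm, 3)[mod_genes]
  n <- length(mod_genes); agree <- 0; tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    agree <- agree + ((cl[i] == cl[j]) == (truth[mod_genes][i] == truth[mod_genes][j]))
    tot <- tot + 1
  }
  expect_gte(agree / tot, 0.95)
})
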