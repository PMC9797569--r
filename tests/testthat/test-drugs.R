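test_that("dedup_auc removes wide duplicates, averages close ones, keeps singletons", {
  raw <- drug_response_raw(
    drug_id = c("d1", "d1", "d2", "d2", "d3"),
    cell_line_id = c("c1", "c1", "c1", "c1", "c1"),
    auc = c(0.50, 0.75, 0.50, 0.60, 0.42))
  tab <- dedup_auc(raw)
  expect_true(is.na(tab$auc["d1", "c1"]))       # range 0.25 > 0.2: removed
  expect_equal(tab$auc["d2", "c1"], 0.55)       # range 0.10: averaged
  expect_equal(tab$auc["d3", "c1"], 0.42)       # singleton passthrough
  expect_equal(tab$n_removed, 1)
  expect_true(tab$from_duplicates["d2", "c1"])
  expect_false(tab$from_duplicates["d3", "c1"])

  # a range of exactly 0.2 is tolerated (strictly greater is removed)
  raw2 <- drug_response_raw(c("d", "d"), c("c", "c"), c(0.4, 0.6))
  expect_equal(dedup_auc(raw2)$auc["d", "c"], 0.5)

  # >2 replicates: range = max - min over all of them
  raw3 <- drug_response_raw(rep("d", 3), rep("c", 3), c(0.40, 0.50, 0.65))
  expect_true(is.na(dedup_auc(raw3)$auc["d", "c"]))
})

test_that("dedup without duplicates is the identity on values", {
  set.seed(73)
  raw <- drug_response_raw(rep(paste0("d", 1:4), each = 5),
                           rep(paste0("c", 1:5), times = 4),
                           runif(20))
  tab <- dedup_auc(raw)
  expect_equal(unname(tab$auc["d2", "c3"]),
               raw$auc[raw$drug_id == "d2" & raw$cell_line_id == "c3"])
  expect_false(any(tab$from_duplicates))
  expect_equal(tab$n_removed, 0)
})

test_that("coverage_filter applies a strict < threshold on line fraction", {
  auc <- matrix(runif(200), 2, 100,
                dimnames = list(c("d69", "d70"), paste0("c", 1:100)))
  auc["d69", 1:31] <- NA  # 69 of 100 lines
  auc["d70", 1:30] <- NA  # 70 of 100 lines
  tab <- structure(list(auc = auc, from_duplicates = auc == auc,
                        n_removed = 0L), class = "drug_response_table")
  kept <- coverage_filter(tab, min_frac = 0.7)
  expect_identical(rownames(kept$auc), "d70")
  expect_identical(rownames(coverage_filter(tab, min_frac = 0)$auc),
                   c("d69", "d70"))
  expect_error(coverage_filter(kept, min_frac = 0.999), "every drug")
})

test_that("dedup then coverage filter is idempotent", {
  dr <- simulate_drug_response(10, 60, n_clusters = 1, cluster_size = 4,
                               effect_size = 0.5, dup_fraction = 0.2,
                               seed = 79)
  once <- coverage_filter(dedup_auc(dr$raw))
  twice <- coverage_filter(once)
  expect_identical(once$auc, twice$auc)
})

test_that("drug ranking ascends by median AUC with deterministic ties", {
  auc <- rbind(a = c(0.9, 0.9, 0.9), b = c(0.2, 0.2, 0.2),
               m = c(0.5, 0.5, 0.5))
  colnames(auc) <- paste0("c", 1:3)
  tab <- structure(list(auc = auc, from_duplicates = auc > 2, n_removed = 0L),
                   class = "drug_response_table")
  rk <- rank_drugs_by_median_auc(tab)
  expect_identical(rk$drug, c("b", "m", "a"))
  expect_identical(rk$rank, c(1L, 2L, 3L))

  single <- structure(list(auc = auc[1, , drop = FALSE],
                           from_duplicates = auc[1, , drop = FALSE] > 2,
                           n_removed = 0L), class = "drug_response_table")
  expect_identical(rank_drugs_by_median_auc(single)$rank, 1L)

  # brute-force sort oracle on random tables
  set.seed(83)
  for (i in 1:100) {
    nd <- sample(3:8, 1); nl <- sample(5:12, 1)
    vals <- matrix(runif(nd * nl), nd, nl,
                   dimnames = list(paste0("d", seq_len(nd)),
                                   paste0("c", seq_len(nl))))
    vals[sample(length(vals), floor(length(vals) / 5))] <- NA
    vals[, 1] <- runif(nd)  # keep every drug measured at least once
    t2 <- structure(list(auc = vals, from_duplicates = !is.na(vals),
                         n_removed = 0L), class = "drug_response_table")
    rk <- rank_drugs_by_median_auc(t2)
    med <- apply(vals, 1, median, na.rm = TRUE)
    expect_identical(rk$drug[1], names(sort(med))[1])
    expect_true(all(diff(rk$median_auc) >= -1e-15))
  }
})

test_that("drug-drug correlations identify duplicated drugs and planted clusters", {
  set.seed(89)
  base <- matrix(runif(5 * 40), 5, 40,
                 dimnames = list(paste0("d", 1:5), paste0("c", 1:40)))
  base["d2", ] <- base["d1", ]  # same drug under two names
  tab <- structure(list(auc = base, from_duplicates = base > 2, n_removed = 0L),
                   class = "drug_response_table")
  dc <- drug_drug_correlations(tab)
  expect_equal(dc$rho["d1", "d2"], 1)
  expect_identical(unname(dc$most_similar["d1"]), "d2")
  expect_identical(unname(dc$most_similar["d2"]), "d1")
  expect_true(isSymmetric(dc$rho))

  # permuting cell lines leaves the correlation matrix unchanged
  perm <- sample(40)
  tab2 <- tab; tab2$auc <- tab$auc[, perm]; tab2$from_duplicates <- tab$from_duplicates[, perm]
  expect_equal(drug_drug_correlations(tab2)$rho, dc$rho)

  # planted 4-drug cluster comes out as one clade / mutual top partners
  dr <- simulate_drug_response(12, 300, n_clusters = 1, cluster_size = 4,
                               effect_size = 0.8, seed = 97)
  tabc <- coverage_filter(dedup_auc(dr$raw))
  dcc <- drug_drug_correlations(tabc)
  cl <- names(dr$truth$cluster_assignments)[
    !is.na(dr$truth$cluster_assignments)]
  expect_true(all(dcc$most_similar[cl] %in% cl))
  clades <- cut_clusters(dcc$clustered, 2)
  expect_length(unique(clades[cl]), 1)
})

test_that("sensitivity signatures classify by correlation sign at q < alpha", {
  dr <- simulate_drug_response(8, 300, n_clusters = 1, cluster_size = 4,
                               n_signature_genes = 6, n_genes = 60,
                               effect_size = 0.7, seed = 101)
  tab <- dedup_auc(dr$raw)
  drug <- names(dr$truth$cluster_assignments)[1]
  sig <- sensitivity_signature(tab, drug, dr$expr)
  planted_s <- dr$truth$sensitivity_genes[[drug]]
  planted_r <- dr$truth$resistance_genes[[drug]]
  expect_true(all(sig$class[sig$gene %in% planted_s] == "sensitivity"))
  expect_true(all(sig$class[sig$gene %in% planted_r] == "resistance"))
  expect_true(all(sig$rho[sig$class == "sensitivity"] < 0, na.rm = TRUE))
  expect_true(all(sig$rho[sig$class == "resistance"] > 0, na.rm = TRUE))
  expect_error(sensitivity_signature(tab, "NOPE", dr$expr), "NOPE")
})

test_that("a gene tracking AUC exactly is a perfect resistance marker", {
  set.seed(103)
  auc <- matrix(runif(2 * 30), 2, 30,
                dimnames = list(c("d1", "d2"), paste0("c", 1:30)))
  tab <- structure(list(auc = auc, from_duplicates = auc > 2, n_removed = 0L),
                   class = "drug_response_table")
  ev <- rbind(auc["d1", ], matrix(rnorm(5 * 30, 6), 5, 30))
  rownames(ev) <- c("mirror", paste0("g", 1:5))
  colnames(ev) <- colnames(auc)
  sig <- sensitivity_signature(tab, "d1", expression_matrix(ev))
  expect_equal(sig$rho[sig$gene == "mirror"], 1)
  expect_identical(sig$class[sig$gene == "mirror"], "resistance")
})

test_that("signature GSEA inverts correlations and recovers planted sets", {
  dr <- simulate_drug_response(8, 300, n_clusters = 1, cluster_size = 4,
                               n_signature_genes = 8, n_genes = 80,
                               effect_size = 0.8, seed = 107)
  tab <- dedup_auc(dr$raw)
  drug <- names(dr$truth$cluster_assignments)[1]
  sig <- sensitivity_signature(tab, drug, dr$expr)
  sets <- gene_set_collection(list(
    SENS = dr$truth$sensitivity_genes[[drug]],
    RES = dr$truth$resistance_genes[[drug]],
    RAND = sprintf("G%04d", 41:60)))
  enr <- signature_gsea(sig, sets, n_perm = 300, seed = 3)
  expect_identical(enr$set[which.max(enr$NES)], "SENS")
  expect_lt(enr$q[enr$set == "SENS"], 0.1)
  expect_lt(enr$NES[enr$set == "RES"], 0)

  # determinism and antisymmetry under rho negation
  enr2 <- signature_gsea(sig, sets, n_perm = 300, seed = 3)
  expect_identical(enr, enr2)
  flip <- sig; flip$rho <- -flip$rho
  enr3 <- signature_gsea(flip, sets, n_perm = 300, seed = 3)
  es3 <- setNames(enr3$ES, enr3$set)
  expect_equal(unname(es3[enr$set]), -enr$ES, tolerance = 1e-12)
})
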