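test_that("mean gene-set score matches the dense column-subset mean", {
  nm <- toy_norm(rbind(c(2, 4, 9), c(1, 1, 1)))
  expect_equal(unname(score_gene_set_mean(nm, c("g1", "g2"))), c(3, 1))
  # single-gene set equals that gene's column
  expect_equal(unname(score_gene_set_mean(nm, "g3")),
               as.numeric(nm$values[, "g3"]))
  # gene order and duplicate listing are irrelevant
  expect_equal(score_gene_set_mean(nm, c("g2", "g1", "g2")),
               score_gene_set_mean(nm, c("g1", "g2")))
  expect_error(score_gene_set_mean(nm, "absent", set_name = "setX"),
               "setX")

  set.seed(71)
  dense <- matrix(rexp(20 * 30), 20, 30,
                  dimnames = list(paste0("c", 1:20), paste0("g", 1:30)))
  nm2 <- toy_norm(dense)
  genes <- sample(colnames(dense), 7)
  expect_equal(unname(score_gene_set_mean(nm2, genes)),
               unname(rowMeans(dense[, genes])), tolerance = 1e-12)
})

test_that("binned-reference score is zero in degenerate configurations", {
  # every gene identical in every cell: any control draw cancels the set
  nm <- toy_norm(matrix(3, 10, 60))
  s <- score_gene_set_binned_ref(nm, c("g1", "g2"), n_bins = 5,
                                 ctrl_per_gene = 5, seed = 1)
  expect_equal(unname(s), rep(0, 10))
  # forcing the control set equal to the gene set cancels exactly
  set.seed(72)
  nm2 <- toy_norm(matrix(rexp(300), 10, 30))
  s2 <- score_gene_set_binned_ref(nm2, c("g1", "g5"),
                                  control_genes = c("g1", "g5"))
  expect_equal(unname(s2), rep(0, 10), tolerance = 1e-12)
})

test_that("binned-reference score detects a planted program and is seeded", {
  expr <- gen_expression(n_cells_per_state = c(A = 80, B = 80),
                         n_genes = 300, effect = 1.5, seed = 73)
  nm <- normalize_log(expr$counts)
  s <- suppressWarnings(
    score_gene_set_binned_ref(nm, expr$markers$A, ctrl_per_gene = 10,
                              seed = 9))
  expect_gt(mean(s[expr$labels == "A"]), mean(s[expr$labels == "B"]))
  s_again <- suppressWarnings(
    score_gene_set_binned_ref(nm, expr$markers$A, ctrl_per_gene = 10,
                              seed = 9))
  expect_identical(s, s_again)
})

test_that("binned-reference score of a random set is centred on zero", {
  set.seed(74)
  # exchangeable data: iid expression, no structure
  nm <- toy_norm(matrix(rexp(40 * 200), 40, 200))
  means <- vapply(1:30, function(i) {
    genes <- sample(colnames(nm$values), 8)
    mean(score_gene_set_binned_ref(nm, genes, n_bins = 10,
                                   ctrl_per_gene = 10, seed = i))
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.05)  # expression scale is Exp(1), mean 1
})

test_that("rank-sum p matches exact enumeration on small groups", {
  sc <- cbind(drug = c(5, 6, 7, 1, 2, 3))
  rownames(sc) <- paste0("c", 1:6)
  labels <- setNames(c("A", "A", "A", "B", "B", "B"), rownames(sc))
  res <- rank_sets_for_group(sc, labels, "A", lfc_min = 0)
  expect_equal(res$p, oracle_ranksum_exact(c(5, 6, 7), c(1, 2, 3)))
  expect_equal(res$p, 2 / 20)  # the two one-sided extremes among C(6,3)
})

test_that("identical score distributions are not flagged", {
  sc <- cbind(drug = c(1:10, 1:10))
  rownames(sc) <- paste0("c", 1:20)
  labels <- setNames(rep(c("A", "B"), each = 10), rownames(sc))
  res <- rank_sets_for_group(sc, labels, "A", exact_max = 0)
  expect_equal(res$p, 1)  # rank sum sits exactly at its null expectation
  expect_false(res$flagged)
  # fully constant scores: degenerate contract
  sc2 <- cbind(drug = rep(1, 20))
  rownames(sc2) <- rownames(sc)
  res2 <- rank_sets_for_group(sc2, labels, "A")
  expect_equal(res2$p, 1)
  expect_equal(res2$lfc, 0)
})

test_that("flags are invariant under strictly monotone score transforms", {
  set.seed(75)
  sc <- cbind(d1 = rexp(30), d2 = c(rexp(15, 1 / 5), rexp(15)))
  rownames(sc) <- paste0("c", 1:30)
  labels <- setNames(rep(c("A", "B"), each = 15), rownames(sc))
  base <- rank_sets_for_group(sc, labels, "A", lfc_min = -Inf)
  cubed <- rank_sets_for_group(sc^3, labels, "A", lfc_min = -Inf)
  expect_equal(base$p[order(base$set)], cubed$p[order(cubed$set)])
  expect_equal(base$flagged[order(base$set)],
               cubed$flagged[order(cubed$set)])
})

test_that("planted drug is flagged only for its target state", {
  expr <- gen_expression(n_cells_per_state = c(A = 60, B = 60, C = 60),
                         n_genes = 300, effect = 2, seed = 76)
  nm <- normalize_log(expr$counts)
  s <- suppressWarnings(score_gene_set_binned_ref(nm, expr$markers$A,
                                                  ctrl_per_gene = 10,
                                                  seed = 3))
  sc <- cbind(drugA = s)
  flagged_for <- vapply(c("A", "B", "C"), function(g) {
    rank_sets_for_group(sc, expr$labels, g, lfc_min = 1)$flagged
  }, logical(1))
  expect_true(flagged_for[["A"]])
  expect_false(any(flagged_for[c("B", "C")]))
})

test_that("Welch t-test matches the closed-form oracle", {
  x <- c(0, 0, 0, 2); y <- c(5, 5, 5, 7)
  nm <- toy_norm(cbind(g1 = c(x, y)))
  labels <- setNames(rep(c("A", "B"), each = 4), rownames(nm$values))
  res <- deg_t_test(nm, labels, "A")
  o <- oracle_welch(x, y)
  expect_equal(res$t, o$t, tolerance = 1e-12)
  expect_equal(res$p, o$p, tolerance = 1e-12)
  # cross-check against the stats implementation
  tt <- t.test(x, y)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
})

test_that("constant genes yield p = 1 and planted markers are recovered", {
  nm <- toy_norm(cbind(g1 = rep(2, 10), g2 = c(rep(0, 5), rep(3, 5))))
  labels <- setNames(rep(c("A", "B"), each = 5), rownames(nm$values))
  res <- deg_t_test(nm, labels, "A")
  expect_equal(res$p[res$gene == "g1"], 1)
  expect_false(res$deg[res$gene == "g1"])

  expr <- gen_expression(n_cells_per_state = c(A = 100, B = 100),
                         n_genes = 200, effect = 2, seed = 77)
  nm2 <- normalize_log(expr$counts)
  deg <- deg_t_test(nm2, expr$labels, "A")
  hits <- deg$gene[deg$deg & deg$lfc > 0]
  expect_true(all(expr$markers$A %in% hits))
})

test_that("BH adjustment is step-up and monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))
  expect_error(bh_adjust(c(0.5, 1.2)),
               class = "cardioniche_validation_error")
  set.seed(78)
  p <- runif(40)
  adj <- bh_adjust(p)
  expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
  expect_true(all(adj >= p))
  expect_false(is.unsorted(adj[order(p)]))
})

test_that("gene-score correlations match the covariance oracle", {
  set.seed(79)
  dense <- matrix(rexp(50 * 10), 50, 10,
                  dimnames = list(paste0("s", 1:50), paste0("g", 1:10)))
  score <- rnorm(50)
  nm <- toy_norm(dense)
  res <- correlate_genes_with_score(nm, score)
  for (g in colnames(dense)) {
    o <- oracle_pearson(dense[, g], score)
    expect_equal(res$r[res$gene == g], o$r, tolerance = 1e-12)
    expect_equal(res$p[res$gene == g], o$p, tolerance = 1e-12)
    ct <- cor.test(dense[, g], score)
    expect_equal(res$p[res$gene == g], ct$p.value, tolerance = 1e-10)
  }
})

test_that("correlation handles perfect, inverse and constant columns", {
  score <- c(1, 3, 2, 5, 4)
  nm <- toy_norm(cbind(same = score, inv = -score, flat = rep(1, 5)))
  res <- correlate_genes_with_score(nm, score)
  expect_equal(res$r[res$gene == "same"], 1)
  expect_equal(res$r[res$gene == "inv"], -1)
  expect_true(is.na(res$r[res$gene == "flat"]))
  expect_true(is.na(res$p_adj[res$gene == "flat"]))
  expect_error(correlate_genes_with_score(nm, rep(2, 5)),
               class = "cardioniche_validation_error")
})
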