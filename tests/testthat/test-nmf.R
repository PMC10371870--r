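test_that("the default rank scan yields 95 factors and valid results", {
  ab <- gen_spots(n_row = 8, n_col = 8, seed = 101)
  scan <- nmf_scan(ab, 5:14, seed = 1)
  expect_length(scan, 10)
  expect_equal(sum(vapply(scan, `[[`, integer(1), "n_fact")), 95L)
  for (res in scan) {
    expect_true(all(res$W >= 0))
    expect_true(all(res$H >= 0))
    expect_equal(dim(res$W), c(nrow(ab$abundance), res$n_fact))
  }
})

test_that("an exactly low-rank matrix is recovered at machine precision", {
  set.seed(102)
  w <- matrix(rexp(30), 30, 1,
              dimnames = list(paste0("s", 1:30), NULL))
  h <- matrix(rexp(6), 1, 6, dimnames = list(NULL, paste0("st", 1:6)))
  X <- w %*% h
  res <- nmf_scan(X, 1, seed = 0)[[1]]
  expect_lt(res$reconstruction_error, 1e-8)
})

test_that("reconstruction error is non-increasing in the rank", {
  ab <- gen_spots(seed = 103)
  scan <- nmf_scan(ab, c(2, 4, 6, 8, 10), seed = 1)
  errs <- vapply(scan, `[[`, numeric(1), "reconstruction_error")
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("Cohen's d handles oracle, equal and degenerate cases", {
  expect_equal(factor_effect_size(c(2, 4, 1, 3), c(TRUE, TRUE, FALSE, FALSE)),
               oracle_cohens_d(c(2, 4), c(1, 3)))
  expect_equal(oracle_cohens_d(c(2, 4), c(1, 3)), 1 / sqrt(2))
  expect_equal(factor_effect_size(rep(5, 10), rep(c(TRUE, FALSE), 5)), 0)
  # zero pooled SD with distinct means: capped sentinel
  expect_equal(factor_effect_size(c(3, 3, 2, 2), c(TRUE, TRUE, FALSE, FALSE)),
               1e6)
  expect_error(factor_effect_size(1:4, rep(TRUE, 4)))
})

test_that("permutation p matches exhaustive enumeration on 6 spots", {
  loadings <- c(5.2, 4.8, 6.1, 1.0, 1.3, 0.7)
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  p_ex <- permutation_effect_p(loadings, mask, exhaustive = TRUE)
  # independent enumeration of all C(6,3) = 20 masks
  d_obs <- oracle_cohens_d(loadings[mask], loadings[!mask])
  d_all <- apply(combn(6, 3), 2, function(i) {
    oracle_cohens_d(loadings[i], loadings[-i])
  })
  expect_equal(as.numeric(p_ex), mean(d_all >= d_obs - 1e-12))
  expect_equal(as.numeric(p_ex), 1 / 20)
})

test_that("constant loadings give p = 1; p is affine-invariant", {
  mask <- rep(c(TRUE, FALSE), each = 10)
  expect_equal(as.numeric(permutation_effect_p(rep(2, 20), mask,
                                               n_perm = 50, seed = 1)), 1)
  set.seed(104)
  x <- rnorm(20)
  p1 <- permutation_effect_p(x, mask, n_perm = 200, seed = 7,
                             exhaustive = FALSE)
  p2 <- permutation_effect_p(3 * x + 10, mask, n_perm = 200, seed = 7,
                             exhaustive = FALSE)
  expect_equal(as.numeric(p1), as.numeric(p2))
})

test_that("permutation p is roughly uniform when mask carries no signal", {
  set.seed(105)
  pvals <- vapply(1:60, function(i) {
    x <- rnorm(24)
    mask <- sample(rep(c(TRUE, FALSE), each = 12))
    as.numeric(permutation_effect_p(x, mask, n_perm = 60, seed = i,
                                    exhaustive = FALSE))
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("best-/fine-factor selection applies the published rules", {
  # three factors engineered to effect sizes near 3.0, 1.4 and 1.6;
  # fine set must be the two exceeding half the best (1.5)
  n <- 40
  mask <- rep(c(TRUE, FALSE), each = n / 2)
  mk_col <- function(d) {
    x <- rep(c(0, 1), length.out = n)          # within-group sd ~ 0.5
    x + ifelse(mask, d * 0.5129892, 0)         # calibrated shift
  }
  W <- cbind(f1 = mk_col(3.0), f2 = mk_col(1.4), f3 = mk_col(1.6))
  ds <- apply(W, 2, factor_effect_size, mask = mask)
  expect_equal(unname(round(ds, 1)), c(3.0, 1.4, 1.6))
  res <- structure(list(n_fact = 3L, W = W,
                        H = matrix(1, 3, 2,
                                   dimnames = list(colnames(W),
                                                   c("sA", "sB"))),
                        reconstruction_error = 0.1, seed = 0L),
                   class = "nmf_result")
  sel <- select_factors(list(res), mask, n_perm = 400, seed = 9)
  expect_equal(sel$best$factor, "f1")
  expect_equal(sel$chosen_n_fact, 3L)
  expect_setequal(sel$fine_factors$factor, c("f1", "f3"))
})

test_that("selection is empty when nothing is significant", {
  res <- structure(list(n_fact = 2L,
                        W = matrix(1, 20, 2,
                                   dimnames = list(paste0("s", 1:20),
                                                   c("f1", "f2"))),
                        H = matrix(1, 2, 2), reconstruction_error = 0.5,
                        seed = 0L),
                   class = "nmf_result")
  mask <- rep(c(TRUE, FALSE), 10)
  sel <- select_factors(list(res), mask, n_perm = 100, seed = 2)
  expect_null(sel$best)
  expect_true(is.na(sel$chosen_n_fact))
  expect_equal(nrow(sel$fine_factors), 0)
})

test_that("planted two-compartment niches are recovered by fine-factors", {
  ab <- gen_spots(n_row = 14, n_col = 14,
                  regions = niche_recovery_regions(), seed = 106)
  scan <- nmf_scan(ab, 5:10, seed = 1)
  mask <- !is.na(ab$structure)
  sel <- select_factors(scan, mask, n_perm = 300, seed = 11)
  expect_false(is.null(sel$best))
  expect_gte(nrow(sel$fine_factors), 2)
  run <- scan[[match(sel$chosen_n_fact,
                     vapply(scan, `[[`, integer(1), "n_fact"))]]
  Wn <- sweep(run$W, 2, colMeans(run$W), "/")
  assigned <- colnames(run$W)[apply(Wn, 1, which.max)]
  jacc <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  best_j <- vapply(c("nicheA", "nicheB"), function(reg) {
    spots_r <- rownames(ab$abundance)[!is.na(ab$structure) &
                                        ab$structure == reg]
    max(vapply(sel$fine_factors$factor, function(f) {
      jacc(rownames(run$W)[assigned == f], spots_r)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(best_j > 0.8))
  # the fine factors' top states match the planted programs
  tops <- lapply(sel$fine_factors$factor, function(f) {
    factor_top_states(run, f, threshold = 0.4)$state
  })
  expect_true(any(vapply(tops, function(s) "s1" %in% s, logical(1))))
  expect_true(any(vapply(tops, function(s) "s4" %in% s, logical(1))))
})

test_that("top-state reporting applies the normalized-weight threshold", {
  res <- structure(list(n_fact = 1L,
                        W = matrix(1, 2, 1),
                        H = matrix(c(10, 5, 3, 1), 1, 4,
                                   dimnames = list("factor_1",
                                                   paste0("s", 1:4))),
                        reconstruction_error = 0, seed = 0L),
                   class = "nmf_result")
  top <- factor_top_states(res, "factor_1", threshold = 0.4)
  expect_equal(top$state, c("s1", "s2"))  # 1.0 and 0.5 pass, 0.3 does not
})
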