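write_lr_files <- function(interactions, complexes, dir) {
  ip <- file.path(dir, "inter.csv")
  cp <- file.path(dir, "cx.csv")
  write.csv(interactions, ip, row.names = FALSE)
  write.csv(complexes, cp, row.names = FALSE)
  list(interactions = ip, complexes = cp)
}

test_that("database loading validates complex references", {
  d <- withr::local_tempdir()
  f <- write_lr_files(
    data.frame(partner_a = c("LIG1", "LIG2"),
               partner_b = c("REC1", "CPLX1")),
    data.frame(complex_name = "CPLX1", member_1 = "RA", member_2 = "RB"),
    d)
  db <- load_lr_database(f$interactions, f$complexes)
  expect_equal(nrow(db$interactions), 2)
  expect_length(db$complexes, 1)
  expect_equal(db$complexes$CPLX1, c("RA", "RB"))

  f2 <- write_lr_files(
    data.frame(partner_a = "LIG1", partner_b = "complex:X"),
    data.frame(complex_name = "CPLX1", member_1 = "RA", member_2 = "RB"),
    d)
  expect_error(load_lr_database(f2$interactions, f2$complexes),
               "X", class = "cardioniche_validation_error")
})

test_that("a generated module at curated scale parses completely", {
  d <- withr::local_tempdir()
  mod <- gen_lr_module(n_simple = 700, n_complex = 150, seed = 131)
  f <- write_lr_files(mod$interactions, mod$complexes, d)
  db <- load_lr_database(f$interactions, f$complexes)
  expect_gt(nrow(db$interactions), 800)
  expect_equal(length(db$complexes), 150)
  expect_true(any(db$interactions$is_proxy))
})

test_that("expressed fraction depends only on the zero pattern", {
  vals <- rbind(c(1, 0), c(2, 0), c(3, 1), c(0, 0), c(0, 0),
                c(1, 1), c(0, 2), c(5, 0), c(0, 0), c(0, 0))
  nm <- toy_norm(vals)
  labels <- setNames(rep("A", 10), rownames(nm$values))
  expect_equal(expressed_fraction(nm, labels, "g1", "A"), 0.5)
  expect_equal(expressed_fraction(nm, labels, "g2", "A"), 0.3)
  expect_warning(f0 <- expressed_fraction(nm, labels, "absent", "A"))
  expect_equal(f0, 0)
  # scaling the values (as normalization would) leaves fractions unchanged
  nm2 <- toy_norm(log1p(vals * 17))
  expect_equal(expressed_fraction(nm2, labels, "g1", "A"), 0.5)
})

test_that("LR mean averages partner means with the complex-min rule", {
  d <- withr::local_tempdir()
  f <- write_lr_files(
    data.frame(partner_a = c("L", "L"), partner_b = c("R", "CX")),
    data.frame(complex_name = "CX", member_1 = "R", member_2 = "R2"),
    d)
  db <- load_lr_database(f$interactions, f$complexes)
  # sender cells express L at mean 2; receiver R at mean 4, R2 at mean 20
  vals <- rbind(c(2, 0, 0), c(2, 0, 0), c(0, 4, 20), c(0, 4, 20))
  colnames(vals) <- c("L", "R", "R2")
  nm <- toy_norm(vals)
  labels <- setNames(c("S", "S", "T", "T"), rownames(nm$values))
  expect_equal(lr_mean(nm, labels, db, 1, "S", "T"), 3)
  # complex partner value is min(4, 20) = 4
  expect_equal(lr_mean(nm, labels, db, 2, "S", "T"), 3)
  expect_equal(lr_mean(nm, labels, db, 2, "S", "T", complex_rule = "mean"),
               (2 + 12) / 2)
})

test_that("LR mean matches a dense brute-force computation", {
  d <- withr::local_tempdir()
  set.seed(132)
  genes <- paste0("g", 1:30)
  f <- write_lr_files(
    data.frame(partner_a = "g1", partner_b = "CX"),
    data.frame(complex_name = "CX", member_1 = "g5", member_2 = "g9"),
    d)
  db <- load_lr_database(f$interactions, f$complexes)
  dense <- matrix(rexp(100 * 30), 100, 30,
                  dimnames = list(paste0("c", 1:100), genes))
  nm <- toy_norm(dense)
  labels <- setNames(sample(c("A", "B"), 100, replace = TRUE),
                     rownames(dense))
  expect_equal(lr_mean(nm, labels, db, 1, "A", "B"),
               oracle_lr_mean(dense, labels, "g1", c("g5", "g9"), "A", "B"),
               tolerance = 1e-12)
  # swapping sender/receiver together with the partners is symmetric
  f2 <- write_lr_files(data.frame(partner_a = "CX", partner_b = "g1"),
                       data.frame(complex_name = "CX", member_1 = "g5",
                                  member_2 = "g9"), d)
  db2 <- load_lr_database(f2$interactions, f2$complexes)
  expect_equal(lr_mean(nm, labels, db, 1, "A", "B"),
               lr_mean(nm, labels, db2, 1, "B", "A"), tolerance = 1e-12)
})

test_that("label-permutation p is exact in exhaustive mode", {
  d <- withr::local_tempdir()
  f <- write_lr_files(data.frame(partner_a = "L", partner_b = "R"),
                      data.frame(complex_name = character(0),
                                 member_1 = character(0)), d)
  db <- load_lr_database(f$interactions, f$complexes)
  vals <- cbind(L = c(5, 4, 6, 0, 0, 1), R = c(0, 1, 0, 3, 4, 5))
  nm <- toy_norm(vals)
  labels <- setNames(c("A", "A", "A", "B", "B", "B"), rownames(nm$values))
  p_ex <- lr_permutation_p(nm, labels, db, 1, "A", "B", min_cells = 1,
                           exhaustive = TRUE)
  # enumeration over all C(6,3) = 20 assignments of the A labels
  obs <- (mean(vals[1:3, "L"]) + mean(vals[4:6, "R"])) / 2
  null_stats <- apply(combn(6, 3), 2, function(i) {
    (mean(vals[i, "L"]) + mean(vals[-i, "R"])) / 2
  })
  expect_equal(as.numeric(p_ex), mean(null_stats >= obs - 1e-12))
})

test_that("degenerate labellings and tiny states give p = 1", {
  d <- withr::local_tempdir()
  f <- write_lr_files(data.frame(partner_a = "L", partner_b = "R"),
                      data.frame(complex_name = character(0),
                                 member_1 = character(0)), d)
  db <- load_lr_database(f$interactions, f$complexes)
  nm <- toy_norm(cbind(L = rexp(8), R = rexp(8)))
  one_state <- setNames(rep("A", 8), rownames(nm$values))
  expect_equal(as.numeric(lr_permutation_p(nm, one_state, db, 1, "A", "A")),
               1)
  two <- setNames(rep(c("A", "B"), each = 4), rownames(nm$values))
  p_small <- lr_permutation_p(nm, two, db, 1, "A", "B", min_cells = 10,
                              n_perm = 20, seed = 1)
  expect_equal(as.numeric(p_small), 1)
  expect_true(isTRUE(attr(p_small, "untestable")))
})

test_that("a planted directional pair is detected asymmetrically", {
  set.seed(133)
  d <- withr::local_tempdir()
  f <- write_lr_files(data.frame(partner_a = "LIG", partner_b = "REC"),
                      data.frame(complex_name = character(0),
                                 member_1 = character(0)), d)
  db <- load_lr_database(f$interactions, f$complexes)
  n <- 40
  # ligand high in A only; receptor high in B only; background low
  lig <- c(rexp(n, 1 / 5), rexp(n, 10))
  rec <- c(rexp(n, 10), rexp(n, 1 / 5))
  nm <- toy_norm(cbind(LIG = lig, REC = rec,
                       matrix(rexp(2 * n * 5), 2 * n, 5)))
  labels <- setNames(rep(c("A", "B"), each = n), rownames(nm$values))
  p_ab <- lr_permutation_p(nm, labels, db, 1, "A", "B", n_perm = 400,
                           seed = 2)
  p_ba <- lr_permutation_p(nm, labels, db, 1, "B", "A", n_perm = 400,
                           seed = 2)
  expect_lt(as.numeric(p_ab), 0.05)
  expect_gte(as.numeric(p_ba), 0.05)
})

test_that("the niche screen enforces fraction, significance and DEG gates", {
  set.seed(134)
  d <- withr::local_tempdir()
  n <- 30
  # planted: LIG in A (always on), REC in B (always on)
  # sparse: SPRS expressed in only 5% of A cells
  lig <- c(rexp(n, 1 / 4) + 1, rep(0, n))
  rec <- c(rep(0, n), rexp(n, 1 / 4) + 1)
  sprs <- c(ifelse(seq_len(n) <= ceiling(0.05 * n) - 1, 3, 0), rep(0, n))
  flat <- rep(1, 2 * n)  # expressed everywhere, not differential
  nm <- toy_norm(cbind(LIG = lig, REC = rec, SPRS = sprs, FLAT = flat))
  labels <- setNames(rep(c("A", "B"), each = n), rownames(nm$values))
  f <- write_lr_files(
    data.frame(partner_a = c("LIG", "SPRS", "FLAT"),
               partner_b = c("REC", "REC", "FLAT")),
    data.frame(complex_name = character(0), member_1 = character(0)), d)
  db <- load_lr_database(f$interactions, f$complexes)
  res <- niche_interaction_screen(nm, labels, db, c("A", "B"),
                                  mode = "statistical", n_perm = 200,
                                  seed = 7, min_cells = 5)
  sel <- res[res$selected, ]
  expect_true(all(sel$partner_a == "LIG"))
  # the sparsely expressed ligand is excluded regardless of p
  expect_false(any(res$selected[res$partner_a == "SPRS"]))

  res_deg <- niche_interaction_screen(nm, labels, db, c("A", "B"),
                                      mode = "deg", min_cells = 5)
  # FLAT-FLAT passes the fraction filter but no member is a DEG
  ff <- res_deg[res_deg$partner_a == "FLAT", ]
  expect_true(all(ff$frac_pass))
  expect_false(any(ff$selected))
  # the planted pair has DEG members and survives
  expect_true(any(res_deg$selected[res_deg$partner_a == "LIG" &
                                     res_deg$sender == "A" &
                                     res_deg$receiver == "B"]))
})

test_that("raising the fraction threshold only shrinks the screen", {
  set.seed(135)
  d <- withr::local_tempdir()
  n <- 24
  vals <- matrix(rbinom(2 * n * 6, 1, 0.3) * rexp(2 * n * 6), 2 * n, 6)
  colnames(vals) <- paste0("g", 1:6)
  nm <- toy_norm(vals)
  labels <- setNames(rep(c("A", "B"), each = n), rownames(nm$values))
  f <- write_lr_files(
    data.frame(partner_a = c("g1", "g3", "g5"),
               partner_b = c("g2", "g4", "g6")),
    data.frame(complex_name = character(0), member_1 = character(0)), d)
  db <- load_lr_database(f$interactions, f$complexes)
  screen_at <- function(fr) {
    r <- niche_interaction_screen(nm, labels, db, c("A", "B"),
                                  mode = "statistical", min_frac = fr,
                                  n_perm = 50, seed = 3, min_cells = 5)
    r[r$selected, c("partner_a", "sender", "receiver")]
  }
  lo <- screen_at(0.1); hi <- screen_at(0.4)
  expect_true(nrow(merge(hi, lo)) == nrow(hi))
})
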