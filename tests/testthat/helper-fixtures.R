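# Shared fixture builders and independent brute-force oracles.
# Oracles are deliberately naive re-derivations (enumeration, closed
# forms, O(n*m) scans) kept separate from the package's code paths.

suppressPackageStartupMessages({
  library(Matrix)
  library(GenomicRanges)
})

# dense matrix -> count_matrix with generated names
toy_counts <- function(values, row_kind = "cell", prefix = "c") {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0(prefix, seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("g", seq_len(ncol(values)))
  count_matrix(Matrix(values, sparse = TRUE), row_kind)
}

# dense matrix of already-normalized values -> norm_matrix (bypasses
# normalization so tests can force exact expression values)
toy_norm <- function(values, row_kind = "cell", prefix = "c") {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0(prefix, seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("g", seq_len(ncol(values)))
  structure(list(values = Matrix(values, sparse = TRUE), row_kind = row_kind,
                 norm_params = list(target_sum = NA, pseudocount = 1)),
            class = "norm_matrix")
}

# line of spots along one axis; abundance columns supplied as a matrix
toy_abundance <- function(abundance, structure = NULL) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)))
    rownames(abundance) <- paste0("s", seq_len(nrow(abundance)))
  if (is.null(colnames(abundance)))
    colnames(abundance) <- paste0("g", seq_len(ncol(abundance)))
  abundance_matrix(abundance, array_row = rep(0, nrow(abundance)),
                   array_col = seq_len(nrow(abundance)),
                   structure = structure)
}

# two disjoint state programs over two disjoint spot bands + background;
# the construction used for factor-recovery checks
niche_recovery_regions <- function() {
  list(
    nicheA = list(rows = 3:5, mixture = c(s1 = 0.5, s2 = 0.3, s3 = 0.2)),
    nicheB = list(rows = 9:11, mixture = c(s4 = 0.5, s5 = 0.3, s6 = 0.2)),
    none = list(rows = c(1:2, 6:8, 12:14),
                mixture = c(b1 = 0.4, b2 = 0.3, b3 = 0.2, b4 = 0.1)))
}

# --- oracles ---------------------------------------------------------------

# BH step-up by the textbook recipe
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# exact two-sided rank-sum p by full enumeration of label assignments
oracle_ranksum_exact <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  e_w <- nx * (nx + length(y) + 1) / 2
  w_obs <- sum(r[seq_len(nx)])
  splits <- combn(nx + length(y), nx)
  w_all <- apply(splits, 2, function(i) sum(r[i]))
  mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-12)
}

# Welch t statistic, df and p from first principles
oracle_welch <- function(x, y) {
  v1 <- var(x) / length(x); v2 <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Pearson r and p via explicit covariance / sd computation
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# Yates-corrected chi-square statistic and p for a 2x2 table
oracle_chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  E <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  O <- matrix(c(a, c, b, d), 2, 2)
  stat <- sum((abs(O - E) - 0.5)^2 / E)
  list(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

oracle_cohens_d <- function(x, y) {
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  (mean(x) - mean(y)) / sp
}

# O(n*m) per-SNP interval scan in 0-based half-open coordinates
oracle_snp_proportion <- function(peak_start0, peak_end0, snp_pos0) {
  inside <- vapply(snp_pos0, function(p) {
    any(p >= peak_start0 & p < peak_end0)
  }, logical(1))
  mean(inside)
}

# dense LR mean: average of partner-a mean in sender and partner-b mean in
# receiver, complex partners taken as the min over member means
oracle_lr_mean <- function(dense, labels, a_genes, b_genes, sender,
                           receiver) {
  am <- min(colMeans(dense[labels == sender, a_genes, drop = FALSE]))
  bm <- min(colMeans(dense[labels == receiver, b_genes, drop = FALSE]))
  (am + bm) / 2
}
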