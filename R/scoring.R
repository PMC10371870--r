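#' Mean gene-set score per barcode
#'
#' Scores each row as the arithmetic mean of its normalized expression over
#' the set genes present in the matrix. Gene order and duplicate listings do
#' not affect the score.
#'
#' @param norm a `norm_matrix` from [normalize_log()].
#' @param genes character vector of gene symbols.
#' @param set_name optional name used in error messages.
#' @return Numeric vector of scores, named by row id.
#' @export
score_gene_set_mean <- function(norm, genes, set_name = "gene set") {
  stopifnot(inherits(norm, "norm_matrix"))
  present <- intersect(unique(genes), colnames(norm$values))
  if (!length(present)) {
    .validation_error("no genes of ", set_name, " present in the matrix")
  }
  s <- Matrix::rowMeans(norm$values[, present, drop = FALSE])
  stats::setNames(as.numeric(s), rownames(norm$values))
}

#' Gene-set score with expression-binned control genes
#'
#' Ranks all genes by global mean expression, cuts them into `n_bins`
#' equal-size bins, and for every set gene draws `ctrl_per_gene` control
#' genes uniformly without replacement from the same bin (set genes
#' excluded). The score is the mean over set genes minus the mean over the
#' pooled control draws, so a random set on exchangeable data is centred on
#' zero. When a bin holds fewer eligible genes than requested, the draw
#' falls back to sampling with replacement and warns.
#'
#' @inheritParams score_gene_set_mean
#' @param n_bins number of expression bins; default 25.
#' @param ctrl_per_gene control genes drawn per set gene; default 50.
#' @param seed RNG seed for the control draw.
#' @param control_genes optional explicit control set (test hook); when
#'   given, no sampling is done.
#' @return Numeric vector of scores, named by row id.
#' @export
score_gene_set_binned_ref <- function(norm, genes, n_bins = 25,
                                      ctrl_per_gene = 50, seed = NULL,
                                      set_name = "gene set",
                                      control_genes = NULL) {
  stopifnot(inherits(norm, "norm_matrix"))
  all_genes <- colnames(norm$values)
  .assert(length(all_genes) >= n_bins,
          "matrix has fewer genes than requested bins")
  set <- intersect(unique(genes), all_genes)
  if (!length(set)) {
    .validation_error("no genes of ", set_name, " present in the matrix")
  }
  if (is.null(control_genes)) {
    gmeans <- Matrix::colMeans(norm$values)
    rank_pos <- rank(gmeans, ties.method = "first")
    bin <- ceiling(rank_pos / (length(all_genes) / n_bins))
    bin_members <- split(all_genes, bin)
    control_genes <- with_seed(seed, {
      unlist(lapply(set, function(g) {
        pool <- setdiff(bin_members[[as.character(bin[match(g, all_genes)])]],
                        set)
        if (length(pool) >= ctrl_per_gene) {
          sample(pool, ctrl_per_gene)
        } else if (length(pool)) {
          warning("control bin exhausted for ", g,
                  "; sampling with replacement")
          sample(pool, ctrl_per_gene, replace = TRUE)
        } else {
          warning("no eligible control genes in the bin of ", g)
          character(0)
        }
      }))
    })
  }
  set_mean <- Matrix::rowMeans(norm$values[, set, drop = FALSE])
  if (length(control_genes)) {
    # duplicates keep their multiplicity: each draw contributes equally
    ctrl <- norm$values[, control_genes, drop = FALSE]
    ctrl_mean <- Matrix::rowMeans(ctrl)
  } else {
    ctrl_mean <- 0
  }
  stats::setNames(as.numeric(set_mean - ctrl_mean), rownames(norm$values))
}

# two-sided rank-sum p for x vs y.
# Exact enumeration of all C(n, nx) splits when both sides are small,
# otherwise the tie-corrected normal approximation (no continuity
# correction). The exact two-sided p is the null mass of
# |W - E[W]| >= |W_obs - E[W]| where W is the in-group rank sum.
.ranksum_p <- function(x, y, exact_max = 8) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  if (stats::var(pooled) == 0) return(1)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  e_w <- nx * (nx + ny + 1) / 2
  if (nx <= exact_max && ny <= exact_max) {
    splits <- utils::combn(nx + ny, nx)
    w_all <- colSums(matrix(r[splits], nrow = nx))
    return(mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-12))
  }
  n <- nx + ny
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w_obs - e_w) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

# Binned-reference scores can be <= 0; means are clamped at zero before
# the pseudocounted ratio so the fold change stays defined and monotone in
# the "higher in group" direction.
.log2_fc <- function(mean_in, mean_out, eps = 1e-9) {
  log2((pmax(mean_in, 0) + eps) / (pmax(mean_out, 0) + eps))
}

#' Rank score sets for specificity in one group
#'
#' For every column of a score matrix, tests whether scores in `group` are
#' higher than in all other rows with a two-sided rank-sum test (exact
#' enumeration when both sides have at most `exact_max` members, otherwise
#' tie-corrected normal approximation), computes the log2 fold change of the
#' group mean over the rest mean with a small pseudocount (scores from the
#' binned-reference method can be non-positive), and adjusts p values across
#' sets by Benjamini-Hochberg. Sets passing `lfc > lfc_min` and
#' `p_adj < p_adj_max` are flagged.
#'
#' @param scores numeric matrix (rows = barcodes, columns = sets/drugs) or a
#'   named list of score vectors.
#' @param labels named character vector (or two-column data.frame) mapping
#'   row id to group label.
#' @param group label defining the in-group.
#' @param lfc_min log2 fold-change gate (strict `>`); default 2.
#' @param p_adj_max adjusted-p gate (strict `<`); default 0.05.
#' @param eps pseudocount in the fold change; default 1e-9.
#' @param exact_max per-side size limit for exact enumeration; default 8.
#' @return A data.frame with one row per set: `set`, `group`, `lfc`, `p`,
#'   `p_adj`, `flagged`, ordered by decreasing lfc among flagged first.
#' @export
rank_sets_for_group <- function(scores, labels, group, lfc_min = 2,
                                p_adj_max = 0.05, eps = 1e-9,
                                exact_max = 8) {
  if (is.list(scores) && !is.data.frame(scores)) {
    scores <- do.call(cbind, scores)
  }
  scores <- as.matrix(scores)
  lab <- .align_labels(labels, rownames(scores))
  .assert(group %in% lab, "group not present in labels: ", group)
  in_g <- lab == group
  .assert(sum(in_g) >= 2 && sum(!in_g) >= 2,
          "need at least 2 rows in and out of the group")
  res <- lapply(colnames(scores), function(s) {
    x <- scores[in_g, s]
    y <- scores[!in_g, s]
    if (stats::var(c(x, y)) == 0) {
      data.frame(set = s, group = group, lfc = 0, p = 1)
    } else {
      data.frame(set = s, group = group,
                 lfc = .log2_fc(mean(x), mean(y), eps),
                 p = .ranksum_p(x, y, exact_max))
    }
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$flagged <- out$lfc > lfc_min & out$p_adj < p_adj_max
  out[order(-out$flagged, -out$lfc), , drop = FALSE]
}

#' Welch t-test differential expression per gene
#'
#' Compares `group` against `reference` (all other labels by default) with a
#' per-gene Welch two-sample t-test, Benjamini-Hochberg correction and log2
#' fold changes of group over reference means. A gene with zero variance on
#' both sides is reported with `p = 1` (not testable under the t model).
#'
#' @param norm a `norm_matrix`.
#' @param labels named labels per row (see [rank_sets_for_group()]).
#' @param group label defining the in-group.
#' @param reference optional label(s) forming the reference; default: all
#'   rows outside `group`.
#' @param p_adj_max DEG gate on adjusted p (strict `<`); default 0.05.
#' @param lfc_min optional fold-change gate applied to the `deg` flag;
#'   default 0 (any upregulation not required).
#' @param eps pseudocount in the fold change.
#' @return A data.frame with one row per gene: `gene`, `lfc`, `t`, `p`,
#'   `p_adj`, `deg`.
#' @export
deg_t_test <- function(norm, labels, group, reference = NULL,
                       p_adj_max = 0.05, lfc_min = 0, eps = 1e-9) {
  stopifnot(inherits(norm, "norm_matrix"))
  lab <- .align_labels(labels, rownames(norm$values))
  in_g <- lab == group
  out_g <- if (is.null(reference)) !in_g else lab %in% reference
  .assert(sum(in_g) >= 2 && sum(out_g) >= 2,
          "need at least 2 rows per side")
  X <- norm$values[in_g, , drop = FALSE]
  Y <- norm$values[out_g, , drop = FALSE]
  n1 <- nrow(X); n2 <- nrow(Y)
  m1 <- Matrix::colMeans(X); m2 <- Matrix::colMeans(Y)
  v1 <- (Matrix::colSums(X^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (Matrix::colSums(Y^2) - n2 * m2^2) / (n2 - 1)
  v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               1)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(t_stat), df), 1)
  out <- data.frame(gene = colnames(norm$values),
                    lfc = .log2_fc(m1, m2, eps),
                    t = as.numeric(t_stat),
                    p = as.numeric(p),
                    row.names = NULL)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$deg <- out$p_adj < p_adj_max & out$lfc > lfc_min
  out
}

#' Benjamini-Hochberg adjustment with validation
#'
#' Step-up adjusted p values: order-preserving with the input, each at least
#' the raw p, capped at 1.
#'
#' @param pvalues numeric vector of p values in \[0, 1\].
#' @return Adjusted p values in input order.
#' @export
bh_adjust <- function(pvalues) {
  .assert(is.numeric(pvalues) && !anyNA(pvalues),
          "p values must be numeric without NA")
  if (any(pvalues < 0 | pvalues > 1)) {
    .validation_error("p values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Correlate every gene with a per-row score
#'
#' Pearson correlation of each gene's expression profile with a score vector
#' (for example the pan-neuronal cytoskeletal score over Visium spots), with
#' two-sided p values from the t transform and Benjamini-Hochberg correction
#' across the testable genes. Genes with zero variance get `r = NA` and are
#' excluded from the correction.
#'
#' @param norm a `norm_matrix`.
#' @param score numeric score per row (aligned by position or by name).
#' @return A data.frame per gene: `gene`, `r`, `p`, `p_adj`, `mean_expr`,
#'   ordered by decreasing `r` (NA last).
#' @export
correlate_genes_with_score <- function(norm, score) {
  stopifnot(inherits(norm, "norm_matrix"))
  n <- nrow(norm$values)
  .assert(n >= 3, "need at least 3 rows")
  if (!is.null(names(score))) score <- score[rownames(norm$values)]
  .assert(length(score) == n && all(is.finite(score)),
          "score must be finite and match the number of rows")
  if (stats::sd(score) == 0) {
    .validation_error("score vector is constant; correlation undefined")
  }
  X <- norm$values
  mx <- Matrix::colMeans(X)
  sc <- score - mean(score)
  cov_xy <- as.numeric(Matrix::crossprod(X, sc)) / (n - 1)
  var_x <- (Matrix::colSums(X^2) - n * mx^2) / (n - 1)
  var_x <- pmax(var_x, 0)
  r <- ifelse(var_x > 0, cov_xy / sqrt(var_x * stats::var(score)), NA_real_)
  r <- pmin(pmax(r, -1), 1)
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- ifelse(is.na(r), NA_real_, 2 * stats::pt(-abs(t_stat), n - 2))
  p_adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  p_adj[ok] <- stats::p.adjust(p[ok], method = "BH")
  out <- data.frame(gene = colnames(X), r = as.numeric(r), p = p,
                    p_adj = p_adj, mean_expr = as.numeric(mx),
                    row.names = NULL)
  out[order(-out$r, na.last = TRUE), , drop = FALSE]
}

#' Default pan-neuronal cytoskeletal marker set
#'
#' The four generic pan-neuronal cytoskeletal markers used to score
#' ganglionated-plexus spots: peripherin and the three neurofilament chains.
#'
#' @return Character vector of gene symbols.
#' @export
pan_neuronal_markers <- function() c("PRPH", "NEFL", "NEFM", "NEFH")
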