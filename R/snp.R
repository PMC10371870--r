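#' Construct a barcode-by-peak accessibility matrix
#'
#' @param values matrix-like, rows = barcodes, columns = peaks; coerced to
#'   sparse. Values need not be binary yet (see [binarize_counts()]).
#' @param peaks [GenomicRanges::GRanges] of peak intervals; `name` metadata
#'   (or names) must match the matrix columns.
#' @param labels named character vector mapping barcode to cell state.
#' @return An object of class `peak_matrix`.
#' @export
peak_matrix <- function(values, peaks, labels) {
  values <- as(as(as(values, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  .assert(!is.null(rownames(values)) && !is.null(colnames(values)),
          "peak matrix needs barcode and peak names")
  if (any(values@x < 0)) .validation_error("peak counts must be >= 0")
  peak_ids <- S4Vectors::mcols(peaks)$name
  if (is.null(peak_ids)) peak_ids <- names(peaks)
  .assert(!is.null(peak_ids) && all(colnames(values) %in% peak_ids),
          "every peak column needs a matching interval")
  peaks <- peaks[match(colnames(values), peak_ids)]
  lab <- .align_labels(labels, rownames(values))
  structure(list(values = values, peaks = peaks,
                 labels = stats::setNames(lab, rownames(values))),
            class = "peak_matrix")
}

#' @export
dim.peak_matrix <- function(x) dim(x$values)

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("<peak_matrix> %d barcodes x %d peaks, %d states\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$labels))))
  invisible(x)
}

#' Binarize peak counts
#'
#' Sets every entry to 1 if the read count is greater than 0. Idempotent on
#' binary input.
#'
#' @param pm a [peak_matrix()] (or bare sparse matrix).
#' @return The same type with binary values.
#' @export
binarize_counts <- function(pm) {
  if (inherits(pm, "peak_matrix")) {
    v <- pm$values
    v@x <- as.numeric(v@x > 0)
    pm$values <- Matrix::drop0(v)
    pm
  } else {
    v <- as(as(as(pm, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    v@x <- as.numeric(v@x > 0)
    Matrix::drop0(v)
  }
}

#' Call open peaks per cell state
#'
#' Aggregates the binarized barcode-by-peak matrix by cell state: a peak is
#' open for a state when it is detected in at least `frac` (default 5%) of
#' that state's barcodes (inclusive).
#'
#' @param pm a binarized [peak_matrix()].
#' @param frac detection-fraction cutoff (inclusive `>=`); default 0.05.
#' @return An object of class `open_peak_calls`: list with `open` (state x
#'   peak logical matrix), `n_cells` per state, and the peak `GRanges`.
#' @export
call_open_peaks <- function(pm, frac = 0.05) {
  stopifnot(inherits(pm, "peak_matrix"))
  v <- binarize_counts(pm)$values
  states <- sort(unique(pm$labels))
  open <- t(vapply(states, function(s) {
    rows <- pm$labels == s
    Matrix::colMeans(v[rows, , drop = FALSE]) >= frac
  }, logical(ncol(v))))
  dimnames(open) <- list(states, colnames(v))
  n_cells <- vapply(states, function(s) sum(pm$labels == s), integer(1))
  structure(list(open = open, n_cells = n_cells, peaks = pm$peaks,
                 frac = frac),
            class = "open_peak_calls")
}

#' @export
print.open_peak_calls <- function(x, ...) {
  cat(sprintf("<open_peak_calls> %d states x %d peaks (>= %g%% rule)\n",
              nrow(x$open), ncol(x$open), 100 * x$frac))
  invisible(x)
}

#' Proportion of SNPs inside open peaks
#'
#' Fraction of SNPs whose position lies within at least one open peak
#' (half-open interval containment); a SNP hitting several peaks counts
#' once.
#'
#' @param open_peaks [GenomicRanges::GRanges] of the state's open peaks.
#' @param snps [GenomicRanges::GRanges] of 1-bp SNP intervals.
#' @return Proportion in \[0, 1\].
#' @export
snp_proportion <- function(open_peaks, snps) {
  .assert(length(snps) >= 1, "snp_proportion needs at least one SNP")
  if (length(open_peaks) == 0) return(0)
  hits <- GenomicRanges::countOverlaps(snps, open_peaks, type = "within")
  mean(hits > 0)
}

# For a fixed SNP set, the proportion for any open-peak subset only needs
# the SNP-by-peak incidence; precompute it once.
.snp_peak_incidence <- function(peaks, snps) {
  ov <- GenomicRanges::findOverlaps(snps, peaks, type = "within")
  Matrix::sparseMatrix(i = S4Vectors::queryHits(ov),
                       j = S4Vectors::subjectHits(ov),
                       x = 1,
                       dims = c(length(snps), length(peaks)))
}

#' Permutation test for SNP enrichment in a state's open peaks
#'
#' The observed statistic is the SNP proportion ([snp_proportion()]) in the
#' state's open peaks. The null shuffles the open/closed labels over the
#' state's full peak set, keeping the number of open peaks fixed, and
#' recomputes the proportion; `p` is the inclusive fraction of permutations
#' whose proportion is at least the observed one. All subsets are
#' enumerated instead when `choose(n_peaks, n_open) <= exhaustive_limit`.
#'
#' @param calls an [call_open_peaks()] result.
#' @param state cell-state name.
#' @param snps [GenomicRanges::GRanges] of SNP positions.
#' @param n_perm permutations; default 1000.
#' @param seed RNG seed.
#' @param exhaustive force/auto (`NULL`) enumeration.
#' @param exhaustive_limit auto-enumeration cap; default 10000.
#' @return List with `proportion`, `p` (attribute `p_smoothed`), `n_open`
#'   and `n_perm_used`.
#' @export
snp_permutation_test <- function(calls, state, snps, n_perm = 1000,
                                 seed = NULL, exhaustive = NULL,
                                 exhaustive_limit = 10000) {
  stopifnot(inherits(calls, "open_peak_calls"))
  .assert(state %in% rownames(calls$open), "unknown state: ", state)
  open <- calls$open[state, ]
  n_open <- sum(open)
  .assert(n_open >= 1, "state has no open peaks: ", state)
  n_peaks <- length(open)
  M <- .snp_peak_incidence(calls$peaks, snps)
  obs <- snp_proportion(calls$peaks[open], snps)
  if (is.null(exhaustive)) {
    exhaustive <- choose(n_peaks, n_open) <= exhaustive_limit
  }
  if (exhaustive) {
    idx <- utils::combn(n_peaks, n_open)
    props <- vapply(seq_len(ncol(idx)), function(j) {
      ind <- numeric(n_peaks); ind[idx[, j]] <- 1
      mean(as.numeric(M %*% ind) > 0)
    }, numeric(1))
    n_used <- ncol(idx)
  } else {
    props <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        ind <- numeric(n_peaks)
        ind[sample.int(n_peaks, n_open)] <- 1
        mean(as.numeric(M %*% ind) > 0)
      }, numeric(1))
    })
    n_used <- n_perm
  }
  k <- sum(props >= obs - 1e-12)
  p <- k / n_used
  attr(p, "p_smoothed") <- (k + 1) / (n_used + 1)
  list(proportion = obs, p = p, n_open = n_open, n_perm_used = n_used)
}

#' Trait-by-state SNP enrichment scan
#'
#' Runs [snp_permutation_test()] for every (trait, state) combination and
#' corrects the permutation p values by Benjamini-Hochberg, by default over
#' the full grid (`scope = "global"`), optionally within each trait.
#'
#' @param calls an [call_open_peaks()] result.
#' @param traits named list of SNP `GRanges`, one per trait.
#' @param n_perm,seed permutation controls.
#' @param scope `"global"` or `"per_trait"` BH scope.
#' @return A data.frame per (trait, state): `trait`, `state`,
#'   `snp_proportion`, `n_open_peaks`, `p`, `p_adj`.
#' @export
trait_state_scan <- function(calls, traits, n_perm = 1000, seed = 0L,
                             scope = c("global", "per_trait")) {
  stopifnot(inherits(calls, "open_peak_calls"))
  scope <- match.arg(scope)
  .assert(length(traits) >= 1 && !is.null(names(traits)),
          "traits must be a named list")
  states <- rownames(calls$open)
  grid <- expand.grid(trait = names(traits), state = states,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    tr <- snp_permutation_test(calls, grid$state[i],
                               traits[[grid$trait[i]]],
                               n_perm = n_perm,
                               seed = seed + i, exhaustive = FALSE)
    data.frame(trait = grid$trait[i], state = grid$state[i],
               snp_proportion = tr$proportion,
               n_open_peaks = tr$n_open, p = as.numeric(tr$p))
  })
  out <- do.call(rbind, res)
  if (scope == "global") {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
  } else {
    out$p_adj <- stats::ave(out$p, out$trait,
                            FUN = function(p) stats::p.adjust(p, "BH"))
  }
  out
}
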