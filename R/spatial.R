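#' Construct a spot-by-state abundance matrix
#'
#' Holds estimated cell-state abundances per Visium spot (the output format
#' of a deconvolution model such as cell2location), together with array
#' coordinates and an optional manual structure annotation per spot.
#'
#' @param abundance numeric matrix, rows = spots (named), columns = cell
#'   states (named); values are non-negative estimated abundances.
#' @param array_row,array_col numeric coordinates per spot.
#' @param structure optional character vector of structure labels per spot
#'   (`NA` for unannotated spots).
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(abundance, array_row, array_col,
                             structure = NULL) {
  abundance <- as.matrix(abundance)
  .assert(!is.null(rownames(abundance)) && !is.null(colnames(abundance)),
          "abundance matrix needs spot and state names")
  if (any(abundance < 0)) .validation_error("abundances must be >= 0")
  n <- nrow(abundance)
  .assert(length(array_row) == n && length(array_col) == n,
          "coordinate length must match number of spots")
  coords <- cbind(array_row = as.numeric(array_row),
                  array_col = as.numeric(array_col))
  if (anyDuplicated(coords)) {
    .validation_error("spot coordinates must be unique")
  }
  if (is.null(structure)) structure <- rep(NA_character_, n)
  .assert(length(structure) == n, "structure length must match spots")
  structure(list(abundance = abundance, coords = coords,
                 structure = as.character(structure)),
            class = "abundance_matrix")
}

#' @export
dim.abundance_matrix <- function(x) dim(x$abundance)

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d spots x %d states (%d annotated)\n",
              nrow(x$abundance), ncol(x$abundance),
              sum(!is.na(x$structure))))
  invisible(x)
}

#' Read an abundance matrix from TSV
#'
#' Expected columns: `spot`, `array_row`, `array_col`, optional `structure`,
#' then one column per cell state.
#'
#' @param path TSV path.
#' @return An [abundance_matrix()].
#' @export
read_abundance_matrix <- function(path) {
  tab <- read_tsv(path)
  .assert(all(c("spot", "array_row", "array_col") %in% names(tab)),
          "abundance TSV needs spot, array_row, array_col columns")
  meta <- c("spot", "array_row", "array_col", "structure")
  states <- setdiff(names(tab), meta)
  ab <- as.matrix(tab[, states, drop = FALSE])
  rownames(ab) <- tab$spot
  abundance_matrix(ab, tab$array_row, tab$array_col,
                   if ("structure" %in% names(tab)) tab$structure else NULL)
}

#' Write an abundance matrix as TSV
#' @param ab an [abundance_matrix()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_abundance_matrix <- function(ab, path) {
  stopifnot(inherits(ab, "abundance_matrix"))
  tab <- data.frame(spot = rownames(ab$abundance),
                    array_row = ab$coords[, "array_row"],
                    array_col = ab$coords[, "array_col"],
                    structure = ab$structure,
                    ab$abundance, check.names = FALSE, row.names = NULL)
  write_tsv(tab, path)
}

#' Per-spot cell-state proportions
#'
#' Normalizes each spot's abundances to sum to one. Spots with zero total
#' abundance are excluded with a warning.
#'
#' @param ab an [abundance_matrix()].
#' @return Numeric matrix of proportions (rows sum to 1).
#' @export
state_proportions <- function(ab) {
  stopifnot(inherits(ab, "abundance_matrix"))
  tot <- rowSums(ab$abundance)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " zero-abundance spot(s) excluded")
  }
  keep <- tot > 0
  sweep(ab$abundance[keep, , drop = FALSE], 1, tot[keep], "/")
}

#' Cell-state enrichment in an annotated structure
#'
#' For every cell state, compares the pooled (abundance-weighted) state
#' proportion over spots inside the structure with the proportion outside:
#' `OR = [p_in / (1 - p_in)] / [p_out / (1 - p_out)]`. Significance comes
#' from a chi-square test on the 2x2 table of rounded summed abundances
#' (state vs rest) x (in vs out), Yates-corrected, with Benjamini-Hochberg
#' adjustment across states. With `per_spot_mean = TRUE`, `p_in`/`p_out`
#' are instead means of per-spot proportions.
#'
#' @param ab an [abundance_matrix()] with structure labels.
#' @param structure structure label of interest.
#' @param per_spot_mean logical; see Details.
#' @param yates logical; Yates continuity correction for the 2x2 test.
#' @return A data.frame per state: `state`, `structure`, `odds_ratio`,
#'   `chi2_p`, `p_adj`, `n_spots_in`, `n_spots_out`.
#' @export
structure_enrichment <- function(ab, structure, per_spot_mean = FALSE,
                                 yates = TRUE) {
  stopifnot(inherits(ab, "abundance_matrix"))
  in_s <- !is.na(ab$structure) & ab$structure == structure
  .assert(any(in_s) && any(!in_s),
          "structure must be present on >= 1 spot and absent on >= 1 spot")
  A <- ab$abundance
  t_in <- colSums(A[in_s, , drop = FALSE])
  t_out <- colSums(A[!in_s, , drop = FALSE])
  if (per_spot_mean) {
    pr <- state_proportions(ab)
    keep <- rownames(pr)
    in_pr <- in_s[match(keep, rownames(A))]
    p_in <- colMeans(pr[in_pr, , drop = FALSE])
    p_out <- colMeans(pr[!in_pr, , drop = FALSE])
  } else {
    p_in <- t_in / sum(t_in)
    p_out <- t_out / sum(t_out)
  }
  odds <- function(p) ifelse(p >= 1, Inf, p / (1 - p))
  or <- odds(p_in) / odds(p_out)
  or[p_in == 0 & p_out == 0] <- NaN
  chi2_p <- vapply(seq_len(ncol(A)), function(j) {
    tab <- round(matrix(c(t_in[j], sum(t_in) - t_in[j],
                          t_out[j], sum(t_out) - t_out[j]), 2, 2))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
    suppressWarnings(stats::chisq.test(tab, correct = yates)$p.value)
  }, numeric(1))
  out <- data.frame(state = colnames(A), structure = structure,
                    odds_ratio = as.numeric(or), chi2_p = chi2_p,
                    p_adj = stats::p.adjust(chi2_p, method = "BH"),
                    n_spots_in = sum(in_s), n_spots_out = sum(!in_s),
                    row.names = NULL)
  out[order(-out$odds_ratio, na.last = TRUE), , drop = FALSE]
}

#' Spot adjacency from array coordinates
#'
#' Two spots are adjacent when their Euclidean distance in array coordinates
#' is at most `scale` times the minimum pairwise distance. On the hex-offset
#' layout produced by [gen_spots()] the default `scale = 1.5` yields the six
#' hex neighbours of each interior spot.
#'
#' @param ab an [abundance_matrix()] (or a 2-column coordinate matrix).
#' @param scale neighbourhood radius in units of the minimum spacing.
#' @return A logical adjacency matrix (zero diagonal) named by spot.
#' @export
spot_adjacency <- function(ab, scale = 1.5) {
  coords <- if (inherits(ab, "abundance_matrix")) ab$coords else as.matrix(ab)
  .assert(nrow(coords) >= 2, "adjacency needs at least 2 spots")
  d <- as.matrix(stats::dist(coords))
  dmin <- min(d[upper.tri(d)])
  adj <- d <= scale * dmin & d > 0
  if (inherits(ab, "abundance_matrix")) {
    dimnames(adj) <- list(rownames(ab$abundance), rownames(ab$abundance))
  }
  adj
}

#' Call product-abundance niches
#'
#' Multiplies the estimated abundances of two cell states per spot (for the
#' myocardial-stress niche: activated fibroblasts x stressed ventricular
#' cardiomyocytes), selects spots whose product exceeds `threshold`, and
#' returns connected clusters of neighbouring selected spots with strictly
#' more than `min_cluster` members. Adjacency (and hence the minimum spot
#' spacing) is computed on the full spot set.
#'
#' @param ab an [abundance_matrix()].
#' @param state_a,state_b cell-state column names.
#' @param threshold product-abundance cutoff (strict `>`); default 0.03.
#' @param min_cluster minimal cluster size, strict (`n > min_cluster`);
#'   default 5.
#' @param scale adjacency scale passed to [spot_adjacency()].
#' @return An object of class `niche_call`: list with `clusters` (list of
#'   spot-id vectors), `sizes`, `mean_product`, and the per-spot `product`
#'   vector.
#' @export
call_product_niche <- function(ab, state_a, state_b, threshold = 0.03,
                               min_cluster = 5, scale = 1.5) {
  stopifnot(inherits(ab, "abundance_matrix"))
  missing <- setdiff(c(state_a, state_b), colnames(ab$abundance))
  if (length(missing)) {
    .validation_error("state(s) absent from abundance matrix: ",
                      paste(missing, collapse = ", "))
  }
  product <- ab$abundance[, state_a] * ab$abundance[, state_b]
  names(product) <- rownames(ab$abundance)
  cand <- names(product)[product > threshold]
  clusters <- list()
  if (length(cand) >= 1 && nrow(ab$abundance) >= 2) {
    adj <- spot_adjacency(ab, scale)[cand, cand, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)
    for (k in seq_len(comp$no)) {
      members <- cand[comp$membership == k]
      if (length(members) > min_cluster) {
        clusters[[length(clusters) + 1L]] <- members
      }
    }
  }
  structure(list(clusters = clusters,
                 sizes = vapply(clusters, length, integer(1)),
                 mean_product = vapply(clusters,
                                       function(m) mean(product[m]),
                                       numeric(1)),
                 product = product,
                 threshold = threshold, min_cluster = min_cluster),
            class = "niche_call")
}

#' @export
print.niche_call <- function(x, ...) {
  cat(sprintf("<niche_call> %d cluster(s) above product %.3g (n > %d)\n",
              length(x$clusters), x$threshold, x$min_cluster))
  if (length(x$clusters)) {
    for (i in seq_along(x$clusters)) {
      cat(sprintf("  cluster %d: %d spots, mean product %.4g\n",
                  i, x$sizes[i], x$mean_product[i]))
    }
  }
  invisible(x)
}
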