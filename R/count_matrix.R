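#' Construct a barcode-by-gene count matrix
#'
#' A `count_matrix` holds sparse non-negative UMI counts with rows as cells,
#' nuclei or Visium spots and columns as gene symbols. It is the substrate
#' for QC filtering, normalization, scoring, differential expression and the
#' ligand-receptor screen.
#'
#' @param values matrix-like object of non-negative counts, rows = barcodes,
#'   columns = genes. Coerced to a sparse `dgCMatrix`. Row and column names
#'   are required and must be unique (duplicate gene symbols can be
#'   disambiguated up front with [make.unique()]).
#' @param row_kind one of `"cell"`, `"nucleus"`, `"spot"`.
#' @return An object of class `count_matrix`: a list with elements `values`
#'   (sparse counts) and `row_kind`.
#' @examples
#' m <- matrix(rpois(12, 2), 4, 3,
#'             dimnames = list(paste0("c", 1:4), paste0("g", 1:3)))
#' cm <- count_matrix(m, "cell")
#' dim(cm)
#' @export
count_matrix <- function(values, row_kind = c("cell", "nucleus", "spot")) {
  row_kind <- match.arg(row_kind)
  values <- as(as(as(values, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (any(values@x < 0)) {
    .validation_error("count matrix contains negative entries")
  }
  rn <- rownames(values)
  cn <- colnames(values)
  if (is.null(rn) && nrow(values) == 0) rn <- character(0)
  if (is.null(cn) && ncol(values) == 0) cn <- character(0)
  dimnames(values) <- list(rn, cn)
  .assert(!is.null(rn) && !is.null(cn),
          "count matrix requires row and column names")
  if (anyDuplicated(rn)) .validation_error("duplicate row ids in count matrix")
  if (anyDuplicated(cn)) .validation_error("duplicate gene symbols in count matrix")
  structure(list(values = values, row_kind = row_kind), class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' @export
dimnames.count_matrix <- function(x) dimnames(x$values)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d %ss x %d genes, %d nonzero\n",
              nrow(x$values), x$row_kind, ncol(x$values),
              length(x$values@x)))
  invisible(x)
}

#' Read a MatrixMarket count matrix with barcode and gene label files
#'
#' Reads a MatrixMarket coordinate file whose rows are barcodes (cells,
#' nuclei or spots) and whose columns are genes, together with one-column
#' label files. Set `transpose = TRUE` for CellRanger-style exports in which
#' the matrix is stored genes-by-barcodes.
#'
#' Duplicate gene symbols are disambiguated by suffixing `.1`, `.2`, ...
#' (first occurrence kept verbatim).
#'
#' @param matrix_path path to the `.mtx` file (gzipped accepted).
#' @param genes_path path to a one-column file of gene symbols.
#' @param barcodes_path path to a one-column file of barcode ids.
#' @param row_kind row type passed to [count_matrix()].
#' @param transpose logical; if `TRUE` the stored matrix is genes x barcodes
#'   and is transposed on read.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(matrix_path, genes_path, barcodes_path,
                              row_kind = c("cell", "nucleus", "spot"),
                              transpose = FALSE) {
  row_kind <- match.arg(row_kind)
  m <- Matrix::readMM(matrix_path)
  # pattern (binary) MatrixMarket files read back as ngTMatrix
  m <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (transpose) m <- Matrix::t(m)
  genes <- readLines(genes_path)
  genes <- genes[nzchar(genes)]
  # label files may carry extra tab-separated columns (id \t symbol)
  genes <- vapply(strsplit(genes, "\t", fixed = TRUE),
                  function(f) f[[length(f)]], character(1))
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  if (length(barcodes) != nrow(m)) {
    .format_error("barcode file has ", length(barcodes),
                  " entries but matrix has ", nrow(m), " rows")
  }
  if (length(genes) != ncol(m)) {
    .format_error("gene file has ", length(genes),
                  " entries but matrix has ", ncol(m), " columns")
  }
  if (any(m@x < 0)) .validation_error("matrix contains negative counts")
  dimnames(m) <- list(barcodes, make.unique(genes, sep = "."))
  count_matrix(m, row_kind)
}

#' Write a count matrix as MatrixMarket plus label files
#'
#' Inverse of [read_count_matrix()] (with `transpose = FALSE`).
#'
#' @param cm a [count_matrix()].
#' @param matrix_path,genes_path,barcodes_path output paths.
#' @return Invisibly, `cm`.
#' @export
write_count_matrix <- function(cm, matrix_path, genes_path, barcodes_path) {
  stopifnot(inherits(cm, "count_matrix"))
  Matrix::writeMM(cm$values, matrix_path)
  writeLines(colnames(cm$values), genes_path)
  writeLines(rownames(cm$values), barcodes_path)
  invisible(cm)
}

.default_mito_ribo <- function(genes) {
  genes[grepl("^MT-", genes) | grepl("^RP[SL]", genes)]
}

#' QC-filter cells or nuclei
#'
#' Retains barcodes with strictly more than `min_genes` detected genes and a
#' mitochondrial + ribosomal read fraction strictly below `max_frac`. The
#' default fraction cutoff is 20% for cells and 5% for nuclei. By default
#' mitochondrial/ribosomal genes are recognised by symbol prefix (`MT-`,
#' `RPS`, `RPL`); pass `mito_ribo_genes` to override.
#'
#' @param cm a [count_matrix()] with `row_kind` `"cell"` or `"nucleus"`.
#' @param mito_ribo_genes optional character vector of gene symbols counted
#'   as mitochondrial/ribosomal; symbols absent from the matrix are ignored
#'   with a message.
#' @param min_genes detected-gene cutoff (strict `>`); default 200.
#' @param max_frac mito+ribo fraction cutoff (strict `<`); default 0.20 for
#'   cells, 0.05 for nuclei.
#' @return The filtered [count_matrix()]; surviving rows keep their order.
#' @export
qc_filter_cells <- function(cm, mito_ribo_genes = NULL, min_genes = 200,
                            max_frac = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  .assert(cm$row_kind %in% c("cell", "nucleus"),
          "qc_filter_cells expects cells or nuclei, got row_kind = ",
          cm$row_kind)
  if (is.null(max_frac)) {
    max_frac <- if (cm$row_kind == "cell") 0.20 else 0.05
  }
  genes <- colnames(cm$values)
  if (is.null(mito_ribo_genes)) {
    mr <- .default_mito_ribo(genes)
  } else {
    unknown <- setdiff(mito_ribo_genes, genes)
    if (length(unknown)) {
      message(length(unknown), " mito/ribo gene(s) absent from matrix; ignored")
    }
    mr <- intersect(mito_ribo_genes, genes)
  }
  detected <- Matrix::rowSums(cm$values > 0)
  total <- Matrix::rowSums(cm$values)
  mr_count <- if (length(mr)) {
    Matrix::rowSums(cm$values[, mr, drop = FALSE])
  } else {
    rep(0, nrow(cm$values))
  }
  frac <- ifelse(total > 0, mr_count / total, 1)
  keep <- detected > min_genes & frac < max_frac
  if (!any(keep)) warning("QC filter removed every barcode")
  count_matrix(cm$values[keep, , drop = FALSE], cm$row_kind)
}

#' QC-filter Visium spots
#'
#' Retains spots with strictly more than `min_umi` total UMI counts and at
#' least `min_genes` detected genes.
#'
#' @param cm a [count_matrix()] with `row_kind = "spot"`.
#' @param min_umi UMI cutoff (strict `>`); default 500.
#' @param min_genes detected-gene cutoff (inclusive `>=`); default 300.
#' @return The filtered [count_matrix()]; surviving rows keep their order.
#' @export
qc_filter_spots <- function(cm, min_umi = 500, min_genes = 300) {
  stopifnot(inherits(cm, "count_matrix"))
  .assert(cm$row_kind == "spot",
          "qc_filter_spots expects spots, got row_kind = ", cm$row_kind)
  total <- Matrix::rowSums(cm$values)
  detected <- Matrix::rowSums(cm$values > 0)
  keep <- total > min_umi & detected >= min_genes
  if (!any(keep)) warning("QC filter removed every spot")
  count_matrix(cm$values[keep, , drop = FALSE], cm$row_kind)
}

#' Total-count normalize and log-transform
#'
#' Scales each barcode's counts to `target_sum` (default: the median of the
#' nonzero row sums) and applies `log1p`. All-zero rows stay zero.
#'
#' @param cm a [count_matrix()].
#' @param target_sum per-row total after scaling; default median row sum.
#' @return A `norm_matrix`: list with sparse `values`, the source `row_kind`
#'   and `norm_params` (target sum, pseudocount).
#' @export
normalize_log <- function(cm, target_sum = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  total <- Matrix::rowSums(cm$values)
  .assert(any(total > 0), "normalize_log needs at least one nonzero row")
  if (is.null(target_sum)) target_sum <- stats::median(total[total > 0])
  scale <- ifelse(total > 0, target_sum / total, 0)
  v <- Matrix::Diagonal(x = scale) %*% cm$values
  v <- as(v, "CsparseMatrix")
  v@x <- log1p(v@x)
  dimnames(v) <- dimnames(cm$values)
  structure(list(values = v, row_kind = cm$row_kind,
                 norm_params = list(target_sum = target_sum, pseudocount = 1)),
            class = "norm_matrix")
}

#' @export
dim.norm_matrix <- function(x) dim(x$values)

#' @export
dimnames.norm_matrix <- function(x) dimnames(x$values)

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("<norm_matrix> %d %ss x %d genes (target_sum = %.4g, log1p)\n",
              nrow(x$values), x$row_kind, ncol(x$values),
              x$norm_params$target_sum))
  invisible(x)
}

# Coerce a labels argument (named vector or data.frame with id/label
# columns) to a named character vector aligned to the given row ids.
.align_labels <- function(labels, row_ids) {
  if (is.data.frame(labels)) {
    .assert(ncol(labels) >= 2, "label data.frame needs id and label columns")
    labels <- stats::setNames(as.character(labels[[2]]),
                              as.character(labels[[1]]))
  }
  .assert(!is.null(names(labels)), "labels must be named by row id")
  .assert(all(row_ids %in% names(labels)),
          "labels missing for some rows: ",
          paste(utils::head(setdiff(row_ids, names(labels)), 3), collapse = ", "))
  as.character(labels[row_ids])
}

#' Write a data frame as TSV
#'
#' Tab-separated, no quoting, no row names; the convention used for all
#' tabular outputs of the package.
#'
#' @param table a data.frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input path.
#' @return A data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
}
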