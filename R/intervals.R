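#' Read a BED file of genomic intervals
#'
#' Parses a 3+ column tab-delimited BED file (0-based half-open
#' coordinates) into a `GRanges`. The fourth column, when present, becomes
#' the interval name; further columns are preserved as metadata columns.
#' `GRanges` uses 1-based closed coordinates, so a BED line
#' `chr1 100 601` becomes `chr1:101-601` covering bases 100..600 in 0-based
#' numbering; [write_bed()] inverts the shift.
#'
#' @param path path to a BED file (gzipped accepted).
#' @return A [GenomicRanges::GRanges] with a `name` metadata column.
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           stringsAsFactors = FALSE, comment.char = "#")
  .assert(ncol(tab) >= 3, "BED file needs at least 3 columns: ", path)
  chrom <- as.character(tab[[1]])
  start0 <- tab[[2]]
  end0 <- tab[[3]]
  if (any(is.na(start0)) || any(is.na(end0))) {
    .validation_error("BED file has missing coordinates: ", path)
  }
  if (any(start0 < 0)) .validation_error("BED start < 0 in ", path)
  if (any(start0 >= end0)) {
    .validation_error("BED interval with start >= end in ", path)
  }
  name <- if (ncol(tab) >= 4) as.character(tab[[4]]) else
    paste0("iv", seq_len(nrow(tab)))
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1L, end = end0),
                               name = name)
  if (ncol(tab) > 4) {
    extra <- tab[, -(1:4), drop = FALSE]
    names(extra) <- paste0("V", seq(5, ncol(tab)))
    S4Vectors::mcols(gr) <- cbind(S4Vectors::mcols(gr), extra)
  }
  gr
}

#' Write intervals as BED
#'
#' Writes a `GRanges` back to 0-based half-open BED, with the `name`
#' metadata column (or running ids) as the fourth column.
#'
#' @param gr a [GenomicRanges::GRanges].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(gr, path) {
  name <- S4Vectors::mcols(gr)$name
  if (is.null(name)) name <- paste0("iv", seq_along(gr))
  tab <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    name = name)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build 1-bp SNP intervals from positions
#'
#' @param chrom chromosome per SNP (recycled).
#' @param pos SNP positions; 0-based by default, set `one_based = TRUE` for
#'   conventional variant coordinates.
#' @param name optional SNP ids.
#' @param one_based logical; convert from 1-based coordinates.
#' @return A [GenomicRanges::GRanges] of width-1 intervals.
#' @export
snp_granges <- function(chrom, pos, name = NULL, one_based = FALSE) {
  .assert(all(pos >= if (one_based) 1 else 0), "SNP position out of range")
  start1 <- if (one_based) pos else pos + 1L
  if (is.null(name)) name <- paste0("rs_synth", seq_along(pos))
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start1, width = 1L),
                         name = name)
}
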