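#' Family-specific pChEMBL activity threshold
#'
#' Converts the per-family nanomolar potency cutoffs used to gate drug-target
#' records (kinases 30 nM; GPCRs and nuclear hormone receptors 100 nM; ion
#' channels 10 uM; all others 1 uM) to the pChEMBL scale:
#' `pchembl_min = 9 - log10(cutoff_nM)`, so 100 nM corresponds to 7.0.
#'
#' @param family one of `"kinase"`, `"gpcr"`, `"nuclear_receptor"`,
#'   `"ion_channel"`, `"other"`.
#' @return Minimal pChEMBL value an active record must reach (inclusive).
#' @examples
#' family_pchembl_threshold("gpcr")        # 7
#' family_pchembl_threshold("ion_channel") # 5
#' @export
family_pchembl_threshold <- function(family) {
  cutoffs_nm <- c(kinase = 30, gpcr = 100, nuclear_receptor = 100,
                  ion_channel = 1e4, other = 1e3)
  bad <- setdiff(family, names(cutoffs_nm))
  if (length(bad)) {
    .validation_error("unknown target family: ", paste(bad, collapse = ", "))
  }
  unname(9 - log10(cutoffs_nm[family]))
}

#' Read a ChEMBL-export-like drug-target table
#'
#' Expected CSV columns: `drug_id`, `drug_name`, `max_phase`, `organism`,
#' `target_gene`, `target_family`, `pchembl` (may be empty), `atc_codes`
#' (semicolon-separated, may be empty).
#'
#' @param path CSV path.
#' @return A data.frame of drug-target records.
#' @export
read_drug_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("drug_id", "drug_name", "max_phase", "organism",
              "target_gene", "target_family", "pchembl", "atc_codes")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    .format_error("drug table missing columns: ",
                  paste(missing, collapse = ", "))
  }
  tab$pchembl <- suppressWarnings(as.numeric(tab$pchembl))
  tab$max_phase <- as.integer(tab$max_phase)
  tab
}

#' Filter drug-target records into per-drug gene sets
#'
#' Keeps records matching the target organism and a minimal clinical phase,
#' and (when `require_active`) gates bioactivity at the family-specific
#' pChEMBL threshold ([family_pchembl_threshold()]), comparing the **best**
#' (maximum) pChEMBL per drug-target pair inclusively (`>=`). Records with
#' missing pChEMBL are dropped under the activity gate and kept otherwise.
#' Drugs left without targets are removed.
#'
#' @param table data.frame of records as from [read_drug_table()].
#' @param max_phase_min minimal clinical phase (4 = approved; 1-3 selects
#'   preclinical bioactive molecules).
#' @param organism organism filter; default `"Homo sapiens"`.
#' @param require_active logical; apply the pChEMBL family gate.
#' @return An object of class `drug_gene_sets`: a named list keyed by
#'   `drug_id`, each element a list with `drug_name`, `atc_codes` and
#'   `genes` (sorted, unique).
#' @export
filter_drug_targets <- function(table, max_phase_min = 4,
                                organism = "Homo sapiens",
                                require_active = TRUE) {
  if (nrow(table) == 0) {
    warning("empty drug-target table")
    return(structure(list(), class = "drug_gene_sets"))
  }
  keep <- table$organism == organism & table$max_phase >= max_phase_min
  tab <- table[keep, , drop = FALSE]
  if (require_active && nrow(tab)) {
    tab <- tab[!is.na(tab$pchembl), , drop = FALSE]
    if (nrow(tab)) {
      # activity is judged on the best measurement per drug-target pair
      key <- paste(tab$drug_id, tab$target_gene, tab$target_family, sep = "\r")
      best <- tapply(tab$pchembl, key, max)
      thr <- family_pchembl_threshold(tab$target_family)
      tab <- tab[unname(best[key]) >= thr, , drop = FALSE]
    }
  }
  if (nrow(tab) == 0) {
    warning("no drug-target records survived filtering")
    return(structure(list(), class = "drug_gene_sets"))
  }
  sets <- lapply(split(tab, tab$drug_id), function(d) {
    codes <- unlist(strsplit(d$atc_codes[!is.na(d$atc_codes)], ";",
                             fixed = TRUE))
    codes <- unique(trimws(codes))
    codes <- codes[nzchar(codes)]
    list(drug_name = d$drug_name[[1]],
         atc_codes = codes,
         genes = sort(unique(d$target_gene)))
  })
  structure(sets, class = "drug_gene_sets")
}

#' @export
print.drug_gene_sets <- function(x, ...) {
  cat(sprintf("<drug_gene_sets> %d drugs, %d distinct target genes\n",
              length(x),
              length(unique(unlist(lapply(x, `[[`, "genes"))))))
  invisible(x)
}

#' Group drugs by ATC code prefix
#'
#' ATC levels correspond to code prefixes of length 1, 3, 4, 5 and 7. A drug
#' carrying k distinct level-prefixes appears in all k groups; drugs with no
#' ATC code fall under `"unclassified"`.
#'
#' @param sets a [filter_drug_targets()] result.
#' @param level ATC level 1-5; default 1 (anatomical main group letter).
#' @return Named list mapping ATC prefix to a character vector of drug ids.
#' @export
group_by_atc <- function(sets, level = 1) {
  stopifnot(inherits(sets, "drug_gene_sets"))
  widths <- c(1L, 3L, 4L, 5L, 7L)
  .assert(level %in% seq_along(widths), "ATC level must be 1..5")
  w <- widths[[level]]
  groups <- list()
  for (drug in names(sets)) {
    codes <- sets[[drug]]$atc_codes
    prefixes <- if (length(codes)) unique(substr(codes, 1L, w)) else "unclassified"
    for (p in prefixes) groups[[p]] <- c(groups[[p]], drug)
  }
  groups[order(names(groups))]
}

#' Write per-drug gene sets as TSV
#'
#' One row per drug: id, name, semicolon-joined ATC codes and target genes.
#'
#' @param sets a [filter_drug_targets()] result.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_drug_gene_sets <- function(sets, path) {
  stopifnot(inherits(sets, "drug_gene_sets"))
  tab <- data.frame(
    drug_id = names(sets),
    drug_name = vapply(sets, `[[`, character(1), "drug_name"),
    atc_codes = vapply(sets, function(s) paste(s$atc_codes, collapse = ";"),
                       character(1)),
    genes = vapply(sets, function(s) paste(s$genes, collapse = ";"),
                   character(1)),
    row.names = NULL)
  write_tsv(tab, path)
}
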