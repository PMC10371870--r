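#' Default pipeline configuration
#'
#' Flat list of every tunable the pipeline stages use, at the package
#' defaults: QC (200 genes, 20%/5% mito+ribo, 500 UMI / 300 genes for
#' spots), family pChEMBL cutoffs, drug-ranking gates (log2FC > 2,
#' BH p < 0.05), 10% expression filter, 5% open-peak rule, 1000
#' permutations, NMF rank range 5..14 with fine-factor proportion 0.5, and
#' the 0.03 / n > 5 product-niche rule. Serialize with [yaml::write_yaml()]
#' and reload with [read_config()].
#'
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param out_dir output directory.
#' @return A named list (class `run_config`).
#' @export
default_config <- function(seed = 1L, out_dir = "cardioniche_out") {
  structure(list(
    seed = as.integer(seed), out_dir = out_dir,
    qc_min_genes = 200, qc_max_frac_cell = 0.20, qc_max_frac_nucleus = 0.05,
    spot_min_umi = 500, spot_min_genes = 300,
    drug_max_phase_min = 4, drug_lfc_min = 2, drug_p_adj_max = 0.05,
    score_n_bins = 25, score_ctrl_per_gene = 50,
    lr_min_frac = 0.1, lr_p_max = 0.05, lr_min_cells = 10,
    open_peak_frac = 0.05, n_perm = 1000,
    nmf_n_fact_min = 5, nmf_n_fact_max = 14,
    factor_alpha = 0.05, factor_proportion = 0.5,
    niche_threshold = 0.03, niche_min_cluster = 5,
    adjacency_scale = 1.5),
    class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to [default_config()].
#'
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown)) {
    .validation_error("unknown config key(s): ",
                      paste(unknown, collapse = ", "))
  }
  base[names(cfg)] <- cfg
  base
}

#' Run the full pipeline on a synthetic fixture bundle
#'
#' End-to-end orchestration over a directory produced by
#' [write_synth_bundle()] (or real data in the same formats): QC and
#' normalization, drug-target filtering/scoring/ranking for the first cell
#' state, structure enrichment and product-niche calling on the abundance
#' matrix, the NMF scan with factor selection, the trait-by-state SNP
#' enrichment scan, and the statistical ligand-receptor screen. Each stage
#' writes a TSV into `config$out_dir`, and a machine-readable JSON report
#' records parameters, seeds and row counts.
#'
#' @param input_dir directory with the input bundle.
#' @param config a `run_config` list; default [default_config()].
#' @param stages subset of stages to run.
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(input_dir, config = default_config(),
                         stages = c("qc", "drug", "enrich", "niche",
                                    "gwas", "lr")) {
  need <- function(f) {
    p <- file.path(input_dir, f)
    if (!file.exists(p)) .validation_error("missing input file: ", p)
    p
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package_version = as.character(utils::packageVersion("cardioniche")),
                 seed = config$seed, parameters = unclass(config),
                 stages = list())
  counts <- read_count_matrix(need("counts.mtx"), need("genes.tsv"),
                              need("barcodes.tsv"))
  labels_tab <- read_tsv(need("cell_states.tsv"))
  labels <- stats::setNames(labels_tab[[2]], labels_tab[[1]])

  if ("qc" %in% stages) {
    counts <- qc_filter_cells(counts, min_genes = config$qc_min_genes,
                              max_frac = config$qc_max_frac_cell)
    report$stages$qc <- list(n_cells_kept = nrow(counts$values))
  }
  norm <- normalize_log(counts)
  labels <- labels[rownames(norm$values)]
  state1 <- sort(unique(labels))[1]

  if ("drug" %in% stages) {
    drugs <- read_drug_table(need("drug_targets.csv"))
    sets <- filter_drug_targets(drugs,
                                max_phase_min = config$drug_max_phase_min)
    scores <- vapply(sets, function(s) {
      score_gene_set_binned_ref(norm, s$genes,
                                n_bins = min(config$score_n_bins,
                                             ncol(norm$values)),
                                ctrl_per_gene = config$score_ctrl_per_gene,
                                seed = config$seed + 11L)
    }, numeric(nrow(norm$values)))
    ranking <- rank_sets_for_group(scores, labels, state1,
                                   lfc_min = config$drug_lfc_min,
                                   p_adj_max = config$drug_p_adj_max)
    write_tsv(ranking, file.path(config$out_dir, "drug_ranking.tsv"))
    report$stages$drug <- list(n_drugs = length(sets),
                               n_flagged = sum(ranking$flagged),
                               group = state1)
  }
  if (any(c("enrich", "niche") %in% stages)) {
    ab <- read_abundance_matrix(need("abundance.tsv"))
  }
  if ("enrich" %in% stages) {
    structs <- setdiff(unique(ab$structure), NA)
    enr <- do.call(rbind, lapply(structs, function(s) {
      structure_enrichment(ab, s)
    }))
    write_tsv(enr, file.path(config$out_dir, "structure_enrichment.tsv"))
    top2 <- colnames(ab$abundance)[
      order(-colSums(ab$abundance))][1:2]
    niche <- call_product_niche(ab, top2[1], top2[2],
                                threshold = config$niche_threshold,
                                min_cluster = config$niche_min_cluster,
                                scale = config$adjacency_scale)
    member <- data.frame(
      spot = unlist(niche$clusters),
      cluster = rep(seq_along(niche$clusters), niche$sizes))
    write_tsv(member, file.path(config$out_dir, "product_niche.tsv"))
    report$stages$enrich <- list(n_structures = length(structs),
                                 n_niche_clusters = length(niche$clusters))
  }
  if ("niche" %in% stages) {
    scan <- nmf_scan(ab, config$nmf_n_fact_min:config$nmf_n_fact_max,
                     seed = config$seed + 21L)
    struct1 <- setdiff(unique(ab$structure), NA)[1]
    mask <- !is.na(ab$structure) & ab$structure == struct1
    sel <- select_factors(scan, mask, alpha = config$factor_alpha,
                          proportion = config$factor_proportion,
                          n_perm = config$n_perm,
                          seed = config$seed + 22L)
    write_tsv(sel$table, file.path(config$out_dir, "nmf_factors.tsv"))
    report$stages$niche <- list(
      total_factors = sum(vapply(scan, `[[`, integer(1), "n_fact")),
      structure = struct1,
      chosen_n_fact = sel$chosen_n_fact,
      n_fine_factors = nrow(sel$fine_factors))
  }
  if ("gwas" %in% stages) {
    peaks <- read_bed(need("peaks.bed"))
    pk_counts <- read_count_matrix(need("peak_counts.mtx"),
                                   need("peak_ids.tsv"),
                                   need("peak_barcodes.tsv"))
    pk_labels_tab <- read_tsv(need("peak_cell_states.tsv"))
    pm <- peak_matrix(pk_counts$values, peaks,
                      stats::setNames(pk_labels_tab[[2]],
                                      pk_labels_tab[[1]]))
    calls <- call_open_peaks(binarize_counts(pm),
                             frac = config$open_peak_frac)
    snp_files <- list.files(input_dir, pattern = "^snps_.*\\.bed$",
                            full.names = TRUE)
    traits <- lapply(snp_files, read_bed)
    names(traits) <- sub("^snps_(.*)\\.bed$", "\\1", basename(snp_files))
    scan <- trait_state_scan(calls, traits, n_perm = config$n_perm,
                             seed = config$seed + 31L)
    write_tsv(scan, file.path(config$out_dir, "snp_enrichment.tsv"))
    report$stages$gwas <- list(n_traits = length(traits),
                               n_states = nrow(calls$open),
                               n_significant = sum(scan$p_adj < 0.05))
  }
  if ("lr" %in% stages) {
    db <- load_lr_database(need("lr_interactions.csv"),
                           need("lr_complexes.csv"))
    niche_states <- utils::head(sort(unique(labels)), 2)
    screen <- niche_interaction_screen(
      norm, labels, db, niche_states, mode = "statistical",
      min_frac = config$lr_min_frac, p_max = config$lr_p_max,
      n_perm = min(config$n_perm, 200L), seed = config$seed + 41L,
      min_cells = config$lr_min_cells)
    write_tsv(screen, file.path(config$out_dir, "lr_screen.tsv"))
    report$stages$lr <- list(n_interactions = nrow(db$interactions),
                             n_selected = sum(screen$selected))
  }
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
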