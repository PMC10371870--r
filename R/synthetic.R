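# Seeded generators for every input the toolkit consumes, with planted
# signal so each stage has a known answer. Defaults emulate the study
# conditions the analyses assume: overdispersed negative-binomial counts,
# a hex-offset Visium-like spot grid with annotated structures, 501-bp
# fixed-width accessibility peaks, and ChEMBL-/CellPhoneDB-style tables.

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Generate a synthetic cell-by-gene count matrix with planted programs
#'
#' Draws negative-binomial counts (mean/dispersion parameterisation) with
#' per-state marker programs: the `markers_per_state` marker genes of state
#' `s` have their mean multiplied by `2^effect` in cells of `s`. Gene base
#' means are log-normal, cell depth factors log-normal, so the matrix shows
#' realistic library-size variation.
#'
#' @param n_cells_per_state named integer vector: cells per state.
#' @param n_genes total genes; default 400.
#' @param markers_per_state markers planted per state; default 10.
#' @param effect log2 fold shift of marker means in their state; default 2.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   default 0.5.
#' @param base_mean_meanlog,base_mean_sdlog log-normal parameters of gene
#'   base means.
#' @param seed RNG seed.
#' @param row_kind row type of the returned matrix.
#' @return List with `counts` (a [count_matrix()]), `labels` (named state
#'   per cell) and `markers` (named list of marker genes per state).
#' @export
gen_expression <- function(n_cells_per_state = c(stateA = 200, stateB = 200,
                                                 stateC = 200),
                           n_genes = 400, markers_per_state = 10,
                           effect = 2, dispersion = 0.5,
                           base_mean_meanlog = 0, base_mean_sdlog = 1,
                           seed = 1L, row_kind = "cell") {
  .assert(!is.null(names(n_cells_per_state)),
          "n_cells_per_state must be named by state")
  n_states <- length(n_cells_per_state)
  .assert(n_states * markers_per_state <= n_genes,
          "marker programs exceed the gene count")
  with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    states <- names(n_cells_per_state)
    markers <- stats::setNames(vector("list", n_states), states)
    pool <- genes
    for (s in states) {
      markers[[s]] <- sort(sample(pool, markers_per_state))
      pool <- setdiff(pool, markers[[s]])
    }
    base_mu <- stats::rlnorm(n_genes, base_mean_meanlog, base_mean_sdlog)
    names(base_mu) <- genes
    n_cells <- sum(n_cells_per_state)
    labels <- rep(states, n_cells_per_state)
    cells <- sprintf("cell_%05d", seq_len(n_cells))
    depth <- stats::rlnorm(n_cells, 0, 0.25)
    size <- 1 / dispersion
    counts <- matrix(0L, n_cells, n_genes, dimnames = list(cells, genes))
    for (s in states) {
      rows <- which(labels == s)
      mu <- base_mu
      mu[markers[[s]]] <- mu[markers[[s]]] * 2^effect
      m <- outer(depth[rows], mu)
      counts[rows, ] <- stats::rnbinom(length(m), mu = m, size = size)
    }
    list(counts = count_matrix(Matrix::Matrix(counts, sparse = TRUE),
                               row_kind),
         labels = stats::setNames(labels, cells),
         markers = markers)
  })
}

# hex-offset coordinates: odd rows shifted half a column, rows compressed
# by sqrt(3)/2, so each interior spot has 6 equidistant neighbours.
.hex_coords <- function(n_row, n_col) {
  i <- rep(seq_len(n_row), each = n_col)
  j <- rep(seq_len(n_col), times = n_row)
  data.frame(array_row = (i - 1) * sqrt(3) / 2,
             array_col = (j - 1) + (i %% 2 == 0) * 0.5,
             grid_row = i, grid_col = j)
}

#' Generate a synthetic spot-by-state abundance matrix
#'
#' Lays out a hex-offset grid of spots, tiles it with rectangular regions
#' (in grid-row bands), and draws per-spot state abundances as
#' `total x Dirichlet(concentration x region mixture)`, where the spot
#' total emulates the handful of cells contributing to a Visium spot.
#' Structure labels equal the region names (regions named `"none"` stay
#' unannotated).
#'
#' @param n_row,n_col grid dimensions; default 14 x 14.
#' @param regions named list of region definitions: each a list with `rows`
#'   (grid-row indices) and `mixture` (named state proportions summing
#'   to 1). Regions must tile the grid without overlap. The default plants
#'   a central compartment, a peripheral ring and background myocardium in
#'   the spirit of a compartmentalized node.
#' @param concentration Dirichlet concentration (higher = crisper
#'   mixtures); default 50.
#' @param total_meanlog,total_sdlog log-normal parameters of the spot
#'   total abundance; defaults `log(7)` and 0.3 (about seven nuclei per
#'   spot).
#' @param seed RNG seed.
#' @return An [abundance_matrix()].
#' @export
gen_spots <- function(n_row = 14, n_col = 14,
                      regions = default_spot_regions(n_row),
                      concentration = 50,
                      total_meanlog = log(7), total_sdlog = 0.3,
                      seed = 1L) {
  coords <- .hex_coords(n_row, n_col)
  assigned <- rep(NA_character_, nrow(coords))
  for (rn in names(regions)) {
    hit <- coords$grid_row %in% regions[[rn]]$rows
    .assert(!any(hit & !is.na(assigned)), "regions overlap at region ", rn)
    assigned[hit] <- rn
  }
  .assert(!anyNA(assigned), "regions do not tile the grid")
  states <- unique(unlist(lapply(regions, function(r) names(r$mixture))))
  for (rn in names(regions)) {
    mix <- regions[[rn]]$mixture
    .assert(abs(sum(mix) - 1) < 1e-8,
            "mixture of region ", rn, " does not sum to 1")
  }
  with_seed(seed, {
    n <- nrow(coords)
    ab <- matrix(0, n, length(states),
                 dimnames = list(sprintf("spot_%04d", seq_len(n)), states))
    totals <- stats::rlnorm(n, total_meanlog, total_sdlog)
    for (k in seq_len(n)) {
      mix <- regions[[assigned[k]]]$mixture
      alpha <- stats::setNames(rep(1e-3, length(states)), states)
      alpha[names(mix)] <- pmax(concentration * mix, 1e-3)
      ab[k, ] <- totals[k] * .rdirichlet1(alpha)
    }
    structure_lab <- ifelse(assigned == "none", NA_character_, assigned)
    abundance_matrix(ab, coords$array_row, coords$array_col, structure_lab)
  })
}

#' Default region layout for [gen_spots()]
#'
#' A central compartment (distinct pacemaker-like mixture), a peripheral
#' band around it, and background myocardium filling the rest.
#'
#' @param n_row grid rows available.
#' @return Named list of region definitions.
#' @export
default_spot_regions <- function(n_row = 14) {
  mid <- seq(ceiling(n_row / 2) - 1, ceiling(n_row / 2) + 1)
  peri <- setdiff(seq(min(mid) - 2, max(mid) + 2), mid)
  rest <- setdiff(seq_len(n_row), c(mid, peri))
  list(
    central = list(rows = mid,
                   mixture = c(P_cell = 0.45, FB_node = 0.25, glial = 0.15,
                               MP = 0.05, EC_cap = 0.10)),
    peripheral = list(rows = peri,
                      mixture = c(P_cell = 0.12, FB_node = 0.10,
                                  glial = 0.08, aCM1 = 0.45, EC_cap = 0.15,
                                  SMC = 0.10)),
    none = list(rows = rest,
                mixture = c(aCM1 = 0.28, aCM2 = 0.15, vCM1 = 0.14,
                            FB1 = 0.12, EC_cap = 0.10, EC_ven = 0.06,
                            PC = 0.05, SMC = 0.04, MP = 0.03,
                            FB_act = 0.01, vCM3_str = 0.01, mast = 0.01))
  )
}

#' Region layout planting a product-abundance stress niche
#'
#' A compact block of spots where activated-fibroblast and
#' stressed-cardiomyocyte abundances are jointly high (so their product
#' clears the default 0.03 call threshold), embedded in background
#' myocardium where both are rare.
#'
#' @param n_row,n_col grid dimensions the layout is built for.
#' @return Named list of region definitions for [gen_spots()].
#' @export
stress_niche_regions <- function(n_row = 12, n_col = 12) {
  mid <- seq(ceiling(n_row / 2) - 1, ceiling(n_row / 2) + 1)
  rest <- setdiff(seq_len(n_row), mid)
  list(
    stress = list(rows = mid,
                  mixture = c(FB_act = 0.30, vCM3_str = 0.30, vCM1 = 0.20,
                              EC_cap = 0.10, MP = 0.10)),
    # background keeps both stress states rare (joint product of their
    # abundances far below the 0.03 call threshold)
    none = list(rows = rest,
                mixture = c(vCM1 = 0.52, aCM1 = 0.20, FB1 = 0.12,
                            EC_cap = 0.10, FB_act = 0.005,
                            vCM3_str = 0.005, MP = 0.05))
  )
}

#' Generate synthetic peaks, a barcode-by-peak matrix and trait SNPs
#'
#' Places `n_peaks` non-overlapping 501-bp fixed-width peaks on a synthetic
#' chromosome, chooses a true open-peak set per state (a shared baseline
#' fraction plus state-specific peaks), and draws binary barcode detection
#' with high probability in truly open peaks and a low background
#' otherwise. One trait per entry of `enrichment`: each SNP falls, with
#' probability `min(1, factor x coverage)`, uniformly inside a truly open
#' peak of the trait's target state, and uniformly on the chromosome
#' otherwise - so `factor = 1` is (approximately) the null and larger
#' factors plant enrichment.
#'
#' @param n_peaks number of peaks; default 120.
#' @param peak_width fixed width in bp; default 501.
#' @param genome_length chromosome length; default `n_peaks * 4000`.
#' @param states character vector of state names.
#' @param n_barcodes_per_state barcodes per state; default 80.
#' @param base_open_frac fraction of peaks open in every state; default 0.3.
#' @param specific_per_state additional state-specific open peaks;
#'   default 10.
#' @param detect_open,detect_closed per-barcode detection probabilities;
#'   defaults 0.4 and 0.01.
#' @param enrichment named list: trait -> list(state, factor, n_snps).
#' @param seed RNG seed.
#' @return List with `pm` (a [peak_matrix()]), `peaks` (`GRanges`),
#'   `traits` (named list of SNP `GRanges`) and `true_open` (state x peak
#'   logical matrix).
#' @export
gen_peaks_snps <- function(n_peaks = 120, peak_width = 501,
                           genome_length = n_peaks * 4000,
                           states = c("stateA", "stateB", "stateC"),
                           n_barcodes_per_state = 80,
                           base_open_frac = 0.3, specific_per_state = 10,
                           detect_open = 0.4, detect_closed = 0.01,
                           enrichment = list(trait1 = list(state = "stateA",
                                                           factor = 5,
                                                           n_snps = 200)),
                           seed = 1L) {
  .assert(n_peaks * (peak_width + 1) <= genome_length,
          "genome too small for the requested peaks")
  with_seed(seed, {
    # non-overlapping starts on a jittered lattice
    slot <- floor(genome_length / n_peaks)
    starts0 <- (seq_len(n_peaks) - 1L) * slot +
      sample.int(slot - peak_width, n_peaks, replace = TRUE) - 1L
    peaks <- GenomicRanges::GRanges("chrS",
                                    IRanges::IRanges(start = starts0 + 1L,
                                                     width = peak_width),
                                    name = sprintf("peak_%04d",
                                                   seq_len(n_peaks)))
    true_open <- matrix(FALSE, length(states), n_peaks,
                        dimnames = list(states,
                                        S4Vectors::mcols(peaks)$name))
    shared <- sample.int(n_peaks, round(base_open_frac * n_peaks))
    free <- setdiff(seq_len(n_peaks), shared)
    for (s in states) {
      spec <- sample(free, specific_per_state)
      free <- setdiff(free, spec)
      true_open[s, c(shared, spec)] <- TRUE
    }
    n_bc <- n_barcodes_per_state * length(states)
    barcodes <- sprintf("bc_%05d", seq_len(n_bc))
    labels <- stats::setNames(rep(states, each = n_barcodes_per_state),
                              barcodes)
    prob <- ifelse(true_open[labels, , drop = FALSE], detect_open,
                   detect_closed)
    vals <- matrix(stats::rbinom(length(prob), 1, prob), nrow = n_bc,
                   dimnames = list(barcodes, colnames(true_open)))
    pm <- peak_matrix(Matrix::Matrix(vals, sparse = TRUE), peaks, labels)
    traits <- lapply(enrichment, function(e) {
      # plant into peaks open *specifically* in the target state (its
      # cell-state-specific regulatory elements); peaks shared with other
      # states would leak the enrichment into every state carrying them
      others <- setdiff(states, e$state)
      specific <- true_open[e$state, ] &
        colSums(true_open[others, , drop = FALSE]) == 0
      open_idx <- which(specific)
      if (!length(open_idx)) open_idx <- which(true_open[e$state, ])
      # under uniform placement a SNP lands in the state's open peaks with
      # probability p0; mix in targeted placement so the expected SNP
      # proportion becomes factor * p0 (factor 1 -> purely uniform)
      p0 <- sum(true_open[e$state, ]) * peak_width / genome_length
      q <- max(0, min(1, p0 * (e$factor - 1) / (1 - p0)))
      in_open <- stats::runif(e$n_snps) < q
      pos <- integer(e$n_snps)
      if (any(in_open)) {
        pk <- sample(open_idx, sum(in_open), replace = TRUE)
        pos[in_open] <- starts0[pk] +
          sample.int(peak_width, sum(in_open), replace = TRUE) - 1L
      }
      if (any(!in_open)) {
        pos[!in_open] <- sample.int(genome_length, sum(!in_open)) - 1L
      }
      snp_granges("chrS", pos)
    })
    list(pm = pm, peaks = peaks, traits = traits, true_open = true_open)
  })
}

#' Generate a synthetic ChEMBL-export-like drug-target table
#'
#' Plants one approved, fully active drug per entry of `planted` whose
#' target genes are the given marker program, plus decoy drugs that fail
#' the standard filters in different ways: sub-threshold pChEMBL, wrong
#' organism, or too low a clinical phase.
#'
#' @param planted named list: drug name -> list(genes, family, atc). The
#'   planted pChEMBL sits 1 unit above the family threshold.
#' @param n_decoys decoys per failure mode; default 5.
#' @param n_neutral approved, active competitor drugs with random target
#'   genes (these survive filtering, so planted drugs are ranked against
#'   real competition); default 10.
#' @param targets_per_neutral target genes per competitor; default 5.
#' @param gene_pool genes decoy/competitor targets are drawn from.
#' @param seed RNG seed.
#' @return A data.frame in the [read_drug_table()] column layout.
#' @export
gen_drug_table <- function(planted, n_decoys = 5, n_neutral = 10,
                           targets_per_neutral = 5,
                           gene_pool = sprintf("G%04d", 1:400),
                           seed = 1L) {
  with_seed(seed, {
    rows <- list()
    add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(...)
    i <- 0L
    for (nm in names(planted)) {
      p <- planted[[nm]]
      i <- i + 1L
      for (g in p$genes) {
        add(drug_id = sprintf("PLANT%03d", i), drug_name = nm,
            max_phase = 4L, organism = "Homo sapiens", target_gene = g,
            target_family = p$family,
            pchembl = family_pchembl_threshold(p$family) + 1,
            atc_codes = if (is.null(p$atc)) "" else p$atc)
      }
    }
    fams <- c("kinase", "gpcr", "nuclear_receptor", "ion_channel", "other")
    for (d in seq_len(n_neutral)) {
      fam <- sample(fams, 1)
      for (g in sample(gene_pool, targets_per_neutral)) {
        add(drug_id = sprintf("NEUT%03d", d),
            drug_name = sprintf("competitor_%d", d), max_phase = 4L,
            organism = "Homo sapiens", target_gene = g,
            target_family = fam,
            pchembl = family_pchembl_threshold(fam) + 0.5,
            atc_codes = sample(c("A01AA", "C01EB;N05AA", ""), 1))
      }
    }
    for (d in seq_len(n_decoys)) {
      fam <- sample(fams, 3, replace = TRUE)
      add(drug_id = sprintf("DECOYW%03d", d),   # weak bioactivity
          drug_name = sprintf("decoy_weak_%d", d), max_phase = 4L,
          organism = "Homo sapiens", target_gene = sample(gene_pool, 1),
          target_family = fam[1],
          pchembl = family_pchembl_threshold(fam[1]) - 0.5, atc_codes = "")
      add(drug_id = sprintf("DECOYO%03d", d),   # wrong organism
          drug_name = sprintf("decoy_org_%d", d), max_phase = 4L,
          organism = "Rattus norvegicus", target_gene = sample(gene_pool, 1),
          target_family = fam[2],
          pchembl = family_pchembl_threshold(fam[2]) + 1, atc_codes = "")
      add(drug_id = sprintf("DECOYP%03d", d),   # preclinical phase
          drug_name = sprintf("decoy_phase_%d", d), max_phase = 2L,
          organism = "Homo sapiens", target_gene = sample(gene_pool, 1),
          target_family = fam[3],
          pchembl = family_pchembl_threshold(fam[3]) + 1, atc_codes = "")
    }
    do.call(rbind, rows)
  })
}

#' Generate a synthetic ligand-receptor module
#'
#' Builds interaction and complex tables in the CellPhoneDB-style schema of
#' [load_lr_database()]: simple gene-gene pairs, receptor complexes with
#' 2-3 members, and a fraction of proxy-ligand interactions. Useful both as
#' a screen fixture and to exercise the loader at the scale of a full
#' curated module.
#'
#' @param n_simple simple interactions; default 700.
#' @param n_complex complex-receptor interactions; default 150.
#' @param proxy_frac fraction of simple interactions flagged as ligand
#'   proxies; default 0.2.
#' @param gene_pool symbols partners are drawn from.
#' @param seed RNG seed.
#' @return List with `interactions` and `complexes` data.frames (write them
#'   with [utils::write.csv()] to feed [load_lr_database()]).
#' @export
gen_lr_module <- function(n_simple = 700, n_complex = 150,
                          proxy_frac = 0.2,
                          gene_pool = sprintf("LG%04d", 1:2000),
                          seed = 1L) {
  with_seed(seed, {
    a <- sample(gene_pool, n_simple, replace = TRUE)
    b <- sample(gene_pool, n_simple, replace = TRUE)
    cx_names <- sprintf("CPX%03d", seq_len(max(n_complex, 1)))
    sizes <- sample(2:3, n_complex, replace = TRUE)
    members <- lapply(sizes, function(k) sample(gene_pool, k))
    complexes <- data.frame(
      complex_name = cx_names[seq_len(n_complex)],
      member_1 = vapply(members, `[`, character(1), 1),
      member_2 = vapply(members, `[`, character(1), 2),
      member_3 = vapply(members, function(m) {
        if (length(m) >= 3) m[3] else ""
      }, character(1)))
    inter <- data.frame(
      partner_a = c(a, sample(gene_pool, n_complex, replace = TRUE)),
      partner_b = c(b, cx_names[seq_len(n_complex)]),
      is_proxy = c(stats::runif(n_simple) < proxy_frac,
                   rep(FALSE, n_complex)))
    list(interactions = inter, complexes = complexes)
  })
}

#' Write the full synthetic fixture bundle to a directory
#'
#' Emits every input format the toolkit consumes: count MTX + labels,
#' cell-state annotation TSV, abundance TSV, peak/SNP BEDs, the
#' barcode-by-peak MTX, the drug-target CSV and the interaction/complex
#' CSVs.
#'
#' @param dir output directory (created if needed).
#' @param seed master RNG seed.
#' @return Invisibly, a named list of the generated objects.
#' @export
write_synth_bundle <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr <- gen_expression(seed = seed)
  write_count_matrix(expr$counts,
                     file.path(dir, "counts.mtx"),
                     file.path(dir, "genes.tsv"),
                     file.path(dir, "barcodes.tsv"))
  write_tsv(data.frame(barcode = names(expr$labels),
                       cell_state = unname(expr$labels)),
            file.path(dir, "cell_states.tsv"))
  ab <- gen_spots(seed = seed + 1L)
  write_abundance_matrix(ab, file.path(dir, "abundance.tsv"))
  ps <- gen_peaks_snps(seed = seed + 2L)
  write_bed(ps$peaks, file.path(dir, "peaks.bed"))
  for (tr in names(ps$traits)) {
    write_bed(ps$traits[[tr]], file.path(dir, paste0("snps_", tr, ".bed")))
  }
  write_count_matrix(count_matrix(ps$pm$values, "cell"),
                     file.path(dir, "peak_counts.mtx"),
                     file.path(dir, "peak_ids.tsv"),
                     file.path(dir, "peak_barcodes.tsv"))
  write_tsv(data.frame(barcode = names(ps$pm$labels),
                       cell_state = unname(ps$pm$labels)),
            file.path(dir, "peak_cell_states.tsv"))
  drugs <- gen_drug_table(
    planted = list(planted_drug = list(genes = expr$markers$stateA,
                                       family = "gpcr", atc = "C01EB")),
    gene_pool = colnames(expr$counts$values), seed = seed + 3L)
  utils::write.csv(drugs, file.path(dir, "drug_targets.csv"),
                   row.names = FALSE)
  lr <- gen_lr_module(n_simple = 40, n_complex = 10,
                      gene_pool = colnames(expr$counts$values),
                      seed = seed + 4L)
  utils::write.csv(lr$interactions, file.path(dir, "lr_interactions.csv"),
                   row.names = FALSE)
  utils::write.csv(lr$complexes, file.path(dir, "lr_complexes.csv"),
                   row.names = FALSE)
  invisible(list(expression = expr, abundance = ab, peaks = ps,
                 drugs = drugs, lr = lr))
}
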