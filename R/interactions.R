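#' Load a ligand-receptor interaction database
#'
#' Reads CellPhoneDB-style tables: an interactions CSV with columns
#' `partner_a`, `partner_b` (plus optional annotation columns such as
#' `is_proxy`, marking ligand proxies - biosynthetic enzymes or transporters
#' standing in for non-gene-encoded ligands), and a complexes CSV with
#' columns `complex_name`, `member_1`, `member_2`, ... (empty members
#' allowed). A partner is a complex when its name appears in the complex
#' table (the explicit `complex:NAME` prefix is also accepted); otherwise it
#' is a protein id resolved to a gene symbol through `gene_map` (identity by
#' default). Interactions referencing undefined complexes are rejected with
#' the offending names.
#'
#' @param interactions_csv path to the interaction table.
#' @param complexes_csv path to the complex table.
#' @param gene_map optional named character vector (protein id -> gene
#'   symbol) or a 2-column CSV path.
#' @return An object of class `lr_database`: list with `interactions`
#'   (data.frame), `complexes` (named list of member gene vectors) and
#'   `gene_map`.
#' @export
load_lr_database <- function(interactions_csv, complexes_csv,
                             gene_map = NULL) {
  inter <- utils::read.csv(interactions_csv, stringsAsFactors = FALSE)
  .assert(all(c("partner_a", "partner_b") %in% names(inter)),
          "interactions CSV needs partner_a and partner_b columns")
  comp_tab <- utils::read.csv(complexes_csv, stringsAsFactors = FALSE)
  if (nrow(comp_tab)) {
    .assert("complex_name" %in% names(comp_tab),
            "complexes CSV needs a complex_name column")
  }
  if (is.character(gene_map) && length(gene_map) == 1 &&
      file.exists(gene_map)) {
    gm <- utils::read.csv(gene_map, stringsAsFactors = FALSE)
    gene_map <- stats::setNames(gm[[2]], gm[[1]])
  }
  member_cols <- grep("^member_", names(comp_tab), value = TRUE)
  complexes <- list()
  for (i in seq_len(nrow(comp_tab))) {
    members <- unlist(comp_tab[i, member_cols], use.names = FALSE)
    members <- members[!is.na(members) & nzchar(members)]
    .assert(length(members) >= 1, "complex without members: ",
            comp_tab$complex_name[i])
    complexes[[comp_tab$complex_name[i]]] <- as.character(members)
  }
  strip <- function(x) sub("^complex:", "", x)
  flagged <- grepl("^complex:", c(inter$partner_a, inter$partner_b))
  referenced <- strip(c(inter$partner_a, inter$partner_b))[flagged]
  undefined <- setdiff(referenced, names(complexes))
  if (length(undefined)) {
    .validation_error("interaction references undefined complex(es): ",
                      paste(unique(undefined), collapse = ", "))
  }
  if (!"is_proxy" %in% names(inter)) inter$is_proxy <- FALSE
  structure(list(interactions = inter, complexes = complexes,
                 gene_map = gene_map),
            class = "lr_database")
}

#' @export
print.lr_database <- function(x, ...) {
  cat(sprintf("<lr_database> %d interactions, %d complexes\n",
              nrow(x$interactions), length(x$complexes)))
  invisible(x)
}

# Resolve one partner (gene, protein id, or complex name) to member genes.
.resolve_partner <- function(db, partner) {
  name <- sub("^complex:", "", partner)
  if (name %in% names(db$complexes)) {
    members <- db$complexes[[name]]
  } else {
    members <- partner
  }
  if (!is.null(db$gene_map)) {
    mapped <- db$gene_map[members]
    if (anyNA(mapped)) {
      .validation_error("unresolvable member(s) of partner ", partner, ": ",
                        paste(members[is.na(mapped)], collapse = ", "))
    }
    members <- unname(mapped)
  }
  members
}

#' Fraction of a state's cells expressing a gene
#'
#' The fraction of cells of `state` with nonzero expression; it depends only
#' on the zero pattern, so raw and normalized matrices agree. A gene absent
#' from the matrix yields 0 with a warning.
#'
#' @param norm a `norm_matrix` (or `count_matrix`).
#' @param labels named cell-state labels per row.
#' @param gene gene symbol.
#' @param state cell-state name.
#' @return Fraction in \[0, 1\].
#' @export
expressed_fraction <- function(norm, labels, gene, state) {
  v <- norm$values
  lab <- .align_labels(labels, rownames(v))
  rows <- lab == state
  .assert(any(rows), "state has no cells: ", state)
  if (!gene %in% colnames(v)) {
    warning("gene absent from matrix: ", gene)
    return(0)
  }
  mean(v[rows, gene] > 0)
}

# mean expression of each member gene within given rows; complex partner
# value is the limiting-subunit minimum (or mean) of member means.
.partner_value <- function(v, rows, genes, complex_rule) {
  missing <- setdiff(genes, colnames(v))
  if (length(missing)) {
    .validation_error("unresolvable member gene(s): ",
                      paste(missing, collapse = ", "))
  }
  means <- Matrix::colMeans(v[rows, genes, drop = FALSE])
  if (complex_rule == "min") min(means) else mean(means)
}

#' LR mean of an interaction between two states
#'
#' The partner value in a state is the mean normalized expression of the
#' partner gene over that state's cells, or - for a complex partner - the
#' minimum over the member-gene means (limiting subunit; set
#' `complex_rule = "mean"` for the average). The LR mean is the average of
#' the `partner_a` value in the sender state and the `partner_b` value in
#' the receiver state.
#'
#' @param norm a `norm_matrix`.
#' @param labels named cell-state labels per row.
#' @param db an [load_lr_database()] result.
#' @param interaction row index into `db$interactions`, or a list/row with
#'   `partner_a` and `partner_b`.
#' @param sender,receiver cell-state names.
#' @param complex_rule `"min"` (default) or `"mean"`.
#' @return The LR mean (non-negative on non-negative expression).
#' @export
lr_mean <- function(norm, labels, db, interaction, sender, receiver,
                    complex_rule = c("min", "mean")) {
  complex_rule <- match.arg(complex_rule)
  v <- norm$values
  lab <- .align_labels(labels, rownames(v))
  if (is.numeric(interaction)) {
    interaction <- db$interactions[interaction, ]
  }
  a_genes <- .resolve_partner(db, interaction$partner_a)
  b_genes <- .resolve_partner(db, interaction$partner_b)
  s_rows <- lab == sender
  r_rows <- lab == receiver
  .assert(any(s_rows), "no cells in sender state ", sender)
  .assert(any(r_rows), "no cells in receiver state ", receiver)
  (.partner_value(v, s_rows, a_genes, complex_rule) +
      .partner_value(v, r_rows, b_genes, complex_rule)) / 2
}

#' Label-permutation p value for an interaction
#'
#' Null distribution from shuffling cell-state labels across all cells and
#' recomputing the LR mean; `p` is the inclusive fraction of permuted LR
#' means at least the observed one. Degenerate cases get `p = 1`: fewer
#' than two distinct labels, a sender or receiver below `min_cells`, or a
#' partner with zero expression in its state. With `exhaustive = TRUE` and
#' exactly two label values, all label assignments are enumerated.
#'
#' @inheritParams lr_mean
#' @param n_perm permutations; default 1000.
#' @param seed RNG seed.
#' @param min_cells minimal cells per tested state; default 10 (set lower
#'   for toy fixtures).
#' @param exhaustive enumerate all two-state label assignments.
#' @return Numeric p with attributes `p_smoothed` and `lr_mean` (observed).
#' @export
lr_permutation_p <- function(norm, labels, db, interaction, sender, receiver,
                             n_perm = 1000, seed = NULL, min_cells = 10,
                             complex_rule = c("min", "mean"),
                             exhaustive = FALSE) {
  complex_rule <- match.arg(complex_rule)
  v <- norm$values
  lab <- .align_labels(labels, rownames(v))
  if (is.numeric(interaction)) interaction <- db$interactions[interaction, ]
  obs <- lr_mean(norm, labels, db, interaction, sender, receiver,
                 complex_rule)
  if (length(unique(lab)) < 2) {
    p <- 1; attr(p, "p_smoothed") <- 1; attr(p, "lr_mean") <- obs
    return(p)
  }
  a_genes <- .resolve_partner(db, interaction$partner_a)
  b_genes <- .resolve_partner(db, interaction$partner_b)
  s_rows <- lab == sender
  r_rows <- lab == receiver
  a_zero <- all(v[s_rows, intersect(a_genes, colnames(v)), drop = FALSE] == 0)
  b_zero <- all(v[r_rows, intersect(b_genes, colnames(v)), drop = FALSE] == 0)
  if (sum(s_rows) < min_cells || sum(r_rows) < min_cells ||
      a_zero || b_zero) {
    p <- 1; attr(p, "p_smoothed") <- 1; attr(p, "lr_mean") <- obs
    attr(p, "untestable") <- TRUE
    return(p)
  }
  stat <- function(permuted_lab) {
    sp <- permuted_lab == sender
    rp <- permuted_lab == receiver
    (.partner_value(v, sp, a_genes, complex_rule) +
        .partner_value(v, rp, b_genes, complex_rule)) / 2
  }
  if (exhaustive) {
    vals <- sort(unique(lab))
    .assert(length(vals) == 2, "exhaustive mode needs exactly 2 states")
    n1 <- sum(lab == vals[1]); n <- length(lab)
    idx <- utils::combn(n, n1)
    null_stats <- vapply(seq_len(ncol(idx)), function(j) {
      pl <- rep(vals[2], n); pl[idx[, j]] <- vals[1]
      stat(pl)
    }, numeric(1))
    n_used <- ncol(idx)
  } else {
    null_stats <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) stat(sample(lab)), numeric(1))
    })
    n_used <- n_perm
  }
  k <- sum(null_stats >= obs - 1e-12)
  p <- k / n_used
  attr(p, "p_smoothed") <- (k + 1) / (n_used + 1)
  attr(p, "lr_mean") <- obs
  p
}

#' Screen interactions among the states of a niche
#'
#' Evaluates every database interaction for every ordered (sender,
#' receiver) pair within `niche_states`. All member genes of `partner_a`
#' must be expressed in at least `min_frac` (default 10%) of sender cells,
#' and those of `partner_b` in the receiver. On top of that,
#' `mode = "statistical"` requires a label-permutation p below `p_max`,
#' while `mode = "deg"` requires at least one member gene to be
#' differentially expressed in the sender or receiver state (Welch t,
#' `p_adj < p_max`, `log2FC > deg_lfc_min`).
#'
#' @param norm a `norm_matrix`.
#' @param labels named cell-state labels per row.
#' @param db an [load_lr_database()] result.
#' @param niche_states character vector of the niche's states.
#' @param mode `"statistical"` or `"deg"`.
#' @param min_frac expression-fraction filter; default 0.1.
#' @param p_max significance gate; default 0.05.
#' @param deg_lfc_min DEG fold-change gate; default 0.1.
#' @param n_perm,seed,min_cells,complex_rule permutation controls.
#' @return A data.frame per (interaction, sender, receiver):
#'   `partner_a`, `partner_b`, `sender`, `receiver`, `lr_mean`,
#'   `frac_pass`, `p` (statistical mode), `deg_pass` (deg mode) and
#'   `selected`.
#' @export
niche_interaction_screen <- function(norm, labels, db, niche_states,
                                     mode = c("statistical", "deg"),
                                     min_frac = 0.1, p_max = 0.05,
                                     deg_lfc_min = 0.1, n_perm = 1000,
                                     seed = 0L, min_cells = 10,
                                     complex_rule = "min") {
  mode <- match.arg(mode)
  lab <- .align_labels(labels, rownames(norm$values))
  .assert(length(niche_states) >= 1, "empty niche state set")
  missing <- setdiff(niche_states, unique(lab))
  if (length(missing)) {
    .validation_error("niche state(s) absent from labels: ",
                      paste(missing, collapse = ", "))
  }
  deg_tabs <- NULL
  if (mode == "deg") {
    deg_tabs <- lapply(stats::setNames(niche_states, niche_states),
                       function(s) {
                         deg_t_test(norm, labels, s, p_adj_max = p_max,
                                    lfc_min = deg_lfc_min)
                       })
  }
  frac_of <- function(genes, state) {
    min(vapply(genes, function(g) {
      expressed_fraction(norm, labels, g, state)
    }, numeric(1)))
  }
  rows <- list()
  pairs <- expand.grid(sender = niche_states, receiver = niche_states,
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(db$interactions))) {
    inter <- db$interactions[i, ]
    a_genes <- .resolve_partner(db, inter$partner_a)
    b_genes <- .resolve_partner(db, inter$partner_b)
    for (j in seq_len(nrow(pairs))) {
      sender <- pairs$sender[j]; receiver <- pairs$receiver[j]
      fa <- suppressWarnings(frac_of(a_genes, sender))
      fb <- suppressWarnings(frac_of(b_genes, receiver))
      frac_pass <- fa >= min_frac && fb >= min_frac
      lrm <- lr_mean(norm, labels, db, inter, sender, receiver, complex_rule)
      p <- NA_real_
      deg_pass <- NA
      if (mode == "statistical") {
        if (frac_pass) {
          p <- as.numeric(lr_permutation_p(norm, labels, db, inter, sender,
                                           receiver, n_perm = n_perm,
                                           seed = seed + 7919L * i + j,
                                           min_cells = min_cells,
                                           complex_rule = complex_rule))
        }
        selected <- frac_pass && !is.na(p) && p < p_max
      } else {
        members_deg <- c(deg_tabs[[sender]]$deg[
          match(a_genes, deg_tabs[[sender]]$gene)],
          deg_tabs[[receiver]]$deg[
            match(b_genes, deg_tabs[[receiver]]$gene)])
        deg_pass <- any(members_deg, na.rm = TRUE)
        selected <- frac_pass && deg_pass
      }
      rows[[length(rows) + 1L]] <- data.frame(
        partner_a = inter$partner_a, partner_b = inter$partner_b,
        sender = sender, receiver = receiver, lr_mean = lrm,
        frac_pass = frac_pass, p = p, deg_pass = deg_pass,
        selected = selected)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
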