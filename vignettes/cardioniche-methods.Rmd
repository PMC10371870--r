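---
title: "Methods and design notes for cardioniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for cardioniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioniche)
```

# Scope

`cardioniche` packages the statistical machinery used to connect cell
states of the heart to drugs, tissue microenvironments and genetic traits:
drug-target scoring of single cells, knowledge-based and unsupervised
spatial niche analysis, GWAS SNP enrichment in cell-state open chromatin,
and a ligand–receptor screen. Upstream steps that have dedicated tools —
read mapping, ambient-RNA removal, doublet detection, dataset integration,
deconvolution model fitting, peak calling, LD expansion — are out of scope;
the package consumes their standard outputs (MatrixMarket counts, TSV
abundance tables, BED intervals, CSV drug and interaction tables).

# Models and procedures

## Drug-target scoring

A ChEMBL-export-like table is filtered to human, clinically approved
(`max_phase = 4`; 1–3 selects preclinical bioactive molecules) records, and
bioactivity is gated per target family at the pChEMBL equivalent of
family-specific potency cutoffs: 30 nM for kinases, 100 nM for GPCRs and
nuclear hormone receptors, 10 µM for ion channels and 1 µM otherwise,
via `pchembl_min = 9 − log10(cutoff_nM)` (so 100 nM ≡ 7.0). The comparison
is inclusive (`≥`), mirroring cutoffs stated as "≤ x nM", and is applied to
the best (maximum) pChEMBL per drug–target pair, since a pair with one
strong and one weak measurement is still an active interaction. Records
with missing pChEMBL are dropped when the activity gate is on and kept
otherwise.

Per-cell drug scores use either the plain mean of the normalized expression
of the drug's targets, or the binned-reference variant: genes are ranked by
global mean expression and cut into `n_bins = 25` equal-size bins, and each
set gene contributes `ctrl_per_gene = 50` control genes drawn uniformly
without replacement from its bin (set genes excluded; the draw falls back
to replacement with a warning when a bin is exhausted, which routinely
happens on small matrices — with `G` genes a bin holds about `G/25`
candidates). The score is the set mean minus the pooled control mean, so a
random set on exchangeable data is centred on zero. Both bin and control
counts follow the ecosystem convention for control-gene scoring and are
exposed as arguments.

Drugs specific to a cell state are found by a two-sided rank-sum test of
the state's scores against all other cells, with exact enumeration of all
`C(n, m)` splits when both sides have ≤ 8 members and a tie-corrected
normal approximation (no continuity correction) otherwise. The exact
two-sided p is the null mass of `|W − E[W]| ≥ |W_obs − E[W]|`, which equals
the doubled one-sided tail under tie-free symmetry. Flags require
`log2FC > 2` and BH-adjusted `p < 0.05`. Because binned-reference scores
can be negative, group means are clamped at zero before the pseudocounted
ratio `log2((m_in + ε)/(m_out + ε))`, `ε = 1e−9`; the clamp keeps the gate
monotone in the "higher in the state" direction instead of producing NaN.

## Differential expression and score correlation

`deg_t_test()` is a per-gene Welch t-test with BH correction; a gene with
zero variance on both sides is reported with `p = 1` (not testable under
the t model — this includes the corner case of two different constants).
`correlate_genes_with_score()` computes Pearson r per gene against a
per-spot score (for example the pan-neuronal cytoskeletal score over
`PRPH`, `NEFL`, `NEFM`, `NEFH`, shipped as `pan_neuronal_markers()`), with
p from the t transform; constant genes get `r = NA` and are excluded from
the correction.

## Knowledge-based spatial enrichment

For an annotated structure, every cell state gets an odds ratio of pooled
(abundance-weighted) in-structure versus out-structure proportions,
`OR = [p_in/(1−p_in)]/[p_out/(1−p_out)]`. Pooling weights spots by their
total abundance and is robust to low-abundance spots; the mean of per-spot
proportions is available via `per_spot_mean = TRUE` since the published
description does not fix this choice. Significance uses a chi-square test
on the 2×2 table of rounded summed abundances (state vs rest) × (in vs
out) with Yates correction — the default of the routine this analysis is
conventionally run through — and BH across states. The rounding makes the
table counts-like; with abundances in cells-per-spot the entries are
already on a count scale.

## Product-abundance niche calling

`call_product_niche()` multiplies the per-spot abundances of two states
(the activated-fibroblast × stressed-cardiomyocyte configuration is the
motivating case), selects spots with product strictly above 0.03, and
returns connected components of the spot-adjacency graph with strictly
more than 5 members. Adjacency links spots within 1.5 × the minimum
pairwise spacing, which yields the six hex neighbours on a Visium-style
offset grid (and includes diagonals on a square grid, √2 < 1.5); the
minimum spacing is always computed on the full slide so subsetting the
candidate spots cannot rescale the neighbourhood.

## Unsupervised niche discovery

The spot×state abundance matrix is factorized as `X ≈ WH` (non-negative,
Frobenius loss) once per rank in 5…14 — 95 factors in total. The solver
uses deterministic NNDSVD initialisation with multiplicative updates; in
addition, each rank is warm-started from the previous rank's solution
padded with small components, and the better of the two fits is kept.
Multiplicative updates never increase the objective, so the scan's
reconstruction error is non-increasing in the rank by construction. This
plain Frobenius NMF stands in for the Bayesian NMF of the original
deconvolution pipeline; factor loadings, not posterior uncertainties, are
what the downstream selection consumes.

Per factor, loadings are normalized to unit mean (so effect sizes are
comparable across ranks) and scored against a structure annotation with
Cohen's d (pooled SD; capped at ±1e6 when the pooled SD is zero with
unequal means, 0 when means are equal). The permutation p shuffles the
annotation over spots: `p = #{d* ≥ d_obs}/n_perm`, the literal inclusive
fraction (it can be 0); the exactly-valid smoothed estimate
`(k+1)/(n_perm+1)` is attached as an attribute. Selection follows the
published three-step rule: the **best-factor** is the significant factor
with the largest effect size, searched jointly across all ranks (a
per-rank variant exists behind `per_run = TRUE`); the chosen rank is the
smallest one containing at least two factors ("multiple" read as ≥ 2) with
`d > 0.5 × d_best`; those are the **fine-factors**. No significant factor
yields an empty selection, not an error.

## GWAS SNP enrichment

Peak counts are binarized (1 if any read), and a peak is open for a state
when detected in at least 5% of its barcodes (inclusive, "at least 5%").
The SNP proportion is the fraction of a trait's SNPs lying inside at least
one open peak (0-based half-open containment; multi-peak hits count once).
The null shuffles open/closed labels over the state's full peak set,
preserving the open count exactly in every draw; enumeration of all
subsets replaces sampling when `C(n_peaks, n_open) ≤ 10,000`. SNP input
defaults to 0-based single-base intervals for BED consistency, with a
`one_based` flag for conventional variant coordinates. BH runs over the
full trait×state grid by default (the published description does not state
the scope; per-trait scope is available).

## Ligand–receptor screen

The database format follows the CellPhoneDB convention: an interaction
table of partner pairs plus a complex table naming member proteins; ligand
proxies (biosynthetic enzymes or transporters standing in for
non-gene-encoded ligands) are ordinary partners carrying an `is_proxy`
flag. A complex partner's expression in a state is the minimum over member
means (limiting subunit; `complex_rule = "mean"` switches to the average),
and the LR mean is the average of the ligand-side value in the sender and
the receptor-side value in the receiver. The screen keeps interactions
whose members are all expressed in ≥ 10% of the relevant state's cells
and, in `statistical` mode, whose label-permutation p is below 0.05;
`deg` mode instead requires at least one member to be differentially
expressed (Welch t, BH p < 0.05, log2FC > 0.1). States with fewer than 10
cells (configurable) are considered untestable and get `p = 1`.

# Synthetic data: what it emulates and what it does not

The `gen_*` generators produce every input with planted ground truth:

* `gen_expression()` — negative-binomial counts with mean/dispersion
  parameterisation (dispersion 0.5, i.e. `size = 2`: realistic
  overdispersion without fitting), log-normal gene base means, log-normal
  per-cell depth (σ = 0.25), and per-state marker programs whose means are
  multiplied by `2^effect` (default effect 2).
* `gen_spots()` — a hex-offset grid (six equidistant neighbours per
  interior spot), regions tiling the grid in row bands, per-spot state
  abundances `total × Dirichlet(50 × mixture)` with log-normal totals
  (`meanlog = log(7)`, σ = 0.3: about seven nuclei per spot). The default
  layout plants a central compartment, a peripheral band and background
  myocardium; `stress_niche_regions()` plants a block where two stress
  states are jointly abundant while the background keeps their joint
  product far below the 0.03 call threshold.
* `gen_peaks_snps()` — 501-bp fixed-width non-overlapping peaks, per-state
  true open sets (a shared baseline fraction plus state-specific peaks),
  barcode-level detection at 0.4 (open) versus 0.01 (background), and
  trait SNPs whose *enrichment factor* multiplies the expected SNP
  proportion in the target state's open peaks relative to uniform
  placement; the targeted portion lands in peaks open specifically in that
  state so that enrichment does not leak into states sharing baseline
  peaks, and factor 1 reduces to uniform placement.
* `gen_drug_table()` — planted approved drugs whose targets are marker
  programs (pChEMBL one unit above the family threshold), competitor
  drugs that survive filtering with random targets, and decoys failing on
  bioactivity, organism or phase.
* `gen_lr_module()` — interaction/complex tables at the scale of a full
  curated module (hundreds of simple pairs, complexes of 2–3 members, a
  proxy-flagged fraction).

All generators accept a seed, restore the caller's RNG state, and
reproduce bit-identically for a given seed. They emulate the *statistical*
structure each stage assumes — overdispersion, depth variation, spatial
mixtures, state-specific accessibility — but not transcriptome-wide
co-expression, chromatin biology, LD structure, or segmentation noise, so
green tests demonstrate correctness of the statistics on their assumed
input model, not performance on real tissue.

# Numerical choices and degenerate inputs

* Strict versus inclusive thresholds follow the published wording
  everywhere: QC keeps cells with `> 200` genes and mito+ribo fraction
  `< 20%` (cells) / `< 5%` (nuclei); spots need `> 500` UMI and, the one
  genuinely ambiguous bound, `≥ 300` genes (the strict reading would make
  "300" a 301-gene rule; both are configurable). Open peaks use `≥ 5%`;
  niche clusters use `n > 5`; fine-factors use `d > 0.5 d_best`.
* Permutation p-values are inclusive fractions and can be 0; every
  stochastic routine takes a seed and exposes the smoothed estimate.
* Exact enumeration limits: rank-sum ≤ 8 per side; open-label subsets
  ≤ 10,000 combinations; mask permutations ≤ 5,000 combinations.
* Mito/ribo genes default to symbol prefixes `MT-`, `RPS`, `RPL`,
  overridable by an explicit list; duplicate gene symbols are suffixed
  `.1`, `.2` deterministically on read.
* Degenerate cases are defined rather than errors where a downstream scan
  would otherwise die: constant score vectors give `p = 1` and `lfc = 0`;
  zero-variance genes give `p = 1`; all-open peak sets give `p = 1`;
  zero-abundance spots are excluded from proportions with a warning.

# Problem sizes

The shipped tests run on deliberately small instances chosen to exercise
every rule while keeping the suite quick: expression fixtures of 300–600
cells × 200–400 genes, spot grids of 8×8 to 14×14, 40–120 peaks with
160–240 barcodes, 200 SNPs per trait, 200–1,000 permutations, and
calibration studies of 1,000 simulations × 200 permutations. The
acceptance script reruns the full pipeline-level quantities at these sizes
in well under a minute.

# Known limitations

* The Frobenius/NNDSVD NMF is a deterministic approximation of the
  Bayesian NMF used inside deconvolution pipelines; factor values are not
  comparable across implementations even when selections agree.
* The chi-square enrichment test treats rounded summed abundances as
  counts; with abundances far below one cell per spot the rounding
  degrades the test (use `per_spot_mean` proportions and larger pools).
* The rank-sum normal approximation is used for all but very small
  groups; for group sizes near the enumeration boundary with heavy ties
  the approximation is the standard tie-corrected one, not exact.
* The screen evaluates ordered sender–receiver pairs independently; it
  does not model spatial proximity of the states beyond the niche
  membership supplied by the caller.
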