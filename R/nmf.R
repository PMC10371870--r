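# Frobenius NMF with non-negative double SVD (NNDSVD) initialisation and
# multiplicative updates. Deterministic for a given input: the
# initialisation is SVD-based and zero entries are filled with the matrix
# mean, so no RNG is consumed (the seed is recorded for provenance).
.nndsvd_init <- function(X, k) {
  s <- svd(X, nu = k, nv = k)
  W <- matrix(0, nrow(X), k)
  H <- matrix(0, k, ncol(X))
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  H[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (k > 1) {
    for (j in 2:k) {
      u <- s$u[, j]; v <- s$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      n_up <- sqrt(sum(up^2)); n_vp <- sqrt(sum(vp^2))
      n_un <- sqrt(sum(un^2)); n_vn <- sqrt(sum(vn^2))
      if (n_up * n_vp >= n_un * n_vn) {
        sigma <- n_up * n_vp
        if (sigma > 0) {
          W[, j] <- sqrt(s$d[j] * sigma) * up / n_up
          H[j, ] <- sqrt(s$d[j] * sigma) * vp / n_vp
        }
      } else {
        sigma <- n_un * n_vn
        if (sigma > 0) {
          W[, j] <- sqrt(s$d[j] * sigma) * un / n_un
          H[j, ] <- sqrt(s$d[j] * sigma) * vn / n_vn
        }
      }
    }
  }
  fill <- mean(X)
  W[W <= 0] <- fill
  H[H <= 0] <- fill
  list(W = W, H = H)
}

.nmf_fit <- function(X, k, max_iter = 500, tol = 1e-7, init = NULL) {
  if (is.null(init)) init <- .nndsvd_init(X, k)
  W <- init$W; H <- init$H
  eps <- .Machine$double.eps
  err_prev <- Inf
  nx <- norm(X, "F")
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, X) / (crossprod(W, W) %*% H + eps))
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
    if (it %% 10 == 0 || it == max_iter) {
      err <- norm(X - W %*% H, "F") / max(nx, eps)
      if (abs(err_prev - err) < tol) break
      err_prev <- err
    }
  }
  list(W = W, H = H, rel_err = norm(X - W %*% H, "F") / max(nx, eps))
}

#' NMF scan over a range of factor counts
#'
#' Factorizes the spot-by-state abundance matrix `X ~ W H` (non-negative,
#' Frobenius loss, NNDSVD initialisation, multiplicative updates) once for
#' every rank in `n_fact_range`. The default range 5..14 yields 95 factors
#' in total.
#'
#' @param ab an [abundance_matrix()] (or plain non-negative matrix).
#' @param n_fact_range integer vector of ranks; default `5:14`.
#' @param seed recorded in each result for provenance (the fit itself is
#'   deterministic).
#' @param max_iter,tol optimizer controls.
#' @return A list of `nmf_result` objects, one per rank, each with
#'   `n_fact`, `W` (spot x factor), `H` (factor x state),
#'   `reconstruction_error` (relative Frobenius) and `seed`.
#' @export
nmf_scan <- function(ab, n_fact_range = 5:14, seed = 0L,
                     max_iter = 500, tol = 1e-7) {
  X <- if (inherits(ab, "abundance_matrix")) ab$abundance else as.matrix(ab)
  if (any(X < 0)) .validation_error("NMF input must be non-negative")
  kmax <- max(n_fact_range)
  if (kmax > min(dim(X))) {
    .validation_error("rank ", kmax, " exceeds matrix dimension ",
                      min(dim(X)))
  }
  prev <- NULL
  out <- list()
  for (k in sort(n_fact_range)) {
    fit <- .nmf_fit(X, k, max_iter = max_iter, tol = tol)
    if (!is.null(prev) && k > prev$k) {
      # warm start: grow the previous solution by small extra components;
      # multiplicative updates never increase the objective, so this fit
      # starts near the previous optimum and the scan error is
      # non-increasing in the rank. Keep whichever fit is better.
      pad <- k - prev$k
      fill <- mean(X) * 1e-2 + .Machine$double.eps
      init <- list(W = cbind(prev$W, matrix(fill, nrow(X), pad)),
                   H = rbind(prev$H, matrix(fill, pad, ncol(X))))
      warm <- .nmf_fit(X, k, max_iter = max_iter, tol = tol, init = init)
      if (warm$rel_err < fit$rel_err) fit <- warm
    }
    prev <- list(k = k, W = fit$W, H = fit$H)
    dimnames(fit$W) <- list(rownames(X), paste0("factor_", seq_len(k)))
    dimnames(fit$H) <- list(paste0("factor_", seq_len(k)), colnames(X))
    out[[length(out) + 1L]] <-
      structure(list(n_fact = k, W = fit$W, H = fit$H,
                     reconstruction_error = fit$rel_err, seed = seed),
                class = "nmf_result")
  }
  out
}

#' @export
print.nmf_result <- function(x, ...) {
  cat(sprintf("<nmf_result> n_fact = %d, relative error %.4g\n",
              x$n_fact, x$reconstruction_error))
  invisible(x)
}

#' Cohen's d effect size of factor loadings inside a structure
#'
#' `d = (mean_in - mean_out) / pooled SD`. When the pooled SD is zero the
#' result is 0 for equal means and is capped at +/- 1e6 otherwise. A
#' single-spot group falls back to the other group's SD with a warning.
#'
#' @param loadings numeric per-spot loadings.
#' @param mask logical in-structure indicator, same length.
#' @return Cohen's d.
#' @export
factor_effect_size <- function(loadings, mask) {
  .assert(length(loadings) == length(mask), "mask length mismatch")
  mask <- as.logical(mask)
  .assert(any(mask) && any(!mask), "both mask groups must be non-empty")
  x <- loadings[mask]; y <- loadings[!mask]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) {
    warning("single-spot group; using the other group's SD")
    s <- if (n1 >= 2) stats::sd(x) else stats::sd(y)
  } else {
    s <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
                (n1 + n2 - 2))
  }
  diff <- mean(x) - mean(y)
  if (s == 0) {
    if (diff == 0) return(0)
    return(sign(diff) * 1e6)
  }
  min(max(diff / s, -1e6), 1e6)
}

#' Permutation p value for a structure effect size
#'
#' Shuffles the in-structure annotation across spots and recomputes Cohen's
#' d, returning the inclusive fraction of permutations with `d* >= d_obs`
#' (so p can be 0). The smoothed estimate `(k + 1) / (n_perm + 1)` is
#' attached as attribute `"p_smoothed"`. When `exhaustive = TRUE` (or
#' `choose(n, m) <= exhaustive_limit` with `exhaustive = NULL`), all
#' distinct masks are enumerated instead.
#'
#' @param loadings numeric per-spot loadings.
#' @param mask logical in-structure indicator.
#' @param n_perm number of permutations; default 1000.
#' @param seed RNG seed.
#' @param exhaustive force (`TRUE`/`FALSE`) or auto-select (`NULL`)
#'   enumeration of all masks.
#' @param exhaustive_limit auto-enumeration cap on `choose(n, m)`.
#' @return Numeric p in \[0, 1\] with attribute `p_smoothed`.
#' @export
permutation_effect_p <- function(loadings, mask, n_perm = 1000, seed = NULL,
                                 exhaustive = NULL, exhaustive_limit = 5000) {
  mask <- as.logical(mask)
  .assert(n_perm >= 1, "n_perm must be >= 1")
  d_obs <- factor_effect_size(loadings, mask)
  n <- length(loadings); m <- sum(mask)
  if (is.null(exhaustive)) {
    exhaustive <- choose(n, m) <= exhaustive_limit
  }
  if (exhaustive) {
    idx <- utils::combn(n, m)
    d_null <- apply(idx, 2, function(i) {
      mk <- logical(n); mk[i] <- TRUE
      factor_effect_size(loadings, mk)
    })
    k <- sum(d_null >= d_obs - 1e-12)
    p <- k / ncol(idx)
    attr(p, "p_smoothed") <- (k + 1) / (ncol(idx) + 1)
    return(p)
  }
  d_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      factor_effect_size(loadings, sample(mask))
    }, numeric(1))
  })
  k <- sum(d_null >= d_obs - 1e-12)
  p <- k / n_perm
  attr(p, "p_smoothed") <- (k + 1) / (n_perm + 1)
  p
}

#' Best-factor / fine-factor selection across an NMF scan
#'
#' For every factor of every rank, loadings are normalized to unit mean (so
#' factors are comparable across ranks), the structure effect size
#' ([factor_effect_size()]) and its permutation p
#' ([permutation_effect_p()]) are computed, and then:
#'
#' 1. the **best-factor** is the significant factor (permutation
#'    `p < alpha`) with the largest effect size, searched jointly across all
#'    ranks;
#' 2. the chosen rank is the smallest `n_fact` whose run contains at least
#'    two factors with `d > proportion * d_best` (the **fine-factors**);
#' 3. the fine-factors of that run are returned as the refined
#'    microenvironments.
#'
#' With no significant factor the selection is empty (not an error).
#'
#' @param results list of `nmf_result` from [nmf_scan()].
#' @param mask logical in-structure indicator over spots.
#' @param alpha significance level on the permutation p; default 0.05.
#' @param proportion fine-factor fraction of the best effect size;
#'   default 0.5.
#' @param n_perm,seed permutation controls.
#' @param per_run logical; restrict the best-factor search to each run
#'   separately and return the per-run table only (variant mode).
#' @return An object of class `factor_selection`: list with `table` (one
#'   row per factor: `n_fact`, `factor`, `effect_size`, `perm_p`),
#'   `best` (row of the best factor or `NULL`), `chosen_n_fact` (or `NA`),
#'   and `fine_factors` (subset of `table`).
#' @export
select_factors <- function(results, mask, alpha = 0.05, proportion = 0.5,
                           n_perm = 1000, seed = 0L, per_run = FALSE) {
  mask <- as.logical(mask)
  rows <- list()
  for (res in results) {
    stopifnot(inherits(res, "nmf_result"))
    for (j in seq_len(res$n_fact)) {
      w <- res$W[, j]
      mu <- mean(w)
      if (mu > 0) w <- w / mu
      d <- factor_effect_size(w, mask)
      p <- permutation_effect_p(w, mask, n_perm = n_perm,
                                seed = seed + 1000L * res$n_fact + j,
                                exhaustive = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(n_fact = res$n_fact, factor = colnames(res$W)[j],
                   effect_size = d, perm_p = as.numeric(p))
    }
  }
  tab <- do.call(rbind, rows)
  if (per_run) {
    # variant mode: each run judged against its own best significant factor
    per <- lapply(split(tab, tab$n_fact), function(run) {
      sig <- run[run$perm_p < alpha, , drop = FALSE]
      if (nrow(sig) == 0) return(run[0, ])
      run[run$effect_size > proportion * max(sig$effect_size), , drop = FALSE]
    })
    return(structure(list(table = tab, per_run_fine = per,
                          best = NULL, chosen_n_fact = NA_integer_,
                          fine_factors = tab[0, ], per_run = TRUE),
                     class = "factor_selection"))
  }
  sig <- tab[tab$perm_p < alpha, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(structure(list(table = tab, best = NULL,
                          chosen_n_fact = NA_integer_,
                          fine_factors = tab[0, ],
                          note = "no factor reached significance"),
                     class = "factor_selection"))
  }
  best <- sig[which.max(sig$effect_size), , drop = FALSE]
  d_cut <- proportion * best$effect_size
  chosen <- NA_integer_
  fine <- tab[0, ]
  for (k in sort(unique(tab$n_fact))) {
    run <- tab[tab$n_fact == k & tab$effect_size > d_cut, , drop = FALSE]
    if (nrow(run) >= 2) {
      chosen <- k
      fine <- run
      break
    }
  }
  structure(list(table = tab, best = best, chosen_n_fact = chosen,
                 fine_factors = fine, per_run = per_run),
            class = "factor_selection")
}

#' @export
print.factor_selection <- function(x, ...) {
  if (is.null(x$best)) {
    cat("<factor_selection> empty (no significant factor)\n")
    return(invisible(x))
  }
  cat(sprintf("<factor_selection> best: n_fact %d %s (d = %.3f, p = %.4g)\n",
              x$best$n_fact, x$best$factor, x$best$effect_size,
              x$best$perm_p))
  cat(sprintf("  chosen n_fact = %s with %d fine-factor(s)\n",
              x$chosen_n_fact, nrow(x$fine_factors)))
  invisible(x)
}

#' Top cell states of an NMF factor
#'
#' Reports the states whose H weight, normalized to the factor's maximum,
#' exceeds `threshold` (display convention for dot plots of factor
#' composition).
#'
#' @param res an `nmf_result`.
#' @param factor factor column name or index.
#' @param threshold normalized-weight cutoff; default 0.4.
#' @return A data.frame of `state` and `norm_weight`, decreasing.
#' @export
factor_top_states <- function(res, factor, threshold = 0.4) {
  stopifnot(inherits(res, "nmf_result"))
  h <- res$H[factor, ]
  nw <- if (max(h) > 0) h / max(h) else h
  keep <- nw > threshold
  out <- data.frame(state = colnames(res$H)[keep],
                    norm_weight = as.numeric(nw[keep]), row.names = NULL)
  out[order(-out$norm_weight), , drop = FALSE]
}
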