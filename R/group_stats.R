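#' Two-sided Mann-Whitney U test for one TGM cell
#'
#' Compares the per-subject observed accuracies at one (train-time,
#' test-time) cell with per-subject null accuracies. Uses the exact U
#' distribution when both samples have at most 20 values and no ties, and
#' the normal approximation with tie correction otherwise. Degenerate
#' cells (zero rank variance) return `p = 1`.
#'
#' @param obs,null numeric vectors of per-subject accuracies; non-empty.
#' @return two-sided p-value in `(0, 1]`.
#' @export
mann_whitney_cell <- function(obs, null) {
  if (!length(obs) || !length(null)) stopf("both samples must be non-empty")
  p <- suppressWarnings(
    stats::wilcox.test(obs, null, alternative = "two.sided",
                       exact = (length(obs) <= 20 && length(null) <= 20),
                       correct = TRUE)$p.value
  )
  if (!is.finite(p)) p <- 1
  min(p, 1)
}

#' Benjamini-Hochberg step-up significance mask
#'
#' Sorts the p-values ascending, finds the largest `k` with
#' `p_(k) <= k q / m`, and rejects the `k` smallest. Plain step-up rule,
#' no adaptive variants; invariant to the input order.
#'
#' @param pvals numeric vector of p-values in `(0, 1]`.
#' @param q FDR level in `(0, 1)`.
#' @return logical rejection mask aligned with `pvals` (empty input gives
#'   an empty mask).
#' @export
bh_fdr <- function(pvals, q = 0.01) {
  if (!length(pvals)) return(logical(0))
  if (any(pvals <= 0 | pvals > 1)) stopf("p-values must lie in (0, 1]")
  if (q <= 0 || q >= 1) stopf("q must lie in (0, 1)")
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Mass-univariate group statistics over TGMs
#'
#' Runs [mann_whitney_cell()] at every TGM cell across subjects (observed
#' vs label-permutation-null accuracies) and corrects over all cells of
#' the matrix with [bh_fdr()]. Two-sided, so below-chance cells are
#' detectable.
#'
#' @param tgms list of per-subject `tgm` objects (one state pair).
#' @param null_tgms list of the matched per-subject null TGMs (same
#'   shapes; see [null_within_tgm()]).
#' @param q FDR level (default 0.01).
#' @return an object of class `stat_result`: `pvals` and logical `mask`
#'   matrices (train-time x test-time), `q`, `test_name`, `n_subjects`,
#'   `family_size`.
#' @export
mass_univariate <- function(tgms, null_tgms, q = 0.01) {
  if (!length(tgms) || length(tgms) != length(null_tgms)) {
    stopf("need matched observed and null TGM lists")
  }
  dims <- lapply(c(tgms, null_tgms), function(t) dim(t$scores))
  if (length(unique(vapply(dims, paste, collapse = "x", ""))) != 1L) {
    stopf("TGM shapes differ across subjects")
  }
  d <- dims[[1]]
  n_sub <- length(tgms)
  obs <- vapply(tgms, function(t) t$scores, matrix(0, d[1], d[2]))
  nul <- vapply(null_tgms, function(t) t$scores, matrix(0, d[1], d[2]))
  dim(obs) <- c(d[1] * d[2], n_sub)
  dim(nul) <- c(d[1] * d[2], n_sub)
  # vapply stacks cell-major: row index runs over cells, col over subjects
  obs <- t(obs)
  nul <- t(nul)
  pv <- vapply(seq_len(d[1] * d[2]),
               function(i) mann_whitney_cell(obs[, i], nul[, i]), 0)
  mask <- bh_fdr(pv, q)
  structure(
    list(pvals = matrix(pv, d[1], d[2]),
         mask = matrix(mask, d[1], d[2]),
         q = q, test_name = "mann-whitney-u.two-sided.permutation-null",
         n_subjects = n_sub, family_size = d[1] * d[2],
         train_times = tgms[[1]]$train_times,
         test_times = tgms[[1]]$test_times,
         train_state = tgms[[1]]$train_state,
         test_state = tgms[[1]]$test_state),
    class = "stat_result"
  )
}

#' One-sample fallback: Wilcoxon signed rank against chance
#'
#' Alternative second-sample-free test: per cell, a two-sided Wilcoxon
#' signed-rank test of the per-subject accuracies against 0.5.
#'
#' @param tgms list of per-subject `tgm` objects.
#' @param q FDR level.
#' @return a `stat_result`.
#' @export
mass_univariate_vs_chance <- function(tgms, q = 0.01) {
  d <- dim(tgms[[1]]$scores)
  n_sub <- length(tgms)
  obs <- vapply(tgms, function(t) t$scores, matrix(0, d[1], d[2]))
  dim(obs) <- c(d[1] * d[2], n_sub)
  obs <- t(obs)
  pv <- vapply(seq_len(d[1] * d[2]), function(i) {
    x <- obs[, i] - 0.5
    if (all(x == 0)) return(1)
    p <- suppressWarnings(stats::wilcox.test(x, exact = n_sub <= 20)$p.value)
    if (!is.finite(p)) 1 else min(p, 1)
  }, 0)
  mask <- bh_fdr(pv, q)
  structure(
    list(pvals = matrix(pv, d[1], d[2]), mask = matrix(mask, d[1], d[2]),
         q = q, test_name = "wilcoxon-signed-rank.vs-chance",
         n_subjects = n_sub, family_size = d[1] * d[2],
         train_times = tgms[[1]]$train_times,
         test_times = tgms[[1]]$test_times,
         train_state = tgms[[1]]$train_state,
         test_state = tgms[[1]]$test_state),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf(
    "<stat_result> %s -> %s: %d/%d cells significant at q = %g (%s, n = %d)\n",
    x$train_state, x$test_state, sum(x$mask), x$family_size, x$q,
    x$test_name, x$n_subjects))
  invisible(x)
}
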