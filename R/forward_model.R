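#' Ledoit-Wolf shrinkage covariance
#'
#' Maximum-likelihood covariance shrunk toward a scaled identity with the
#' analytically optimal intensity, which keeps per-timepoint covariance
#' estimates well conditioned when channels outnumber trials.
#'
#' @param X `n x p` data matrix (rows = trials).
#' @return list with `cov` (`p x p`) and the `shrinkage` weight in
#'   `[0, 1]`.
#' @export
ledoit_wolf <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / n
  mu <- sum(diag(S)) / p
  d2 <- sum((S - diag(mu, p))^2) / p
  b2_sum <- 0
  for (i in seq_len(n)) {
    xi <- Xc[i, ]
    b2_sum <- b2_sum + sum((tcrossprod(xi) - S)^2)
  }
  b2 <- min(b2_sum / (n^2 * p), d2)
  shrink <- if (d2 > 0) b2 / d2 else 1
  list(cov = shrink * diag(mu, p) + (1 - shrink) * S, shrinkage = shrink)
}

#' Backward-to-forward model (activation-pattern) transform
#'
#' Converts a discriminative weight vector `w` (the backward model, whose
#' entries are contaminated by noise-suppression weights) into the
#' corresponding activation pattern `a = Sigma w / (w' Sigma w)` -- the
#' single-filter case of the covariance-based transform -- which has the
#' units of the data and is interpretable as the scalp distribution of the
#' decoded signal per unit of latent-source variance.
#'
#' @param w channel weight vector.
#' @param sigma_x `channels x channels` training-data covariance at the
#'   same time point; symmetric positive semi-definite.
#' @return activation pattern, same length as `w`.
#' @export
haufe_transform <- function(w, sigma_x) {
  w <- as.numeric(w)
  if (!is.matrix(sigma_x) || nrow(sigma_x) != ncol(sigma_x)) {
    stopf("sigma_x must be a square matrix")
  }
  if (length(w) != nrow(sigma_x)) {
    stopf("dimension mismatch: length(w) = %d, dim(sigma_x) = %d",
          length(w), nrow(sigma_x))
  }
  if (max(abs(sigma_x - t(sigma_x))) > 1e-8 * max(1, max(abs(sigma_x)))) {
    stopf("sigma_x must be symmetric")
  }
  num <- drop(sigma_x %*% w)
  denom <- sum(w * num)
  if (!is.finite(denom) || denom <= 1e-300) {
    stopf("degenerate filter: w' Sigma w = 0")
  }
  num / denom
}

#' Map an activation pattern from standardized units back to uV
#'
#' Multiplies each channel by the training-set mean of its per-trial
#' standardization scales, reversing the initial standardization step so
#' topographies are reported in microvolts.
#'
#' @param pattern activation pattern in standardized units.
#' @param record per-channel scale summary: either the numeric vector of
#'   mean scales or a `fitted_decoder` carrying `scale_summary`.
#' @return pattern in uV.
#' @export
unstandardize_pattern <- function(pattern, record) {
  scales <- if (inherits(record, "fitted_decoder")) record$scale_summary
            else record
  if (is.null(scales)) stopf("no standardization record available")
  if (length(scales) != length(pattern)) {
    stopf("scale summary length does not match pattern")
  }
  pattern * as.numeric(scales)
}

#' Forward-model topography timecourse of a fitted decoder
#'
#' Applies [haufe_transform()] at every training time point, scales each
#' pattern by the class difference of decision values at that time point
#' (so the map depicts the modelled condition-mean difference rather than
#' an arbitrary per-unit-variance pattern), and reverses the
#' standardization to uV. The decision-value calibration makes the peak of
#' the recovered map comparable to the planted condition difference when
#' the classifier is consistent.
#'
#' @param decoder a [fit_decoder()] result with `compute_cov = TRUE`.
#' @param calibrate scale patterns by the decision-value class difference
#'   (default `TRUE`).
#' @param unstandardize map back to uV using the stored scale summary
#'   (default `TRUE`; requires the record).
#' @return an object of class `topography_map`: `patterns`
#'   (`channels x train-time`, uV), `times`, `state`, `subject`, `units`.
#' @export
pattern_timecourse <- function(decoder, calibrate = TRUE,
                               unstandardize = TRUE) {
  if (is.null(decoder$covs)) {
    stopf("decoder carries no covariances; refit with compute_cov = TRUE")
  }
  n_t <- length(decoder$train_times)
  n_ch <- ncol(decoder$W)
  pat <- matrix(0, n_ch, n_t)
  for (t in seq_len(n_t)) {
    a <- haufe_transform(decoder$W[t, ], decoder$covs[, , t])
    if (calibrate) a <- a * decoder$dval_diff[t]
    if (unstandardize) a <- unstandardize_pattern(a, decoder)
    pat[, t] <- a
  }
  structure(
    list(patterns = pat, times = decoder$train_times, state = decoder$state,
         subject = decoder$subject, channel_names = decoder$channel_names,
         layout = decoder$layout,
         units = if (unstandardize) "uV" else "standardized"),
    class = "topography_map"
  )
}

#' @export
print.topography_map <- function(x, ...) {
  cat(sprintf(
    "<topography_map> state %s, subject %s: %d channels x %d times (%s)\n",
    x$state, format(x$subject), nrow(x$patterns), ncol(x$patterns), x$units))
  invisible(x)
}

# Average topography maps (e.g. across CV folds or subjects).
average_topographies <- function(maps) {
  pat <- Reduce(`+`, lapply(maps, `[[`, "patterns")) / length(maps)
  out <- maps[[1]]
  out$patterns <- pat
  out
}
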