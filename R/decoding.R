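#' Classifier specification
#'
#' L2-regularized logistic regression in the sklearn parameterization:
#' minimize `sum_i log(1 + exp(-z_i (w.x_i + b))) + ||w||^2 / (2C)` with
#' `z_i = 2 y_i - 1` and an unpenalized intercept. `C = 1` is the standard
#' default for per-timepoint EEG decoding.
#'
#' @param C inverse regularization strength, `> 0`.
#' @param fit_intercept include an intercept term.
#' @param max_iter Newton iteration cap.
#' @param tol convergence tolerance on the gradient sup-norm.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(C = 1, fit_intercept = TRUE, max_iter = 100L,
                            tol = 1e-9) {
  if (C <= 0) stopf("C must be > 0")
  structure(list(C = C, fit_intercept = fit_intercept,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "classifier_spec")
}

log1pexp <- function(x) {
  # numerically stable log(1 + exp(x))
  out <- x
  small <- x < 33
  out[small] <- log1p(exp(pmin(x[small], 33)))
  out
}

#' Fit one per-timepoint logistic classifier
#'
#' Newton-Raphson minimization of the penalized logistic loss (see
#' [classifier_spec()]), with step halving on non-decrease. The penalty
#' keeps the Hessian positive definite even with more channels than
#' trials, so convergence is quadratic from any start.
#'
#' @param X `trials x channels` matrix of features at one time point.
#' @param y binary labels in `{0, 1}`, both classes present.
#' @param spec a [classifier_spec()].
#' @return list with weight vector `w`, intercept `b`, `converged`,
#'   `n_iter` and the final penalized loss `objective`.
#' @export
fit_timepoint <- function(X, y, spec = classifier_spec()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stopf("both classes must be present in y")
  if (!all(is.finite(X))) stopf("X must be finite")
  n <- nrow(X)
  p <- ncol(X)
  z <- 2 * y - 1
  lambda <- 1 / spec$C
  use_b <- isTRUE(spec$fit_intercept)
  w <- numeric(p)
  b <- 0
  obj <- function(w, b) {
    sum(log1pexp(-z * (drop(X %*% w) + b))) + lambda * sum(w^2) / 2
  }
  f <- obj(w, b)
  converged <- FALSE
  it <- 0L
  while (it < spec$max_iter) {
    it <- it + 1L
    m <- z * (drop(X %*% w) + b)
    s <- stats::plogis(-m)           # 1 - sigma(margin)
    grad_w <- -drop(crossprod(X, z * s)) + lambda * w
    grad_b <- if (use_b) -sum(z * s) else 0
    if (max(abs(c(grad_w, grad_b))) < spec$tol) {
      converged <- TRUE
      break
    }
    wt <- s * (1 - s)                # logistic variance weights
    wt <- pmax(wt, 1e-12)
    H_ww <- crossprod(X, X * wt) + diag(lambda, p)
    if (use_b) {
      H_wb <- drop(crossprod(X, wt))
      H <- rbind(cbind(H_ww, H_wb), c(H_wb, sum(wt)))
      step <- solve(H, c(grad_w, grad_b))
    } else {
      step <- c(solve(H_ww, grad_w), 0)
    }
    alpha <- 1
    repeat {
      w_new <- w - alpha * step[seq_len(p)]
      b_new <- b - alpha * step[p + 1]
      f_new <- obj(w_new, b_new)
      if (f_new <= f + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    w <- w_new
    b <- b_new
    f <- f_new
  }
  if (!converged) {
    # final gradient check with a looser, still-tight threshold
    m <- z * (drop(X %*% w) + b)
    s <- stats::plogis(-m)
    g <- max(abs(c(-drop(crossprod(X, z * s)) + lambda * w,
                   if (use_b) -sum(z * s) else 0)))
    if (g > 1e-5) {
      stopf("logistic fit did not converge: |grad| = %.3g after %d iterations",
            g, it)
    }
  }
  list(w = unname(w), b = unname(b), converged = TRUE, n_iter = it,
       objective = f)
}

# Decode-time trial conditioning: 25 Hz low-pass + per-trial
# standardization, skipped for steps already on the processing log.
condition_trials <- function(epochs, lowpass = 25) {
  if (!is.null(lowpass) && !any(grepl("lowpass", epochs$log))) {
    if (lowpass < epochs$sfreq / 2) {
      epochs <- lowpass_filter(epochs, lowpass)
    }
  }
  if (is.null(epochs$standardization)) {
    epochs <- standardize_trials(epochs)
  }
  epochs
}

#' Fit a per-timepoint decoder over a whole epoch set
#'
#' Fits one [fit_timepoint()] classifier per sample, and (optionally)
#' retains, per training time point, the Ledoit-Wolf-shrunk channel
#' covariance of the training data and the class difference of decision
#' values -- the ingredients of the forward-model transform. The
#' per-trial standardization scales are summarized by their per-channel
#' training-set mean for later uV recovery.
#'
#' @param epochs a conditioned, balanced `epoch_set`.
#' @param spec a [classifier_spec()].
#' @param compute_cov retain per-timepoint covariances (needed by
#'   [pattern_timecourse()]).
#' @return an object of class `fitted_decoder`.
#' @export
fit_decoder <- function(epochs, spec = classifier_spec(),
                        compute_cov = FALSE) {
  validate_epoch_set(epochs)
  d <- dim(epochs$data)
  n_t <- d[3]
  W <- matrix(0, n_t, d[2])
  b <- numeric(n_t)
  covs <- if (compute_cov) array(0, dim = c(d[2], d[2], n_t)) else NULL
  dval_diff <- numeric(n_t)
  y <- epochs$labels
  for (t in seq_len(n_t)) {
    X <- epochs$data[, , t, drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, ncol = d[2])
    fit <- fit_timepoint(X, y, spec)
    W[t, ] <- fit$w
    b[t] <- fit$b
    score <- drop(X %*% fit$w) + fit$b
    dval_diff[t] <- mean(score[y == 1L]) - mean(score[y == 0L])
    if (compute_cov) covs[, , t] <- ledoit_wolf(X)$cov
  }
  scale_summary <- if (!is.null(epochs$standardization) &&
                       identical(epochs$standardization$scope, "trial")) {
    colMeans(epochs$standardization$scale)
  } else {
    NULL
  }
  structure(
    list(W = W, b = b, train_times = epochs$times, covs = covs,
         dval_diff = dval_diff, scale_summary = scale_summary,
         state = epochs$state, subject = epochs$subject,
         channel_names = epochs$layout$names, layout = epochs$layout,
         spec = spec),
    class = "fitted_decoder"
  )
}

new_tgm <- function(scores, train_times, test_times, train_state,
                    test_state, subject, n_folds) {
  structure(
    list(scores = scores, train_times = train_times,
         test_times = test_times, train_state = train_state,
         test_state = test_state, subject = subject, n_folds = n_folds),
    class = "tgm"
  )
}

#' @export
print.tgm <- function(x, ...) {
  cat(sprintf(
    "<tgm> %s -> %s (subject %s, %d fold%s): %d x %d cells, mean accuracy %.3f\n",
    x$train_state, x$test_state, format(x$subject), x$n_folds,
    if (x$n_folds == 1) "" else "s", nrow(x$scores), ncol(x$scores),
    mean(x$scores)))
  invisible(x)
}

#' Score a fitted decoder on test epochs at every time pair
#'
#' `scores[i, j]` is the accuracy of the classifier trained at time `i`
#' applied to the test data at time `j` (fraction of correctly labelled
#' trials; a trial exactly on the decision boundary is called class 1).
#'
#' @param decoder a [fit_decoder()] result.
#' @param test an `epoch_set` with the same channels as the training set.
#' @return a `tgm` object (train-time x test-time accuracy matrix).
#' @export
temporal_generalization <- function(decoder, test) {
  validate_epoch_set(test)
  if (!identical(decoder$channel_names, test$layout$names)) {
    stopf("test channels do not match the decoder's training channels")
  }
  d <- dim(test$data)
  n <- d[1]
  n_test_t <- d[3]
  M <- matrix(aperm(test$data, c(1, 3, 2)), nrow = n * n_test_t) # (trial,time) x ch
  S <- M %*% t(decoder$W)
  S <- sweep(S, 2, decoder$b, "+")
  pred <- (S >= 0) * 1L
  correct <- pred == test$labels # labels recycle down the trial-fastest rows
  acc <- array(correct, dim = c(n, n_test_t, nrow(decoder$W)))
  scores <- t(colMeans(acc)) # train-time x test-time
  new_tgm(scores, decoder$train_times, test$times, decoder$state,
          test$state, test$subject, n_folds = 1L)
}

# Stratified fold assignment: within each class, a seeded shuffle split in
# half (sizes differing by at most one).
stratified_folds <- function(labels, seed) {
  assign_fold <- integer(length(labels))
  local_rng(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(labels == cls))
      half <- ceiling(length(idx) / 2)
      assign_fold[idx[seq_len(half)]] <- 1L
      assign_fold[idx[-seq_len(half)]] <- 2L
    }
  })
  assign_fold
}

#' Within-state temporal-generalization matrix (two-fold CV)
#'
#' Applies decode-time conditioning (25 Hz low-pass + per-trial
#' standardization), splits trials into two stratified folds, fits a
#' per-timepoint decoder on each fold and scores it on the other, and
#' averages the two accuracy matrices. Deterministic given `seed`.
#'
#' @param epochs a balanced `epoch_set` (equal class counts).
#' @param spec a [classifier_spec()].
#' @param seed RNG seed for the fold split.
#' @param lowpass decode-time low-pass edge in Hz, or `NULL` to skip.
#' @param keep_decoders also return the two fold decoders (with
#'   covariances) for forward-model use.
#' @return a `tgm`; if `keep_decoders`, with a `decoders` attribute.
#' @export
within_state_tgm <- function(epochs, spec = classifier_spec(), seed = 1L,
                             lowpass = 25, keep_decoders = FALSE) {
  validate_epoch_set(epochs)
  n0 <- sum(epochs$labels == 0L)
  n1 <- sum(epochs$labels == 1L)
  if (n0 != n1) stopf("epochs must be balanced (got %d vs %d)", n0, n1)
  if (min(n0, n1) < 2L) stopf("need at least 2 trials per class")
  epochs <- condition_trials(epochs, lowpass)
  folds <- stratified_folds(epochs$labels, seed)
  score_sum <- NULL
  decoders <- list()
  for (k in 1:2) {
    train <- subset_trials(epochs, folds != k)
    test <- subset_trials(epochs, folds == k)
    dec <- fit_decoder(train, spec, compute_cov = keep_decoders)
    tg <- temporal_generalization(dec, test)
    score_sum <- if (is.null(score_sum)) tg$scores else score_sum + tg$scores
    if (keep_decoders) decoders[[k]] <- dec
  }
  out <- new_tgm(score_sum / 2, epochs$times, epochs$times, epochs$state,
                 epochs$state, epochs$subject, n_folds = 2L)
  if (keep_decoders) attr(out, "decoders") <- decoders
  out
}

#' Cross-state temporal-generalization matrix
#'
#' Fits the decoder on all balanced trials of the training state and
#' scores it on all balanced trials of the (disjoint) test state; no
#' cross-validation is needed because no trial appears in both sets. Both
#' sets receive the same decode-time conditioning, with test-trial
#' standardization computed per test trial (self-contained, no leakage).
#'
#' @param train,test balanced `epoch_set`s from two different states of
#'   the same subject.
#' @inheritParams within_state_tgm
#' @param keep_decoder also return the fitted decoder (with covariances).
#' @return a `tgm`; if `keep_decoder`, with a `decoder` attribute.
#' @export
cross_state_tgm <- function(train, test, spec = classifier_spec(),
                            lowpass = 25, keep_decoder = FALSE) {
  if (identical(train$state, test$state)) {
    stopf("train and test states are identical; use within_state_tgm()")
  }
  train <- condition_trials(train, lowpass)
  test <- condition_trials(test, lowpass)
  dec <- fit_decoder(train, spec, compute_cov = keep_decoder)
  out <- temporal_generalization(dec, test)
  out$n_folds <- 1L
  if (keep_decoder) attr(out, "decoder") <- dec
  out
}

#' Null (label-permutation) counterpart of a TGM
#'
#' Re-runs the identical decoding with condition labels permuted within
#' the subject (training labels, for cross-state transfer), providing the
#' per-subject null sample used by [mass_univariate()].
#'
#' @param epochs,train,test as in [within_state_tgm()] /
#'   [cross_state_tgm()].
#' @param spec a [classifier_spec()].
#' @param seed seed for the permutation (and fold split).
#' @param lowpass decode-time low-pass edge in Hz, or `NULL`.
#' @return a `tgm`.
#' @export
null_within_tgm <- function(epochs, spec = classifier_spec(), seed = 1L,
                            lowpass = 25) {
  epochs$labels <- local_rng(derive_seed(seed, "permute"),
                             sample(epochs$labels))
  within_state_tgm(epochs, spec, seed = seed, lowpass = lowpass)
}

#' @rdname null_within_tgm
#' @export
null_cross_tgm <- function(train, test, spec = classifier_spec(), seed = 1L,
                           lowpass = 25) {
  train$labels <- local_rng(derive_seed(seed, "permute"),
                            sample(train$labels))
  cross_state_tgm(train, test, spec, lowpass = lowpass)
}

#' Mean accuracy over a peak time window
#'
#' Averages TGM cells whose train and test times both lie in the closed
#' `window` (the conventional summary window is 0.25-0.40 s).
#'
#' @param tgm a `tgm`.
#' @param window `(lo, hi)` in s.
#' @return scalar mean accuracy.
#' @export
peak_window_summary <- function(tgm, window = c(0.25, 0.40)) {
  ti <- tgm$train_times >= window[1] & tgm$train_times <= window[2]
  tj <- tgm$test_times >= window[1] & tgm$test_times <= window[2]
  if (!any(ti) || !any(tj)) stopf("window contains no TGM cells")
  mean(tgm$scores[ti, tj, drop = FALSE])
}
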