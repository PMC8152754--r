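# Shared fixture builders: everything is generated in code, no files.

# Small simulation config at decode-time resolution (62.5 Hz), cheap enough
# for unit tests. States/effects/noise overridable.
quick_cfg <- function(n_subjects = 2, states = c("N2", "N3"),
                      n_channels = 8, n_epochs = 30, amplitude = 12,
                      shared_states = c("N2", "N3"), seed = 1,
                      subject_variability = list(amp_sdlog = 0.2,
                                                 center_sd = 0.03),
                      sfreq = 62.5, epoch_window = c(-0.24, 1.04), ...) {
  sim_config(
    n_subjects = n_subjects, states = states,
    n_epochs_per_condition = n_epochs, sfreq = sfreq,
    epoch_window = epoch_window, layout = channel_layout(n_channels),
    effects = list(VOICE = effect_spec(amplitude = amplitude,
                                       shared_states = shared_states)),
    subject_variability = subject_variability, seed = as.integer(seed), ...
  )
}

# Hand-built epoch set from an explicit array (defaults to white noise).
toy_epochs <- function(n_trials = 8, n_channels = 3, n_samples = 20,
                       sfreq = 50, t0 = 0, labels = NULL, data = NULL,
                       state = "N2", subject = 1, seed = 1) {
  if (is.null(data)) {
    data <- vigildecode:::local_rng(seed, {
      array(stats::rnorm(n_trials * n_channels * n_samples),
            dim = c(n_trials, n_channels, n_samples))
    })
  }
  if (is.null(labels)) labels <- rep(c(0L, 1L), length.out = n_trials)
  times <- t0 + (seq_len(n_samples) - 1) / sfreq
  epoch_set(data, times, labels, state, subject, sfreq,
            channel_layout(n_channels))
}

# Independent penalized-logistic oracle: generic BFGS on the explicit loss.
logistic_oracle <- function(X, y, C = 1) {
  z <- 2 * y - 1
  p <- ncol(X)
  fn <- function(th) {
    w <- th[seq_len(p)]
    b <- th[p + 1]
    sum(log1p(exp(pmin(-z * (drop(X %*% w) + b), 700)))) + sum(w^2) / (2 * C)
  }
  fit <- stats::optim(rep(0, p + 1), fn, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 2000))
  list(w = fit$par[seq_len(p)], b = fit$par[p + 1], value = fit$value)
}

# Exhaustive two-sided Mann-Whitney oracle for small samples (no ties
# assumed): enumerates all C(n+m, n) group assignments of the pooled ranks.
mw_exact_oracle <- function(obs, null) {
  n <- length(obs)
  pooled <- c(obs, null)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(length(pooled), n)
  u_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n * (n + 1) / 2
  })
  mu <- n * length(null) / 2
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
  min(1, p)
}

# By-hand BH step-up mask.
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- suppressWarnings(max(which(ps <= seq_len(m) * q / m + 1e-12)))
  mask <- rep(FALSE, m)
  if (is.finite(k)) mask[ord[seq_len(k)]] <- TRUE
  mask
}

# Fold-averaged topography from the decoders kept on a within-state TGM.
average_topographies_for_test <- function(decoders) {
  vigildecode:::average_topographies(lapply(decoders, pattern_timecourse))
}
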