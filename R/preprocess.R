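#' Preprocessing parameters
#'
#' The trial-conditioning chain applied before decoding, in this fixed
#' order: band-pass -> crop -> decimate -> balance, with the 25 Hz low-pass
#' and per-trial standardization applied at decode time (see
#' [within_state_tgm()]).
#'
#' @param bandpass numeric `(low, high)` FIR band edges in Hz.
#' @param crop_window `(lo, hi)` analysis window in s, closed on both ends.
#' @param decim integer decimation factor.
#' @param lowpass decode-time low-pass edge in Hz (`NULL` to skip).
#' @param n_balance target trials per condition for balanced subsampling.
#' @param seed RNG seed for the balancing draw.
#' @return an object of class `preprocessing_params`.
#' @export
preprocessing_params <- function(bandpass = c(1, 20),
                                 crop_window = c(-0.2, 1.0),
                                 decim = 4L,
                                 lowpass = 25,
                                 n_balance = 100L,
                                 seed = 1L) {
  if (decim < 1) stopf("decim must be >= 1")
  if (n_balance < 2) stopf("n_balance must be >= 2")
  structure(
    list(bandpass = bandpass, crop_window = crop_window,
         decim = as.integer(decim), lowpass = lowpass,
         n_balance = as.integer(n_balance), seed = as.integer(seed)),
    class = "preprocessing_params"
  )
}

# Windowed-sinc (Hamming) FIR design via signal::fir1. Order targets a
# transition bandwidth of 25% of the (lower) edge frequency, floored at
# 2 Hz, and is capped at a third of the epoch length so the compensated
# group delay stays well inside the epoch.
design_fir <- function(sfreq, low = NULL, high = NULL, n_samples,
                       order = NULL) {
  nyq <- sfreq / 2
  edges <- c(low, high)
  if (any(edges <= 0) || any(edges >= nyq)) {
    stopf("filter edges must lie strictly between 0 and the Nyquist (%g Hz)",
          nyq)
  }
  if (!is.null(low) && !is.null(high) && low >= high) {
    stopf("band is inverted: low >= high")
  }
  if (is.null(order)) {
    trans <- max(0.25 * min(edges), 2)
    order <- ceiling(3.3 * sfreq / trans)
    order <- min(order, max(6, 2 * ((n_samples - 1) %/% 6)))
  }
  order <- 2 * ceiling(order / 2) # even order -> integer group delay
  type <- if (is.null(low)) "low" else if (is.null(high)) "high" else "pass"
  as.numeric(signal::fir1(order, edges / nyq, type))
}

# Apply a symmetric odd-length FIR to every (trial, channel) series by FFT
# convolution with group-delay compensation (exactly zero-phase for a
# linear-phase kernel). Vectorized across the whole epoch array.
fir_apply <- function(data, h) {
  d <- dim(data)
  n_t <- d[3]
  delay <- (length(h) - 1L) %/% 2L
  nfft <- stats::nextn(n_t + length(h) - 1L, 2)
  sig <- matrix(aperm(data, c(3, 1, 2)), nrow = n_t) # samples x series
  pad <- matrix(0, nfft, ncol(sig))
  pad[seq_len(n_t), ] <- sig
  hf <- stats::fft(c(h, rep(0, nfft - length(h))))
  out <- Re(stats::mvfft(stats::mvfft(pad) * hf, inverse = TRUE)) / nfft
  out <- out[delay + seq_len(n_t), , drop = FALSE]
  aperm(array(out, dim = c(n_t, d[1], d[2])), c(2, 3, 1))
}

#' Zero-phase FIR band-pass filter
#'
#' Filters every (trial, channel) time series with a windowed-sinc FIR,
#' compensating the linear-phase group delay. Shape is unchanged; edge
#' segments (half the kernel length) should be discarded by a subsequent
#' [crop_epochs()], mirroring the segment-filter-recrop order of the
#' standard pipeline.
#'
#' @param epochs an `epoch_set`.
#' @param low,high band edges in Hz (`low = NULL` for a pure low-pass,
#'   `high = NULL` for a pure high-pass).
#' @param order optional FIR order override.
#' @return the filtered `epoch_set`.
#' @export
bandpass_filter <- function(epochs, low = 1, high = 20, order = NULL) {
  validate_epoch_set(epochs)
  h <- design_fir(epochs$sfreq, low, high, n_samples(epochs), order)
  epochs$data <- fir_apply(epochs$data, h)
  append_log(epochs, sprintf("bandpass(%s-%s Hz, %d taps)",
                             low %||% 0, high %||% "nyq", length(h)))
}

#' Decode-time low-pass filter
#' @rdname bandpass_filter
#' @export
lowpass_filter <- function(epochs, high = 25, order = NULL) {
  validate_epoch_set(epochs)
  h <- design_fir(epochs$sfreq, low = NULL, high = high,
                  n_samples(epochs), order)
  epochs$data <- fir_apply(epochs$data, h)
  append_log(epochs, sprintf("lowpass(%g Hz, %d taps)", high, length(h)))
}

#' Crop an epoch set to an analysis window
#'
#' Retains the samples whose latency lies in the closed interval
#' `[window[1], window[2]]` (both endpoint samples included).
#'
#' @param epochs an `epoch_set`.
#' @param window `(lo, hi)` in s.
#' @return the cropped `epoch_set`.
#' @export
crop_epochs <- function(epochs, window = c(-0.2, 1.0)) {
  validate_epoch_set(epochs)
  eps <- 1e-6 / epochs$sfreq
  keep <- epochs$times >= window[1] - eps & epochs$times <= window[2] + eps
  if (!any(keep)) stopf("crop window contains no samples")
  epochs$data <- epochs$data[, , keep, drop = FALSE]
  epochs$times <- epochs$times[keep]
  append_log(epochs, sprintf("crop(%g..%g s)", window[1], window[2]))
}

#' Decimate an epoch set
#'
#' Keeps every `factor`-th sample starting at the first; the sampling rate
#' is divided by `factor`. Plain sample picking: the preceding band-pass
#' (well below the new Nyquist) acts as the anti-alias filter, and a
#' warning is raised if no such filtering is on record.
#'
#' @param epochs an `epoch_set`.
#' @param factor integer `>= 1`.
#' @return the decimated `epoch_set`.
#' @export
decimate_epochs <- function(epochs, factor = 4L) {
  validate_epoch_set(epochs)
  if (factor < 1) stopf("decimation factor must be >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(epochs)
  if (!any(grepl("bandpass|lowpass", epochs$log))) {
    warning("decimating without a preceding low-pass on record",
            call. = FALSE)
  }
  keep <- seq(1L, n_samples(epochs), by = factor)
  epochs$data <- epochs$data[, , keep, drop = FALSE]
  epochs$times <- epochs$times[keep]
  epochs$sfreq <- epochs$sfreq / factor
  append_log(epochs, sprintf("decimate(%d)", factor))
}

#' Per-trial standardization
#'
#' Removes the mean and scales to unit variance every (trial, channel) time
#' series, using the population SD (divide by N). The per-trial-per-channel
#' `(mean, scale)` pairs are stored on the returned object so the
#' transformation is exactly invertible ([unstandardize_trials()]) and so
#' forward-model patterns can be mapped back to uV. A zero-variance series
#' keeps scale 1 (mean still removed) and is flagged.
#'
#' @param epochs an `epoch_set`.
#' @param scope `"trial"` (default; self-contained per trial) or
#'   `"timepoint"` (mean/SD across epochs per channel-timepoint).
#' @return the standardized `epoch_set` with a `standardization` record.
#' @export
standardize_trials <- function(epochs, scope = c("trial", "timepoint")) {
  validate_epoch_set(epochs)
  scope <- match.arg(scope)
  d <- dim(epochs$data)
  if (scope == "timepoint") {
    mu <- apply(epochs$data, c(2, 3), mean)
    sd_ <- sqrt(apply(epochs$data, c(2, 3), function(v) mean(v^2) - mean(v)^2))
    flagged <- sd_ == 0
    sd_[flagged] <- 1
    for (tr in seq_len(d[1])) {
      epochs$data[tr, , ] <- (epochs$data[tr, , ] - mu) / sd_
    }
    epochs$standardization <- list(scope = scope, mean = mu, scale = sd_,
                                   flagged = flagged)
  } else {
    mu <- apply(epochs$data, c(1, 2), mean)
    sd_ <- sqrt(apply(epochs$data, c(1, 2), function(v) mean(v^2) - mean(v)^2))
    flagged <- sd_ == 0
    sd_[flagged] <- 1
    epochs$data <- (epochs$data - as.vector(mu)) / as.vector(sd_)
    epochs$standardization <- list(scope = scope, mean = mu, scale = sd_,
                                   flagged = flagged)
  }
  if (any(flagged)) {
    message(sum(flagged), " zero-variance series: scale kept at 1")
  }
  append_log(epochs, sprintf("standardize(%s)", scope))
}

#' Invert a per-trial standardization
#'
#' @param epochs an `epoch_set` carrying a `standardization` record with
#'   `scope = "trial"`.
#' @return the `epoch_set` in original units; the record is dropped.
#' @export
unstandardize_trials <- function(epochs) {
  rec <- epochs$standardization
  if (is.null(rec)) stopf("no standardization record present")
  if (identical(rec$scope, "timepoint")) {
    for (tr in seq_len(n_trials(epochs))) {
      epochs$data[tr, , ] <- epochs$data[tr, , ] * rec$scale + rec$mean
    }
  } else {
    epochs$data <- epochs$data * as.vector(rec$scale) + as.vector(rec$mean)
  }
  epochs$standardization <- NULL
  append_log(epochs, "unstandardize")
}

#' Balanced subsampling of epochs
#'
#' Randomly samples, without replacement, `min(n, available)` trials per
#' condition. If either condition has fewer than `n` trials, both are
#' capped at the smaller count so the classes stay exactly balanced and
#' chance accuracy stays at 50%. Deterministic given `seed`.
#'
#' @param epochs an `epoch_set`.
#' @param n target trials per condition (default 100).
#' @param seed RNG seed for the draw.
#' @return the subsampled `epoch_set` (trials in original relative order).
#' @export
balance_epochs <- function(epochs, n = 100L, seed = 1L) {
  validate_epoch_set(epochs)
  idx0 <- which(epochs$labels == 0L)
  idx1 <- which(epochs$labels == 1L)
  if (!length(idx0) || !length(idx1)) {
    stopf("both conditions need at least one trial")
  }
  k <- min(n, length(idx0), length(idx1))
  picked <- local_rng(seed, {
    c(sample(idx0, k), sample(idx1, k))
  })
  out <- subset_trials(epochs, sort(picked))
  append_log(out, sprintf("balance(%d/condition, seed=%d)", k, seed))
}

#' Run the fixed preprocessing chain
#'
#' Applies, in order: band-pass -> crop -> decimate -> balance. The 25 Hz
#' low-pass and standardization belong to the decode stage and are applied
#' by the decoding functions.
#'
#' @param epochs a raw `epoch_set`.
#' @param params a [preprocessing_params()].
#' @return the conditioned `epoch_set`.
#' @export
preprocess <- function(epochs, params = preprocessing_params()) {
  epochs <- bandpass_filter(epochs, params$bandpass[1], params$bandpass[2])
  epochs <- crop_epochs(epochs, params$crop_window)
  epochs <- decimate_epochs(epochs, params$decim)
  balance_epochs(epochs, params$n_balance, params$seed)
}
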