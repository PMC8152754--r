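#' Epoched EEG container
#'
#' One subject-state block of epoched EEG: a `trials x channels x samples`
#' numeric array in microvolts, per-trial binary condition labels, a time
#' axis in seconds relative to stimulus onset, and acquisition metadata.
#'
#' @param data numeric array, `trials x channels x samples`, in uV.
#' @param times numeric vector of per-sample latencies (s), strictly
#'   increasing at spacing `1/sfreq`.
#' @param labels integer vector of per-trial condition codes in `{0, 1}`.
#' @param state vigilance-state label (e.g. `"WAKE"`, `"N2"`).
#' @param subject subject identifier.
#' @param sfreq sampling frequency in Hz.
#' @param layout a [channel_layout()].
#' @param standardization optional per-trial-per-channel `(mean, scale)`
#'   record written by [standardize_trials()].
#' @param log character vector of processing steps already applied.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, labels, state, subject, sfreq, layout,
                      standardization = NULL, log = character()) {
  x <- structure(
    list(data = data, times = as.numeric(times),
         labels = as.integer(labels), state = state, subject = subject,
         sfreq = as.numeric(sfreq), layout = layout,
         standardization = standardization, log = log),
    class = "epoch_set"
  )
  validate_epoch_set(x)
}

validate_epoch_set <- function(x) {
  d <- dim(x$data)
  if (length(d) != 3L) stopf("data must be a trials x channels x samples array")
  if (!all(is.finite(x$data))) stopf("data must be finite")
  if (length(x$times) != d[3]) stopf("length(times) must equal n samples")
  if (length(x$labels) != d[1]) stopf("length(labels) must equal n trials")
  if (!all(x$labels %in% c(0L, 1L))) stopf("labels must be 0/1")
  if (d[2] != x$layout$n_channels) stopf("channel axis does not match layout")
  dt <- diff(x$times)
  if (length(dt) && (any(dt <= 0) ||
      max(abs(dt - 1 / x$sfreq)) > 1e-6 / x$sfreq)) {
    stopf("times must increase at spacing 1/sfreq")
  }
  invisible(x)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> subject %s, state %s: %d trials x %d channels x %d samples @ %g Hz, t = [%.3f, %.3f] s\n",
    format(x$subject), x$state, d[1], d[2], d[3], x$sfreq,
    x$times[1], x$times[d[3]]))
  cat(sprintf("  labels: %d x class 0, %d x class 1; steps: %s\n",
              sum(x$labels == 0L), sum(x$labels == 1L),
              if (length(x$log)) paste(x$log, collapse = " -> ") else "(raw)"))
  invisible(x)
}

n_trials <- function(x) dim(x$data)[1]
n_channels_of <- function(x) dim(x$data)[2]
n_samples <- function(x) dim(x$data)[3]

# Subset trials, keeping labels and standardization record aligned.
subset_trials <- function(x, idx) {
  x$data <- x$data[idx, , , drop = FALSE]
  x$labels <- x$labels[idx]
  if (!is.null(x$standardization)) {
    x$standardization$mean <- x$standardization$mean[idx, , drop = FALSE]
    x$standardization$scale <- x$standardization$scale[idx, , drop = FALSE]
    x$standardization$flagged <- x$standardization$flagged[idx, , drop = FALSE]
  }
  x
}

append_log <- function(x, entry) {
  x$log <- c(x$log, entry)
  x
}

#' Write an epoch set to a portable directory bundle
#'
#' The bundle is a directory holding `meta.json` (labels, times, channel
#' names and positions, sampling rate, units, processing log) and
#' `data.csv`, the array flattened to one row per (trial, channel) pair
#' with one column per sample. It round-trips through [read_epochs()].
#'
#' @param x an `epoch_set`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(x, path) {
  validate_epoch_set(x)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(x$data)
  meta <- list(
    format = "vigildecode-epochs-v1",
    n_trials = d[1], n_channels = d[2], n_samples = d[3],
    times = x$times, labels = x$labels, state = x$state,
    subject = x$subject, sfreq = x$sfreq, units = "uV",
    channel_names = x$layout$names,
    channel_positions = unname(x$layout$positions),
    log = x$log
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  flat <- matrix(aperm(x$data, c(3, 2, 1)), nrow = d[1] * d[2], byrow = TRUE)
  data.table::fwrite(data.table::as.data.table(flat),
                     file.path(path, "data.csv"), col.names = FALSE)
  invisible(path)
}

#' Read an epoch set written by [write_epochs()]
#'
#' @param path bundle directory.
#' @return an `epoch_set`.
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$format, "vigildecode-epochs-v1")) {
    stopf("not a vigildecode epochs bundle: %s", path)
  }
  flat <- as.matrix(data.table::fread(file.path(path, "data.csv"),
                                      header = FALSE))
  d <- c(meta$n_trials, meta$n_channels, meta$n_samples)
  data <- aperm(array(t(flat), dim = c(d[3], d[2], d[1])), c(3, 2, 1))
  lay <- channel_layout(meta$n_channels, names = meta$channel_names)
  lay$positions <- matrix(meta$channel_positions, ncol = 2,
                          dimnames = list(NULL, c("x", "y")))
  epoch_set(data, meta$times, meta$labels, meta$state, meta$subject,
            meta$sfreq, lay, log = as.character(meta$log))
}
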