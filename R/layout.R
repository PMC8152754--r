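#' Generic 2-D sensor layout on the unit head disc
#'
#' Places `n` channels deterministically on the unit disc with a sunflower
#' (golden-angle) arrangement, which gives near-uniform coverage at any `n`.
#' The layout is a stand-in for a real high-density net geometry: downstream
#' code only needs inter-channel distances and a rough anterior/posterior
#' axis (positive y = anterior).
#'
#' @param n number of channels (default 173, a reduced high-density montage).
#' @param names optional character vector of channel names; defaults to
#'   `"E001"..`. Must be unique.
#' @return an object of class `channel_layout` with fields `n_channels`,
#'   `positions` (n x 2 matrix, columns x/y) and `names`.
#' @examples
#' lay <- channel_layout(16)
#' plot(lay$positions, asp = 1)
#' @export
channel_layout <- function(n = 173, names = NULL) {
  if (length(n) != 1L || !is.finite(n) || n < 1) {
    stopf("`n` must be a positive integer count")
  }
  n <- as.integer(n)
  if (is.null(names)) names <- sprintf("E%03d", seq_len(n))
  if (anyDuplicated(names)) stopf("channel names must be unique")
  if (length(names) != n) stopf("length(names) must equal n")
  golden <- pi * (3 - sqrt(5))
  k <- seq_len(n)
  # radius 0 for a single channel, otherwise fill the disc up to 0.95
  r <- 0.95 * sqrt((k - 0.5) / n)
  theta <- k * golden
  pos <- cbind(x = r * cos(theta), y = r * sin(theta))
  structure(
    list(n_channels = n, positions = pos, names = names),
    class = "channel_layout"
  )
}

#' @export
print.channel_layout <- function(x, ...) {
  cat(sprintf("<channel_layout> %d channels on the unit disc\n", x$n_channels))
  invisible(x)
}

validate_layout <- function(layout) {
  if (!inherits(layout, "channel_layout")) stopf("not a channel_layout")
  if (layout$n_channels < 1L) stopf("layout is empty")
  r <- sqrt(rowSums(layout$positions^2))
  if (any(r > 1 + 1e-9)) stopf("layout positions must lie within the unit disc")
  invisible(layout)
}
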