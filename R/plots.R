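#' Plot a grid of cross-generalization matrices
#'
#' One tile panel per (train state, test state): colour = group-mean
#' accuracy, dots = FDR-significant cells. Plots only rendered results --
#' nothing is recomputed.
#'
#' @param grid a `cross_generalization_grid`.
#' @param contrast which contrast to plot (default: the first).
#' @param file optional output path (PNG/SVG by extension).
#' @return a ggplot object, invisibly if written to file.
#' @export
plot_tgm_grid <- function(grid, contrast = NULL, file = NULL) {
  contrast <- contrast %||% grid$meta$contrasts[1]
  res <- grid$results[[contrast]]
  states <- grid$meta$states
  dfs <- list()
  for (tr in states) {
    for (te in states) {
      cell <- res[[tr]][[te]]
      tt <- cell$subject_tgms[[1]]$train_times
      ts <- cell$subject_tgms[[1]]$test_times
      dfs[[length(dfs) + 1L]] <- data.frame(
        train_state = factor(tr, levels = states),
        test_state = factor(te, levels = states),
        train_time = rep(tt, times = length(ts)),
        test_time = rep(ts, each = length(tt)),
        accuracy = as.vector(cell$group_mean),
        significant = as.vector(cell$stat$mask)
      )
    }
  }
  df <- do.call(rbind, dfs)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$test_time,
                                        y = .data$train_time,
                                        fill = .data$accuracy)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(data = df[df$significant, , drop = FALSE],
                        size = 0.3, colour = "black") +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, low = "#2166AC",
                                  mid = "white", high = "#B2182B") +
    ggplot2::facet_grid(train_state ~ test_state) +
    ggplot2::labs(x = "test time (s)", y = "train time (s)",
                  fill = "accuracy",
                  title = sprintf("%s: cross-generalization matrices",
                                  contrast)) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 2 + 2 * length(states),
                    height = 1.5 + 2 * length(states), dpi = 150)
    return(invisible(p))
  }
  p
}

#' Plot a forward-model topography at selected times
#'
#' Simple disc scatter map: channel positions coloured by activation, one
#' panel per requested time window (window-averaged).
#'
#' @param map a `topography_map`.
#' @param windows list of `(lo, hi)` time windows in s.
#' @param file optional output path.
#' @return a ggplot object.
#' @export
plot_topography <- function(map, windows = list(c(0.25, 0.40),
                                                c(0.6, 0.9)),
                            file = NULL) {
  dfs <- list()
  for (w in windows) {
    sel <- map$times >= w[1] & map$times <= w[2]
    if (!any(sel)) stopf("window %g..%g s contains no time points", w[1], w[2])
    dfs[[length(dfs) + 1L]] <- data.frame(
      x = map$layout$positions[, 1], y = map$layout$positions[, 2],
      activation = rowMeans(map$patterns[, sel, drop = FALSE]),
      window = sprintf("%.2f-%.2f s", w[1], w[2])
    )
  }
  df <- do.call(rbind, dfs)
  circ <- data.frame(x = cos(seq(0, 2 * pi, length.out = 100)),
                     y = sin(seq(0, 2 * pi, length.out = 100)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$activation)) +
    ggplot2::geom_path(data = circ, colour = "grey50",
                       inherit.aes = FALSE,
                       ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_colour_gradient2(low = "#2166AC", mid = "white",
                                    high = "#B2182B") +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~window) +
    ggplot2::labs(title = sprintf("%s topography (%s)", map$state,
                                  map$units),
                  colour = map$units) +
    ggplot2::theme_void()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 3 * length(windows), height = 3.5,
                    dpi = 150)
    return(invisible(p))
  }
  p
}
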