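#' Build a run configuration from a YAML file
#'
#' The YAML mirrors the constructor arguments, e.g.:
#' ```yaml
#' simulation:
#'   n_subjects: 4
#'   states: [WAKE, N2, N3]
#'   n_channels: 16
#'   n_epochs_per_condition: 60
#'   seed: 7
#' preprocessing: {bandpass: [1, 20], crop_window: [-0.2, 1.0], decim: 4,
#'                 lowpass: 25, n_balance: 100}
#' contrasts: [VOICE]
#' q: 0.01
#' master_seed: 7
#' ```
#' Unstated fields keep their defaults. Effects and noise can be given as
#' lists of [effect_spec()] / [noise_spec()] arguments.
#'
#' @param path YAML file.
#' @param output_dir optional override of the config's output directory.
#' @param master_seed optional override of the master seed.
#' @return a [run_config()].
#' @export
run_config_from_yaml <- function(path, output_dir = NULL,
                                 master_seed = NULL) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulation %||% list()
  if (!is.null(sim_args$n_channels)) {
    sim_args$layout <- channel_layout(sim_args$n_channels)
    sim_args$n_channels <- NULL
  }
  if (!is.null(sim_args$states)) sim_args$states <- unlist(sim_args$states)
  if (!is.null(sim_args$n_epochs_per_condition) &&
      is.list(sim_args$n_epochs_per_condition)) {
    sim_args$n_epochs_per_condition <-
      unlist(sim_args$n_epochs_per_condition)
  }
  if (!is.null(sim_args$effects)) {
    sim_args$effects <- lapply(sim_args$effects, function(e) {
      e <- lapply(e, function(v) if (is.list(v)) unlist(v) else v)
      do.call(effect_spec, e)
    })
  }
  sim <- do.call(sim_config, sim_args)
  pp_args <- lapply(y$preprocessing %||% list(),
                    function(v) if (is.list(v)) unlist(v) else v)
  pp <- do.call(preprocessing_params, pp_args)
  cls <- do.call(classifier_spec, y$classifier %||% list())
  run_config(
    simulation = sim, preprocessing = pp, classifier = cls,
    contrasts = if (!is.null(y$contrasts)) unlist(y$contrasts) else NULL,
    states = if (!is.null(y$states)) unlist(y$states) else NULL,
    q = y$q %||% 0.01,
    peak_window = unlist(y$peak_window %||% c(0.25, 0.40)),
    output_dir = output_dir %||% y$output_dir,
    master_seed = master_seed %||% y$master_seed %||% 1L,
    topographies = y$topographies %||% TRUE
  )
}
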