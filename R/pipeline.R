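#' Full-analysis run configuration
#'
#' @param simulation a [sim_config()] (or a path to a directory of epoch
#'   bundles laid out as `sub<k>_<STATE>_<CONTRAST>/`).
#' @param preprocessing a [preprocessing_params()].
#' @param classifier a [classifier_spec()].
#' @param contrasts contrast names to analyse (subset of the simulation's
#'   effects).
#' @param states ordered state list (defaults to the simulation's).
#' @param q FDR level.
#' @param peak_window summary window in s.
#' @param output_dir directory for result files, or `NULL` to skip
#'   writing.
#' @param master_seed integer; expands into per-(subject, state, contrast)
#'   sub-streams so every stage is reproducible.
#' @param topographies compute forward-model topographies for within-state
#'   decoders (moderately expensive at high channel counts).
#' @return an object of class `run_config`.
#' @export
run_config <- function(simulation = sim_config(),
                       preprocessing = preprocessing_params(),
                       classifier = classifier_spec(),
                       contrasts = NULL,
                       states = NULL,
                       q = 0.01,
                       peak_window = c(0.25, 0.40),
                       output_dir = NULL,
                       master_seed = 1L,
                       topographies = TRUE) {
  if (inherits(simulation, "sim_config")) {
    contrasts <- contrasts %||% names(simulation$effects)
    states <- states %||% simulation$states
  }
  structure(
    list(simulation = simulation, preprocessing = preprocessing,
         classifier = classifier, contrasts = contrasts, states = states,
         q = q, peak_window = peak_window, output_dir = output_dir,
         master_seed = as.integer(master_seed),
         topographies = isTRUE(topographies)),
    class = "run_config"
  )
}

load_subject_state <- function(config, subject, state, contrast) {
  sim <- config$simulation
  if (inherits(sim, "sim_config")) {
    simulate_epochs(sim, subject, state, contrast)
  } else {
    read_epochs(file.path(sim, sprintf("sub%02d_%s_%s", subject, state,
                                       contrast)))
  }
}

#' Run the full decoding analysis
#'
#' For every contrast and subject: simulate (or load) each state's raw
#' epochs, run the preprocessing chain, compute the within-state two-fold
#' TGM for every state and the cross-state transfer TGM for every ordered
#' state pair, plus the matched label-permutation null TGMs; then, at the
#' group level, average TGMs and run the mass-univariate Mann-Whitney +
#' BH-FDR statistics per (train-state, test-state) matrix. Optionally
#' computes fold-averaged forward-model topographies for the within-state
#' decoders. Fully deterministic given the config and `master_seed`.
#'
#' @param config a [run_config()].
#' @return an object of class `cross_generalization_grid`: nested list
#'   `$results[[contrast]][[train_state]][[test_state]]` with fields
#'   `group_mean` (matrix), `stat` (`stat_result`), `subject_tgms`,
#'   `subject_nulls`; `$topographies[[contrast]][[state]]` (group-mean
#'   `topography_map`); `$summary` (data frame); `$meta`.
#' @export
run_full_analysis <- function(config) {
  sim <- config$simulation
  n_sub <- if (inherits(sim, "sim_config")) sim$n_subjects else
    length(list.dirs(sim, recursive = FALSE))
  states <- config$states
  results <- list()
  topos <- list()
  for (contrast in config$contrasts) {
    per_pair <- list()
    topo_subj <- list()
    for (sub in seq_len(n_sub)) {
      balanced <- list()
      for (state in states) {
        raw <- load_subject_state(config, sub, state, contrast)
        pp <- config$preprocessing
        pp$seed <- derive_seed(config$master_seed, "balance", sub, state,
                               contrast)
        balanced[[state]] <- preprocess(raw, pp)
      }
      for (tr_state in states) {
        dec_seed <- derive_seed(config$master_seed, "decode", sub, tr_state,
                                contrast)
        want_topo <- config$topographies
        tg <- within_state_tgm(balanced[[tr_state]], config$classifier,
                               seed = dec_seed,
                               lowpass = config$preprocessing$lowpass,
                               keep_decoders = want_topo)
        nul <- null_within_tgm(balanced[[tr_state]], config$classifier,
                               seed = dec_seed,
                               lowpass = config$preprocessing$lowpass)
        per_pair[[tr_state]][[tr_state]]$subject_tgms[[sub]] <- strip_attrs(tg)
        per_pair[[tr_state]][[tr_state]]$subject_nulls[[sub]] <- nul
        if (want_topo) {
          folds <- attr(tg, "decoders")
          topo_subj[[tr_state]][[sub]] <- average_topographies(
            lapply(folds, pattern_timecourse))
        }
        for (te_state in setdiff(states, tr_state)) {
          ct <- cross_state_tgm(balanced[[tr_state]], balanced[[te_state]],
                                config$classifier,
                                lowpass = config$preprocessing$lowpass)
          cn <- null_cross_tgm(balanced[[tr_state]], balanced[[te_state]],
                               config$classifier,
                               seed = derive_seed(dec_seed, te_state),
                               lowpass = config$preprocessing$lowpass)
          per_pair[[tr_state]][[te_state]]$subject_tgms[[sub]] <- ct
          per_pair[[tr_state]][[te_state]]$subject_nulls[[sub]] <- cn
        }
      }
    }
    for (tr_state in states) {
      for (te_state in states) {
        cell <- per_pair[[tr_state]][[te_state]]
        cell$group_mean <- Reduce(`+`, lapply(cell$subject_tgms,
                                              `[[`, "scores")) / n_sub
        cell$stat <- mass_univariate(cell$subject_tgms, cell$subject_nulls,
                                     config$q)
        per_pair[[tr_state]][[te_state]] <- cell
      }
      if (config$topographies) {
        topos[[contrast]][[tr_state]] <-
          average_topographies(topo_subj[[tr_state]])
      }
    }
    results[[contrast]] <- per_pair
  }
  grid <- structure(
    list(results = results, topographies = topos, summary = NULL,
         meta = list(states = states, contrasts = config$contrasts,
                     n_subjects = n_sub, q = config$q,
                     peak_window = config$peak_window,
                     master_seed = config$master_seed,
                     config_hash = config_hash(config),
                     package_version =
                       as.character(utils::packageVersion("vigildecode")))),
    class = "cross_generalization_grid"
  )
  grid$summary <- summarize_grid(grid)
  if (!is.null(config$output_dir)) write_grid(grid, config$output_dir)
  grid
}

strip_attrs <- function(tg) {
  attr(tg, "decoders") <- NULL
  attr(tg, "decoder") <- NULL
  tg
}

config_hash <- function(config) {
  config$output_dir <- NULL # where results land does not change them
  ser <- jsonlite::toJSON(rapply(unclass(config), function(x) {
    if (is.function(x)) "fn" else x
  }, how = "replace"), auto_unbox = TRUE, digits = 10, force = TRUE)
  fnv1a_hash(as.character(ser))
}

#' Summary table of a cross-generalization grid
#'
#' One row per (contrast, train state, test state): mean and SD across
#' subjects of the peak-window accuracy (in %), the number of
#' FDR-significant cells, and the latency (train time, s) of the maximum
#' group-mean accuracy. With a single subject the SD is reported as 0 with
#' a warning.
#'
#' @param grid a `cross_generalization_grid`.
#' @param peak_window optional override of the summary window.
#' @return a data frame.
#' @export
summarize_grid <- function(grid, peak_window = NULL) {
  pw <- peak_window %||% grid$meta$peak_window
  rows <- list()
  for (contrast in names(grid$results)) {
    for (tr in names(grid$results[[contrast]])) {
      for (te in names(grid$results[[contrast]][[tr]])) {
        cell <- grid$results[[contrast]][[tr]][[te]]
        accs <- vapply(cell$subject_tgms, peak_window_summary, 0,
                       window = pw)
        sd_ <- if (length(accs) > 1) stats::sd(accs) else {
          warning("single subject: SD reported as 0", call. = FALSE)
          0
        }
        gm <- cell$group_mean
        imax <- which(gm == max(gm), arr.ind = TRUE)[1, ]
        rows[[length(rows) + 1L]] <- data.frame(
          contrast = contrast, train_state = tr, test_state = te,
          peak_acc_mean_pct = 100 * mean(accs),
          peak_acc_sd_pct = 100 * sd_,
          n_signif_cells = sum(cell$stat$mask),
          max_acc_latency_s = cell$subject_tgms[[1]]$train_times[imax[1]],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' @export
print.cross_generalization_grid <- function(x, ...) {
  cat(sprintf(
    "<cross_generalization_grid> %d contrast(s) x %d states, %d subjects (hash %s)\n",
    length(x$meta$contrasts), length(x$meta$states), x$meta$n_subjects,
    x$meta$config_hash))
  print(x$summary, digits = 3)
  invisible(x)
}

# Serialize grid results: per-pair CSV matrices + JSON summary/metadata.
write_grid <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (contrast in names(grid$results)) {
    for (tr in names(grid$results[[contrast]])) {
      for (te in names(grid$results[[contrast]][[tr]])) {
        cell <- grid$results[[contrast]][[tr]][[te]]
        stem <- file.path(dir, sprintf("%s_%s_to_%s", contrast, tr, te))
        utils::write.csv(cell$group_mean,
                         paste0(stem, "_mean_tgm.csv"), row.names = FALSE)
        utils::write.csv(cell$stat$pvals,
                         paste0(stem, "_pvals.csv"), row.names = FALSE)
        utils::write.csv(cell$stat$mask * 1L,
                         paste0(stem, "_sigmask.csv"), row.names = FALSE)
      }
    }
  }
  utils::write.csv(grid$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(grid$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
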