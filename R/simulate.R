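#' Specification of a planted condition effect
#'
#' Describes the class-difference signal added to one condition: a spatial
#' Gaussian topography on the head disc and a biphasic temporal envelope
#' with an early positive lobe and a later polarity reversal, emulating a
#' K-complex-like evoked response. The effect is carried only by the states
#' in `shared_states`; elsewhere the two conditions are exchangeable.
#'
#' @param topography_center 2-D coordinate of the spatial maximum on the
#'   unit disc. Default `c(0, 0.45)`: anterior midline (fronto-central).
#' @param topography_spread Gaussian spatial width (disc units).
#' @param peak_window time interval (s) containing the positive-lobe peak.
#' @param reversal_time time (s) at which the envelope changes sign; must
#'   exceed the upper edge of `peak_window`.
#' @param amplitude condition-mean difference, in uV, at the topography
#'   maximum and envelope peak. Must be `>= 0`; the condition receiving the
#'   effect is set by `target_condition`.
#' @param shared_states character vector of states carrying the pattern.
#' @param undershoot relative amplitude of the post-reversal negative lobe
#'   (fraction of the positive peak).
#' @param target_condition which condition (0/1) receives the added signal.
#'   Default 1, the "unfamiliar" condition (the more salient stimulus
#'   elicits the larger response).
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(topography_center = c(0, 0.45),
                        topography_spread = 0.4,
                        peak_window = c(0.25, 0.40),
                        reversal_time = 0.6,
                        amplitude = 5,
                        shared_states = c("N2", "N3"),
                        undershoot = 0.7,
                        target_condition = 1L) {
  if (amplitude < 0) stopf("amplitude must be >= 0")
  if (topography_spread <= 0) stopf("topography_spread must be > 0")
  if (length(peak_window) != 2L || diff(peak_window) <= 0) {
    stopf("peak_window must be an increasing interval")
  }
  if (reversal_time <= peak_window[2]) {
    stopf("reversal_time must lie after the peak window")
  }
  if (!target_condition %in% c(0L, 1L)) stopf("target_condition must be 0 or 1")
  structure(
    list(topography_center = topography_center,
         topography_spread = topography_spread,
         peak_window = peak_window, reversal_time = reversal_time,
         amplitude = amplitude, shared_states = shared_states,
         undershoot = undershoot,
         target_condition = as.integer(target_condition)),
    class = "effect_spec"
  )
}

#' State-specific background-activity specification
#'
#' Background EEG is modelled per state as the sum of 1/f^alpha ("pink")
#' noise, a state-characteristic sinusoidal oscillation with random phase
#' per trial and channel, and white sensor noise. Defaults follow the
#' canonical spectral profile of each vigilance state: posterior alpha
#' (10 Hz) in relaxed wake, theta (7 Hz) in N1, sigma/spindle band (13 Hz)
#' in N2, large slow waves (1.5 Hz) in N3, and mixed theta (6 Hz) in REM.
#'
#' @param state one of WAKE, N1, N2, N3, REM (free-form labels allowed).
#' @param pink_exponent spectral slope alpha of the 1/f^alpha component.
#' @param pink_sd standard deviation (uV) of the pink component.
#' @param oscillation_freq oscillation frequency in Hz; defaults per state.
#' @param oscillation_amp oscillation amplitude in uV; defaults per state.
#' @param white_sd white-noise standard deviation in uV.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(state,
                       pink_exponent = 1,
                       pink_sd = 5,
                       oscillation_freq = NULL,
                       oscillation_amp = NULL,
                       white_sd = 2) {
  freqs <- c(WAKE = 10, N1 = 7, N2 = 13, N3 = 1.5, REM = 6)
  amps <- c(WAKE = 4, N1 = 3, N2 = 3, N3 = 15, REM = 2)
  oscillation_freq <- oscillation_freq %||% unname(freqs[state]) %||% 8
  oscillation_amp <- oscillation_amp %||% unname(amps[state]) %||% 3
  if (is.na(oscillation_freq)) oscillation_freq <- 8
  if (is.na(oscillation_amp)) oscillation_amp <- 3
  if (min(pink_sd, oscillation_amp, white_sd) < 0) {
    stopf("noise amplitudes must be >= 0")
  }
  structure(
    list(state = state, pink_exponent = pink_exponent, pink_sd = pink_sd,
         oscillation_freq = oscillation_freq,
         oscillation_amp = oscillation_amp, white_sd = white_sd),
    class = "noise_spec"
  )
}

#' Simulation configuration
#'
#' Bundles everything that determines a simulated multi-subject,
#' multi-state epoched-EEG dataset. Given the same configuration
#' (including `seed`), [simulate_epochs()] is bit-reproducible.
#'
#' @param n_subjects number of subjects (default 16).
#' @param states ordered vigilance-state labels.
#' @param n_epochs_per_condition trials per condition per state. A single
#'   number, or a named vector keyed by state. The default plants 120
#'   everywhere except N1 (40), so that balanced subsampling to 100 has to
#'   fall back to "all available" for N1.
#' @param sfreq sampling rate, Hz (default 250).
#' @param epoch_window epoch extent in s around stimulus onset
#'   (default `c(-2, 3)`, i.e. 5-s segments).
#' @param layout a [channel_layout()].
#' @param effects named list of [effect_spec()]s, one per contrast
#'   (defaults: `VOICE` shared across N2+N3; `NAME` weaker, WAKE+N3).
#' @param noise named list of [noise_spec()]s keyed by state; defaults per
#'   state.
#' @param subject_variability list with `amp_sdlog` (log-normal jitter SD on
#'   amplitude) and `center_sd` (Gaussian jitter SD on the topography
#'   center, disc units). Jitter is drawn once per subject and shared
#'   across states so that cross-state transfer of a shared pattern is
#'   preserved.
#' @param seed master RNG seed; fully determines the dataset.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 16,
                       states = c("WAKE", "N1", "N2", "N3", "REM"),
                       n_epochs_per_condition = c(default = 120, N1 = 40),
                       sfreq = 250,
                       epoch_window = c(-2, 3),
                       layout = channel_layout(173),
                       effects = list(
                         VOICE = effect_spec(amplitude = 5,
                                             shared_states = c("N2", "N3")),
                         NAME = effect_spec(amplitude = 2.5,
                                            shared_states = c("WAKE", "N3"))
                       ),
                       noise = NULL,
                       subject_variability = list(amp_sdlog = 0.3,
                                                  center_sd = 0.05),
                       seed = 1L) {
  if (n_subjects < 2) stopf("n_subjects must be >= 2")
  if (!(epoch_window[1] <= -0.2 && epoch_window[2] >= 1.0)) {
    stopf("epoch_window must contain [-0.2, 1.0] s")
  }
  validate_layout(layout)
  if (is.null(noise)) {
    noise <- lapply(states, noise_spec)
    names(noise) <- states
  }
  for (ns in noise) {
    if (ns$oscillation_freq >= sfreq / 2) {
      stopf("oscillation_freq must be below the Nyquist frequency")
    }
  }
  structure(
    list(n_subjects = as.integer(n_subjects), states = states,
         n_epochs_per_condition = n_epochs_per_condition, sfreq = sfreq,
         epoch_window = epoch_window, layout = layout, effects = effects,
         noise = noise, subject_variability = subject_variability,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

epochs_for_state <- function(config, state) {
  n <- config$n_epochs_per_condition
  if (length(n) == 1L && is.null(names(n))) return(as.integer(n))
  if (state %in% names(n)) return(as.integer(n[[state]]))
  if ("default" %in% names(n)) return(as.integer(n[["default"]]))
  as.integer(n[[1]])
}

#' Spatial Gaussian topography on a channel layout
#'
#' Per-channel weights `exp(-d^2 / (2 spread^2))` of distance `d` to
#' `center`, rescaled so the maximum (at the channel nearest `center`)
#' equals 1.
#'
#' @param layout a [channel_layout()].
#' @param center 2-D coordinate of the pattern maximum.
#' @param spread Gaussian width; `> 0`. Large `spread` tends to a uniform
#'   topography.
#' @return numeric vector of weights in `[0, 1]`, one per channel.
#' @export
generate_topography <- function(layout, center, spread) {
  validate_layout(layout)
  if (spread <= 0) stopf("spread must be > 0")
  d2 <- (layout$positions[, 1] - center[1])^2 +
    (layout$positions[, 2] - center[2])^2
  w <- exp(-d2 / (2 * spread^2))
  w / max(w)
}

#' Biphasic effect-envelope over an epoch time axis
#'
#' Builds the temporal envelope of the planted condition difference: zero
#' before stimulus onset, a raised-cosine positive lobe peaking at the
#' centre of `spec$peak_window` and returning to zero at
#' `spec$reversal_time`, then a negative half-sine lobe (relative amplitude
#' `spec$undershoot`) returning to zero at the epoch end. The maximum
#' absolute value is 1; multiply by `spec$amplitude` for uV.
#'
#' @param times sorted sample latencies in s, covering the spec's windows.
#' @param spec an [effect_spec()].
#' @return numeric envelope, same length as `times`.
#' @export
generate_effect_timecourse <- function(times, spec) {
  if (is.unsorted(times, strictly = TRUE)) stopf("times must be sorted")
  r <- spec$reversal_time
  if (r < times[1] || r > times[length(times)]) {
    stopf("reversal_time lies outside the time axis")
  }
  peak <- mean(spec$peak_window)
  t_end <- times[length(times)]
  env <- numeric(length(times))
  rise <- times > 0 & times <= peak
  env[rise] <- 0.5 - 0.5 * cos(pi * times[rise] / peak)
  fall <- times > peak & times < r
  env[fall] <- 0.5 + 0.5 * cos(pi * (times[fall] - peak) / (r - peak))
  if (t_end > r) {
    post <- times >= r
    env[post] <- -spec$undershoot * sin(pi * (times[post] - r) / (t_end - r))
  }
  env / max(abs(env))
}

# 1/f^alpha noise: frequency-domain shaping of white noise, one column per
# independent series; each column rescaled to unit SD.
pink_noise <- function(n_samples, n_series, exponent = 1) {
  if (n_samples < 2) return(matrix(stats::rnorm(n_samples * n_series),
                                   n_samples, n_series))
  white <- matrix(stats::rnorm(n_samples * n_series), n_samples, n_series)
  spec <- stats::mvfft(white)
  freq_idx <- c(0, seq_len(n_samples - 1))
  freq_idx <- pmin(freq_idx, n_samples - freq_idx) # symmetric |f| bins
  shape <- c(0, (freq_idx[-1])^(-exponent / 2))
  x <- Re(stats::mvfft(spec * shape, inverse = TRUE)) / n_samples
  sds <- sqrt(colMeans(x^2) - colMeans(x)^2)
  sds[sds == 0] <- 1
  sweep(x, 2, sds, "/")
}

#' Simulate one subject-state-contrast block of epoched EEG
#'
#' Draws background activity (pink + state oscillation + white noise,
#' independent across channels) for every trial and adds the planted
#' class-difference signal `topography (x) envelope * amplitude * subject
#' jitter` to the target condition whenever `state` belongs to the effect's
#' `shared_states`. Labels are balanced. Output is deterministic given
#' `(config$seed, subject, state, contrast)`; subject-level jitter depends
#' only on `(config$seed, subject, contrast)` so a shared pattern is
#' identical across that subject's states.
#'
#' @param config a [sim_config()].
#' @param subject subject index in `1..n_subjects`.
#' @param state a state label from `config$states`.
#' @param contrast name of an entry of `config$effects`.
#' @return an [epoch_set()] in uV.
#' @export
simulate_epochs <- function(config, subject, state, contrast) {
  if (!inherits(config, "sim_config")) stopf("config must be a sim_config")
  if (subject < 1 || subject > config$n_subjects) {
    stopf("subject must be in 1..%d", config$n_subjects)
  }
  if (!state %in% config$states) stopf("unknown state '%s'", state)
  if (!contrast %in% names(config$effects)) {
    stopf("unknown contrast '%s'", contrast)
  }
  spec <- config$effects[[contrast]]
  ns <- config$noise[[state]]
  lay <- config$layout
  n_ch <- lay$n_channels
  i0 <- round(config$epoch_window[1] * config$sfreq)
  i1 <- round(config$epoch_window[2] * config$sfreq)
  times <- (i0:i1) / config$sfreq
  n_t <- length(times)
  n_per <- epochs_for_state(config, state)
  n_trials <- 2L * n_per
  labels <- rep(c(0L, 1L), each = n_per)

  # subject-level jitter: shared across states (supports cross-state transfer)
  jit <- local_rng(derive_seed(config$seed, "subject", subject, contrast), {
    list(amp = stats::rlnorm(1, 0, config$subject_variability$amp_sdlog),
         center = stats::rnorm(2, 0, config$subject_variability$center_sd))
  })

  data <- local_rng(derive_seed(config$seed, subject, state, contrast), {
    x <- array(0, dim = c(n_trials, n_ch, n_t))
    series <- n_trials * n_ch
    if (ns$pink_sd > 0) {
      pk <- pink_noise(n_t, series, ns$pink_exponent) * ns$pink_sd
      x <- x + aperm(array(pk, dim = c(n_t, n_trials, n_ch)), c(2, 3, 1))
    }
    if (ns$oscillation_amp > 0) {
      phases <- matrix(stats::runif(series, 0, 2 * pi), n_trials, n_ch)
      osc <- ns$oscillation_amp *
        sin(outer(2 * pi * ns$oscillation_freq * times, c(phases), "+"))
      x <- x + aperm(array(osc, dim = c(n_t, n_trials, n_ch)), c(2, 3, 1))
    }
    if (ns$white_sd > 0) {
      x <- x + array(stats::rnorm(n_trials * n_ch * n_t, 0, ns$white_sd),
                     dim = c(n_trials, n_ch, n_t))
    }
    x
  })

  if (spec$amplitude > 0 && state %in% spec$shared_states) {
    topo <- generate_topography(lay, spec$topography_center + jit$center,
                                spec$topography_spread)
    env <- generate_effect_timecourse(times, spec)
    signal <- (spec$amplitude * jit$amp) * outer(topo, env) # n_ch x n_t
    target <- which(labels == spec$target_condition)
    for (tr in target) data[tr, , ] <- data[tr, , ] + signal
  }

  epoch_set(data, times, labels, state, subject, config$sfreq, lay,
            log = sprintf("simulate(seed=%d,%s,%s,sub%02d)",
                          config$seed, state, contrast, subject))
}
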