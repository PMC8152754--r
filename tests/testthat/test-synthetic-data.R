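test_that("topography weights follow the spatial Gaussian", {
  # 3 collinear channels at distances {0, d, 2d} from the center, spread d
  lay <- channel_layout(3)
  d <- 0.3
  lay$positions <- cbind(x = c(0, d, 2 * d), y = c(0, 0, 0))
  w <- generate_topography(lay, center = c(0, 0), spread = d)
  expect_equal(w, c(1, exp(-1 / 2), exp(-2)))

  # channel exactly at the center gets weight 1; all weights in [0, 1]
  lay16 <- channel_layout(16)
  ctr <- lay16$positions[5, ]
  w16 <- generate_topography(lay16, ctr, 0.25)
  expect_equal(w16[5], 1)
  expect_true(all(w16 >= 0 & w16 <= 1))

  # Gaussian limit: very large spread tends to a uniform topography
  w_flat <- generate_topography(lay16, c(0, 0.45), spread = 1e4)
  expect_true(all(abs(w_flat - 1) < 1e-6))

  expect_error(generate_topography(lay16, c(0, 0), spread = 0), "spread")
})

test_that("effect envelope is biphasic with the planted timing", {
  times <- seq(-0.2, 1.0, by = 1 / 62.5)
  spec <- effect_spec()
  env <- generate_effect_timecourse(times, spec)

  expect_equal(env[times <= 0], rep(0, sum(times <= 0)))
  expect_equal(max(abs(env)), 1)
  # positive-lobe peak inside the 250-400 ms window
  t_peak <- times[which.max(env)]
  expect_gte(t_peak, 0.25)
  expect_lte(t_peak, 0.40)
  # exactly one sign change, at the grid point nearest the 0.6 s reversal
  post_onset <- env[times > 0]
  sgn <- sign(post_onset[post_onset != 0])
  flips <- which(diff(sgn) != 0)
  expect_length(flips, 1)
  t_nonzero <- times[times > 0][post_onset != 0]
  t_flip <- mean(t_nonzero[flips + c(0, 1)])
  expect_lt(abs(t_flip - 0.6), 1.5 / 62.5)
  # negative lobe returns toward zero at the epoch end
  expect_lt(abs(env[length(env)]), 0.05)

  expect_error(generate_effect_timecourse(seq(0, 0.5, by = 0.01), spec),
               "reversal_time")
})

test_that("simulated epochs are deterministic and carry the planted signal", {
  cfg <- quick_cfg(seed = 11)
  a <- simulate_epochs(cfg, 1, "N2", "VOICE")
  b <- simulate_epochs(cfg, 1, "N2", "VOICE")
  expect_identical(a$data, b$data)
  expect_identical(a$labels, b$labels)

  # noiseless limit: condition-mean difference is exactly topography (x)
  # envelope * amplitude * subject jitter
  cfg0 <- quick_cfg(seed = 11, subject_variability = list(amp_sdlog = 0,
                                                          center_sd = 0))
  cfg0$noise <- lapply(cfg0$noise, function(n) {
    n$pink_sd <- 0; n$oscillation_amp <- 0; n$white_sd <- 0; n
  })
  e0 <- simulate_epochs(cfg0, 1, "N2", "VOICE")
  diff <- apply(e0$data[e0$labels == 1, , , drop = FALSE], c(2, 3), mean) -
    apply(e0$data[e0$labels == 0, , , drop = FALSE], c(2, 3), mean)
  topo <- generate_topography(cfg0$layout, c(0, 0.45), 0.4)
  env <- generate_effect_timecourse(e0$times, cfg0$effects$VOICE)
  expect_equal(diff, 12 * outer(topo, env), tolerance = 1e-12)

  # no effect outside shared states
  ew <- simulate_epochs(quick_cfg(states = c("WAKE", "N2"), seed = 11),
                        1, "WAKE", "VOICE")
  expect_equal(mean(ew$data[ew$labels == 1, , ]) -
                 mean(ew$data[ew$labels == 0, , ]), 0, tolerance = 0.5)

  expect_error(simulate_epochs(cfg, 1, "REM", "VOICE"), "unknown state")
  expect_error(simulate_epochs(cfg, 1, "N2", "ODDBALL"), "unknown contrast")
  expect_error(simulate_epochs(cfg, 99, "N2", "VOICE"), "subject")
})

test_that("state-specific background carries its oscillatory signature", {
  # long pseudo-epochs; Welch-style smoothed periodogram per state
  cfg <- quick_cfg(n_channels = 2, n_epochs = 4, amplitude = 0,
                   states = c("N2", "N3"), sfreq = 62.5,
                   epoch_window = c(-0.2, 8), seed = 4)
  peak_freq <- function(state) {
    ep <- simulate_epochs(cfg, 1, state, "VOICE")
    x <- as.vector(t(ep$data[, 1, ])) # concatenate trials, channel 1
    sp <- stats::spectrum(x, spans = c(11, 11), plot = FALSE)
    f <- sp$freq * cfg$sfreq
    band <- f >= 8 & f <= 20
    list(f = f[band], pow = sp$spec[band], full_pow = sp$spec, full_f = f)
  }
  n2 <- peak_freq("N2")
  n3 <- peak_freq("N3")
  # N2 shows a sigma-band (13 +- 1 Hz) peak ...
  expect_lt(abs(n2$f[which.max(n2$pow)] - 13), 1)
  # ... that is absent from N3 (its 8-20 Hz band is ~monotone 1/f)
  n2_prominence <- max(n2$pow) / stats::median(n2$pow)
  n3_prominence <- max(n3$pow) / stats::median(n3$pow)
  expect_gt(n2_prominence, 5)
  expect_lt(n3_prominence, n2_prominence / 2)
})

test_that("planted-contrast topography is recoverable from sample means", {
  # amplitude ~3x per-sample noise SD, >=100 trials per condition
  cfg <- quick_cfg(n_channels = 16, n_epochs = 100, amplitude = 20,
                   subject_variability = list(amp_sdlog = 0, center_sd = 0),
                   seed = 8)
  ep <- simulate_epochs(cfg, 1, "N2", "VOICE")
  env <- generate_effect_timecourse(ep$times, cfg$effects$VOICE)
  t_pk <- which.max(env)
  diff <- apply(ep$data[ep$labels == 1, , t_pk], 2, mean) -
    apply(ep$data[ep$labels == 0, , t_pk], 2, mean)
  topo <- generate_topography(cfg$layout, c(0, 0.45), 0.4)
  expect_gt(stats::cor(diff, topo), 0.9)
})

test_that("null simulation rejects at the nominal rate", {
  cfg <- quick_cfg(n_channels = 4, n_epochs = 40, amplitude = 0, seed = 13)
  ep <- simulate_epochs(cfg, 1, "N2", "VOICE")
  g1 <- ep$labels == 1
  pvals <- apply(ep$data, c(2, 3), function(v) {
    stats::t.test(v[g1], v[!g1])$p.value
  })
  m <- length(pvals)
  rate <- mean(pvals < 0.05)
  mc_err <- sqrt(0.05 * 0.95 / m)
  expect_lt(rate, 0.05 + 3 * mc_err)
})

test_that("epoch bundles round-trip through the portable writer", {
  cfg <- quick_cfg(n_channels = 5, n_epochs = 6, seed = 2)
  ep <- simulate_epochs(cfg, 2, "N3", "VOICE")
  dir <- withr::local_tempdir()
  write_epochs(ep, file.path(dir, "b"))
  back <- read_epochs(file.path(dir, "b"))
  expect_equal(back$data, ep$data, tolerance = 1e-12)
  expect_identical(back$labels, ep$labels)
  expect_equal(back$times, ep$times)
  expect_equal(back$sfreq, ep$sfreq)
  expect_identical(back$layout$names, ep$layout$names)
})
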