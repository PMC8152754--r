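make_sine_epochs <- function(freq, sfreq = 250, window = c(-2, 3),
                             n_channels = 2) {
  i <- round(window[1] * sfreq):round(window[2] * sfreq)
  times <- i / sfreq
  x <- sin(2 * pi * freq * times)
  data <- aperm(array(rep(x, 2 * n_channels),
                      dim = c(length(x), n_channels, 2)), c(3, 2, 1))
  epoch_set(data, times, c(0L, 1L), "N2", 1, sfreq, channel_layout(n_channels))
}

test_that("band-pass preserves the passband and rejects stop bands", {
  mid <- function(ep) {
    sel <- ep$times > -1 & ep$times < 2 # away from edge transients
    max(abs(ep$data[1, 1, sel]))
  }
  # 10 Hz sinusoid passes within ripple
  ep10 <- bandpass_filter(make_sine_epochs(10), 1, 20)
  expect_equal(mid(ep10), 1, tolerance = 0.05)
  expect_identical(dim(ep10$data), c(2L, 2L, 1251L))
  # 40 Hz attenuated by at least 20 dB
  ep40 <- bandpass_filter(make_sine_epochs(40), 1, 20)
  expect_lt(mid(ep40), 10^(-20 / 20))
  # DC offset removed by the high-pass edge
  dc <- make_sine_epochs(10)
  dc$data[] <- 1
  ep_dc <- bandpass_filter(dc, 1, 20)
  expect_lt(mid(ep_dc), 0.05)
  # invalid bands error out
  expect_error(bandpass_filter(make_sine_epochs(10), 20, 1), "inverted")
  expect_error(bandpass_filter(make_sine_epochs(10), 1, 200), "Nyquist")
})

test_that("crop keeps exactly the closed-interval samples", {
  ep <- make_sine_epochs(10) # 250 Hz, -2..3 s
  cr <- crop_epochs(ep, c(-0.2, 1.0))
  # brute-force oracle: count grid points inside the closed interval
  n_expected <- sum(ep$times >= -0.2 - 1e-12 & ep$times <= 1.0 + 1e-12)
  expect_identical(dim(cr$data)[3], n_expected)
  expect_identical(n_expected, 301L)
  expect_equal(range(cr$times), c(-0.2, 1.0))
  # crop to full extent is the identity
  full <- crop_epochs(ep, range(ep$times))
  expect_equal(full$data, ep$data)
  # empty window errors
  expect_error(crop_epochs(ep, c(0.0011, 0.0019)), "no samples")
})

test_that("decimation picks every k-th sample and rescales sfreq", {
  ep <- crop_epochs(bandpass_filter(make_sine_epochs(5), 1, 20),
                    c(-0.2, 1.0))
  de <- decimate_epochs(ep, 4L)
  expect_identical(dim(de$data)[3], as.integer(ceiling(301 / 4)))
  expect_identical(dim(de$data)[3], 76L)
  expect_equal(de$sfreq, 62.5)
  expect_equal(de$times, ep$times[seq(1, 301, by = 4)])
  # factor 1 is the identity
  expect_equal(decimate_epochs(ep, 1L)$data, ep$data)
  # composition: decimate(2) o decimate(2) == decimate(4)
  d22 <- decimate_epochs(decimate_epochs(ep, 2L), 2L)
  expect_equal(d22$data, de$data)
  expect_equal(d22$sfreq, de$sfreq)
  expect_error(decimate_epochs(ep, 0L), "factor")
  # decimating unfiltered data warns about aliasing risk
  expect_warning(decimate_epochs(make_sine_epochs(5), 4L), "low-pass")
})

test_that("per-trial standardization is exact, invertible, and flagged", {
  ep <- toy_epochs(n_trials = 6, n_channels = 4, n_samples = 25, seed = 3)
  st <- standardize_trials(ep)
  mu <- apply(st$data, c(1, 2), mean)
  v <- apply(st$data, c(1, 2), function(x) mean(x^2) - mean(x)^2)
  expect_equal(max(abs(mu)), 0, tolerance = 1e-12)
  expect_equal(max(abs(v - 1)), 0, tolerance = 1e-10)

  # hand example: [1, 3] -> [-1, 1] with population SD convention
  ep2 <- toy_epochs(n_trials = 1, n_channels = 1, n_samples = 2,
                    labels = 0L, data = array(c(1, 3), dim = c(1, 1, 2)))
  st2 <- standardize_trials(ep2)
  expect_equal(as.vector(st2$data), c(-1, 1))
  expect_equal(as.vector(st2$standardization$mean), 2)
  expect_equal(as.vector(st2$standardization$scale), 1)

  # idempotence up to float tolerance
  st_twice <- standardize_trials(st)
  expect_equal(st_twice$data, st$data, tolerance = 1e-10)

  # round-trip reconstruction within 1e-10 relative tolerance
  back <- unstandardize_trials(st)
  expect_equal(back$data, ep$data, tolerance = 1e-10)

  # constant series: zero output, scale kept at 1, flag raised
  epc <- toy_epochs(n_trials = 2, n_channels = 2, n_samples = 10, seed = 4)
  epc$data[1, 1, ] <- 7
  expect_message(stc <- standardize_trials(epc), "zero-variance")
  expect_equal(stc$data[1, 1, ], rep(0, 10))
  expect_true(stc$standardization$flagged[1, 1])
  expect_equal(unstandardize_trials(stc)$data, epc$data, tolerance = 1e-10)
})

test_that("balanced subsampling caps both classes and is seeded", {
  ep <- toy_epochs(n_trials = 250, n_channels = 2, n_samples = 5,
                   labels = rep(c(0L, 1L), c(120, 130)), seed = 5)
  b <- balance_epochs(ep, 100, seed = 42)
  expect_identical(as.vector(table(b$labels)), c(100L, 100L))

  # N1-style branch: short condition caps both at the minimum
  ep_n1 <- toy_epochs(n_trials = 95, n_channels = 2, n_samples = 5,
                      labels = rep(c(0L, 1L), c(40, 55)), seed = 5)
  b_n1 <- balance_epochs(ep_n1, 100, seed = 42)
  expect_identical(as.vector(table(b_n1$labels)), c(40L, 40L))

  # determinism: same seed, same trial set
  b2 <- balance_epochs(ep, 100, seed = 42)
  expect_identical(b2$data, b$data)
  b3 <- balance_epochs(ep, 100, seed = 43)
  expect_false(identical(b3$data, b$data))

  # exact 50/50 label proportions always
  for (s in 1:5) {
    bb <- balance_epochs(ep_n1, 30, seed = s)
    expect_identical(sum(bb$labels == 0L), sum(bb$labels == 1L))
  }

  ep_one <- toy_epochs(n_trials = 4, labels = rep(0L, 4))
  expect_error(balance_epochs(ep_one, 2), "both conditions")
})

test_that("the preprocessing chain applies the stages in the fixed order", {
  cfg <- quick_cfg(n_channels = 4, n_epochs = 20, sfreq = 250,
                   epoch_window = c(-2, 3), seed = 6)
  out <- preprocess(simulate_epochs(cfg, 1, "N2", "VOICE"),
                    preprocessing_params(n_balance = 15, seed = 2))
  expect_match(paste(out$log, collapse = ";"),
               "bandpass.*crop.*decimate.*balance")
  expect_identical(dim(out$data), c(30L, 4L, 76L))
  expect_equal(out$sfreq, 62.5)
})
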