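test_that("penalized logistic fit matches a brute-force convex oracle", {
  # fixed 4-trial, 2-feature toy problem
  X4 <- matrix(c(-1, -0.5, 0.6, 1.2,
                 0.3, -0.8, 0.9, -0.2), ncol = 2)
  y4 <- c(0L, 0L, 1L, 1L)
  fit <- fit_timepoint(X4, y4)
  oracle <- logistic_oracle(X4, y4)
  expect_equal(c(fit$w, fit$b), c(oracle$w, oracle$b), tolerance = 1e-6)

  # randomized problems, several shapes and C values
  for (i in 1:5) {
    n <- c(10, 30, 20, 12, 50)[i]
    p <- c(2, 5, 8, 3, 4)[i]
    C <- c(1, 1, 0.5, 2, 1)[i]
    X <- vigildecode:::local_rng(100 + i,
                                 matrix(stats::rnorm(n * p), n, p))
    y <- rep(c(0L, 1L), length.out = n)
    fit <- fit_timepoint(X, y, classifier_spec(C = C))
    oracle <- logistic_oracle(X, y, C = C)
    expect_equal(c(fit$w, fit$b), c(oracle$w, oracle$b), tolerance = 1e-6)
  }
})

test_that("logistic fit behaves correctly on degenerate and separable data", {
  # 1-D separable data: perfect training accuracy, positive weight
  X <- matrix(rep(c(-1, 1), each = 50), ncol = 1)
  y <- rep(c(0L, 1L), each = 50)
  fit <- fit_timepoint(X, y)
  expect_gt(fit$w, 0)
  pred <- as.integer(drop(X %*% fit$w) + fit$b >= 0)
  expect_equal(mean(pred == y), 1)

  # shuffled labels give near-chance held-out accuracy
  set.seed(7)
  Xr <- matrix(rnorm(400), 200, 2)
  yr <- sample(rep(c(0L, 1L), 100))
  fit_null <- fit_timepoint(Xr[1:100, ], yr[1:100])
  pred <- as.integer(drop(Xr[101:200, ] %*% fit_null$w) + fit_null$b >= 0)
  expect_lt(abs(mean(pred == yr[101:200]) - 0.5), 3 * sqrt(0.25 / 100))

  expect_error(fit_timepoint(Xr, rep(0L, 200)), "both classes")
})

test_that("temporal generalization scores every train/test time pair", {
  # 2-time, 2-channel toy set with hand-computable decisions
  dec <- list(
    W = matrix(c(1, 0,
                 0, -1), nrow = 2, byrow = TRUE), # train time 1: w=(1,0); 2: (0,-1)
    b = c(0, 0.5), train_times = c(0.1, 0.2), covs = NULL,
    dval_diff = c(1, 1), scale_summary = NULL, state = "N2", subject = 1,
    channel_names = channel_layout(2)$names, layout = channel_layout(2),
    spec = classifier_spec()
  )
  class(dec) <- "fitted_decoder"
  # trials x channels x time: trial 1 (class 0), trial 2 (class 1)
  data <- array(0, dim = c(2, 2, 2))
  data[1, , 1] <- c(-1, 0)   # t1: w1 -> -1 (pred 0 ok), w2 -> 0.5 (pred 1 wrong)
  data[2, , 1] <- c(2, 2)    # t1: w1 -> 2 (pred 1 ok), w2 -> -1.5 (pred 0 wrong)
  data[1, , 2] <- c(1, 1)    # t2: w1 -> 1 (pred 1 wrong), w2 -> -0.5 (pred 0 ok)
  data[2, , 2] <- c(-2, -1)  # t2: w1 -> -2 (pred 0 wrong), w2 -> 1.5 (pred 1 ok)
  test <- epoch_set(data, c(0.1, 0.2), c(0L, 1L), "N2", 1, 10,
                    channel_layout(2))
  tg <- temporal_generalization(dec, test)
  expect_equal(tg$scores, matrix(c(1, 0, 0, 1), 2, 2))

  # inverting test labels flips every score
  test_inv <- test
  test_inv$labels <- 1L - test_inv$labels
  tg_inv <- temporal_generalization(dec, test_inv)
  expect_equal(tg_inv$scores, 1 - tg$scores)

  # channel mismatch errors
  bad <- toy_epochs(n_trials = 4, n_channels = 3, n_samples = 2, sfreq = 10)
  expect_error(temporal_generalization(dec, bad), "channels")
})

test_that("within-state decoding is seeded, stratified, and detects the peak", {
  cfg <- quick_cfg(n_channels = 8, n_epochs = 50, amplitude = 15, seed = 31)
  ep <- balance_epochs(simulate_epochs(cfg, 1, "N2", "VOICE"), 50, seed = 1)
  tg <- within_state_tgm(ep, seed = 5)
  tg2 <- within_state_tgm(ep, seed = 5)
  expect_identical(tg$scores, tg2$scores)
  tg3 <- within_state_tgm(ep, seed = 6)
  expect_false(identical(tg3$scores, tg$scores))

  # diagonal accuracy in the peak window beats the pre-stimulus baseline
  expect_gt(peak_window_summary(tg, c(0.25, 0.40)),
            peak_window_summary(tg, c(-0.19, -0.02)) + 0.2)
  expect_true(all(tg$scores >= 0 & tg$scores <= 1))
  expect_identical(dim(tg$scores), c(length(ep$times), length(ep$times)))

  tiny <- toy_epochs(n_trials = 2, labels = c(0L, 1L))
  expect_error(within_state_tgm(tiny, lowpass = NULL), "at least 2")
  unbal <- toy_epochs(n_trials = 9, labels = rep(c(0L, 1L), c(3, 6)))
  expect_error(within_state_tgm(unbal, lowpass = NULL), "balanced")
})

test_that("cross-state transfer follows the shared neural code", {
  cfg <- quick_cfg(n_channels = 8, n_epochs = 50, amplitude = 15, seed = 32,
                   states = c("N2", "N3", "WAKE"))
  epN2 <- balance_epochs(simulate_epochs(cfg, 1, "N2", "VOICE"), 50, 1)
  epN3 <- balance_epochs(simulate_epochs(cfg, 1, "N3", "VOICE"), 50, 1)
  epW <- balance_epochs(simulate_epochs(cfg, 1, "WAKE", "VOICE"), 50, 1)

  # shared planted pattern: above-chance transfer in the peak window
  ct <- cross_state_tgm(epN2, epN3)
  expect_gt(peak_window_summary(ct), 0.6)
  # no effect in the test state: chance-level transfer
  cw <- cross_state_tgm(epN2, epW)
  expect_lt(abs(peak_window_summary(cw) - 0.5), 0.1)
  expect_error(cross_state_tgm(epN2, epN2), "identical")

  # orthogonal topographies in the two states: chance-level transfer.
  # Build N3-like data whose planted center sits on the opposite pole.
  cfg_far <- quick_cfg(n_channels = 8, n_epochs = 50, amplitude = 15,
                       seed = 32, states = c("N2", "N3", "WAKE"))
  cfg_far$effects$VOICE$topography_center <- c(0, -0.45)
  cfg_far$effects$VOICE$topography_spread <- 0.15
  epN3_far <- balance_epochs(simulate_epochs(cfg_far, 1, "N3", "VOICE"),
                             50, 1)
  cfg_near <- cfg_far
  cfg_near$effects$VOICE$topography_center <- c(0, 0.45)
  epN2_near <- balance_epochs(simulate_epochs(cfg_near, 1, "N2", "VOICE"),
                              50, 1)
  ct_far <- cross_state_tgm(epN2_near, epN3_far)
  expect_lt(peak_window_summary(ct_far), 0.62)
})

test_that("peak-window summary averages exactly the in-window cells", {
  tg <- vigildecode:::new_tgm(
    matrix(1:9 / 10, 3, 3), train_times = c(0.1, 0.2, 0.3),
    test_times = c(0.1, 0.2, 0.3), train_state = "N2", test_state = "N2",
    subject = 1, n_folds = 2L
  )
  # 2x2 window: rows 2-3 x cols 2-3 -> cells {5, 6, 8, 9} / 10
  expect_equal(peak_window_summary(tg, c(0.15, 0.35)), mean(c(5, 6, 8, 9) / 10))
  # full extent: grand mean
  expect_equal(peak_window_summary(tg, c(0, 1)), mean(1:9 / 10))
  # constant matrix
  tg$scores[] <- 0.6
  expect_equal(peak_window_summary(tg, c(0.15, 0.35)), 0.6)
  expect_error(peak_window_summary(tg, c(0.8, 0.9)), "window")
})
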