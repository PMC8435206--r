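test_that("generated hypnograms honor the transition structure", {
  cfg <- synth_config(duration_h = 24)
  truth <- generate_hypnogram(cfg, seed = 71)
  expect_equal(nrow(truth), 21600)
  s <- truth$state
  # forbidden direct wake-to-REM transitions never occur
  expect_false(any(s[-1] == "R" & s[-length(s)] == "W"))
  # all three states occur and REM is the rarest
  counts <- table(factor(s, sleep_states()))
  expect_true(all(counts > 0))
  expect_equal(names(which.min(counts)), "R")
  # deterministic under seed
  expect_identical(truth$state, generate_hypnogram(cfg, seed = 71)$state)
  expect_false(identical(truth$state, generate_hypnogram(cfg, seed = 72)$state))
})

test_that("empirical bout durations track the configured lognormals", {
  # neutral light modulation so the configured distribution applies directly
  cfg <- synth_config(duration_h = 48, light_bout_mult = c(W = 1, NR = 1, R = 1))
  truth <- generate_hypnogram(cfg, seed = 73)
  r <- rle(truth$state)
  set.seed(74)
  for (st in sleep_states()) {
    # mean of epoch-rounded lognormal bout lengths, in epochs
    draws <- stats::rlnorm(40000, log(cfg$bout_median_s[st]), cfg$bout_sdlog[st])
    expected <- mean(pmax(1, round(draws / 4)))
    got <- mean(r$lengths[r$values == st])
    expect_equal(got, expected, tolerance = 0.10)
  }
})

test_that("degenerate configs are rejected", {
  expect_error(synth_config(transition = diag(3)), "absorbing")
  expect_error(synth_config(transition = matrix(1 / 2, 3, 3)), "rowSums")
})

test_that("signals carry the state-dependent spectral and EMG structure", {
  ds <- short_dataset()
  grid <- make_epoch_grid(ds$recording)
  fm <- feature_matrix(ds$recording, grid)
  st <- ds$truth$state
  expect_gt(mean(fm$ch1_delta[st == "NR"]), mean(fm$ch1_delta[st == "W"]))
  rms <- tapply(fm$emg_rms, st, mean)
  expect_true(rms[["W"]] > rms[["NR"]] && rms[["NR"]] > rms[["R"]])
})

test_that("default EMG passes the CV gate and a flat EMG fails it", {
  ds <- short_dataset()
  grid <- make_epoch_grid(ds$recording)
  expect_true(emg_quality(ds$recording, grid, quiet = TRUE)$passed)
  # flat config: no wake bursts, REM tone equal to NREM
  cfg_flat <- synth_config(duration_h = 0.5, wake_burst_sdlog = 0,
                           emg_sd = c(W = 1, NR = 0.25, R = 0.25))
  rec_flat <- generate_signals(ds$truth, cfg_flat, seed = 81)
  q <- emg_quality(rec_flat, grid, quiet = TRUE)
  expect_false(q$passed)
  expect_lt(q$cv, 1.67)
})

test_that("datasets are seeded end to end", {
  cfg <- synth_config(duration_h = 1 / 12)  # 5 min
  d1 <- suppressWarnings(generate_dataset(cfg, seed = 91, n_series = 3,
                                          series_length = 5, n_extra_rem = 0))
  d2 <- suppressWarnings(generate_dataset(cfg, seed = 91, n_series = 3,
                                          series_length = 5, n_extra_rem = 0))
  d3 <- suppressWarnings(generate_dataset(cfg, seed = 92, n_series = 3,
                                          series_length = 5, n_extra_rem = 0))
  expect_equal(nrow(d1$truth), 75)
  expect_identical(d1$recording$brain, d2$recording$brain)
  expect_identical(d1$training, d2$training)
  expect_false(identical(d1$recording$brain, d3$recording$brain))
  # training labels agree with the ground truth at the selected epochs
  expect_equal(d1$training$state, d1$truth$state[d1$training$epoch])
})
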