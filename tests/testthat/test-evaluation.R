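test_that("confusion tabulates (truth, prediction) pairs", {
  # truth (W, W, NR) scored as (W, NR, NR)
  cm <- confusion(pred = c("W", "NR", "NR"), truth = c("W", "W", "NR"))
  expect_equal(cm["W", "W"], 1L)
  expect_equal(cm["W", "NR"], 1L)
  expect_equal(cm["NR", "NR"], 1L)
  expect_equal(sum(cm), 3L)
  ident <- confusion(c("W", "NR", "R"), c("W", "NR", "R"))
  expect_equal(sum(diag(ident)), 3L)
  expect_error(confusion(c("W", "W"), c("W")), "length")
})

test_that("artifact mode drops truth-flagged epochs", {
  truth <- hypnogram(c("W", "NR", "R", "W"),
                     artifact = c(FALSE, TRUE, FALSE, TRUE))
  pred <- c("W", "W", "R", "NR")
  expect_equal(sum(confusion(pred, truth, "include_artifact")), 4L)
  cm <- confusion(pred, truth, "exclude_artifact")
  expect_equal(sum(cm), 2L)
  expect_equal(accuracy(cm), 100)
})

test_that("metrics reproduce hand-computed sensitivity and specificity", {
  cm <- matrix(c(80, 15, 5,
                 10, 85, 5,
                 4, 6, 90), 3, 3, byrow = TRUE,
               dimnames = list(truth = sleep_states(), pred = sleep_states()))
  class(cm) <- c("confusion_matrix", "matrix")
  rep <- metrics(cm)
  expect_equal(attr(rep, "accuracy"), 85.0)
  expect_equal(rep$sensitivity[rep$state == "R"], 90.0)
  expect_equal(rep$specificity[rep$state == "R"], 95.0)  # 190/200

  perfect <- confusion(rep(sleep_states(), 5), rep(sleep_states(), 5))
  prep <- metrics(perfect)
  expect_equal(attr(prep, "accuracy"), 100)
  expect_equal(prep$sensitivity, rep(100, 3))
  expect_equal(prep$specificity, rep(100, 3))

  g <- glance(prep)
  expect_equal(g$accuracy, 100)
  expect_named(g, c("accuracy", "total", "sens_W", "spec_W", "sens_NR",
                    "spec_NR", "sens_R", "spec_R"))
})

test_that("metrics agree with the counting oracle and are order-invariant", {
  set.seed(50)
  for (i in 1:40) {
    n <- sample(20:80, 1)
    truth <- sample(sleep_states(), n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.7, truth, sample(sleep_states(), n, TRUE))
    rep <- suppressWarnings(metrics(confusion(pred, truth)))
    oracle <- naive_metrics(pred, truth)
    expect_equal(attr(rep, "accuracy"), oracle$accuracy)
    for (st in sleep_states()) {
      expect_equal(rep$sensitivity[rep$state == st], oracle[[paste0("sens_", st)]])
      expect_equal(rep$specificity[rep$state == st], oracle[[paste0("spec_", st)]])
    }
    perm <- sample(n)
    rep_p <- suppressWarnings(metrics(confusion(pred[perm], truth[perm])))
    expect_equal(rep_p$sensitivity, rep$sensitivity)
    expect_equal(rep_p$specificity, rep$specificity)
  }
  # absent truth state: undefined sensitivity is NA, not zero
  rep_na <- suppressWarnings(metrics(confusion(c("W", "NR"), c("W", "NR"))))
  expect_true(is.na(rep_na$sensitivity[rep_na$state == "R"]))
})

test_that("state spectra are normalized and scale-invariant", {
  cfg <- synth_config(duration_h = 1/30)
  truth <- hypnogram(rep(c("NR", "W", "R"), 10))
  rec <- generate_signals(truth, cfg, seed = 61)
  grid <- make_epoch_grid(rec)
  sp <- state_spectra(rec, grid, truth)
  expect_setequal(unique(sp$state), sleep_states())
  # NREM dominates wake in the slow-wave band
  df <- attr(welch_psd(rec$brain[1:1000, 1], 250), "df")
  swa_of <- function(st) {
    sub <- sp[sp$channel == "ch1" & sp$state == st, ]
    sum(sub$power_norm[sub$frequency >= 0.5 & sub$frequency < 4]) * df
  }
  expect_gt(swa_of("NR"), swa_of("W"))
  # doubling amplitudes leaves normalized spectra unchanged
  rec2 <- rec
  rec2$brain <- rec$brain * 2
  sp2 <- state_spectra(rec2, grid, truth)
  expect_equal(sp2$power_norm, sp$power_norm, tolerance = 1e-10)
  # single-state recording self-normalizes to broadband integral 1
  mono <- suppressWarnings(state_spectra(rec, grid, rep("W", grid$n_epochs)))
  sub <- mono[mono$channel == "ch1", ]
  expect_equal(sum(sub$power_norm[sub$frequency >= 0.5]) * df, 1,
               tolerance = 1e-10)
  expect_warning(state_spectra(rec, grid, rep(c("W", "NR"), 15)), "R")
})

test_that("SWA timecourse normalizes to the light-period mean and declines", {
  # programmed homeostatic decline over a 3 h light period
  cfg <- synth_config(duration_h = 3, n_brain = 1, light_hours = 3,
                      swa_start = 1.5, swa_end = 0.5)
  truth <- generate_hypnogram(cfg, seed = 62)
  rec <- generate_signals(truth, cfg, seed = 63)
  grid <- make_epoch_grid(rec)
  swa <- swa_timecourse(rec, grid, truth, light_hours = 3)
  expect_equal(nrow(swa), 3)
  expect_equal(mean(swa$swa, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_true(all(diff(swa$swa) < 0))
  expect_error(swa_timecourse(rec, grid, rep("W", grid$n_epochs)), "NREM")
})

test_that("durations and bout statistics enumerate runs correctly", {
  h <- hypnogram(c("W", "W", "NR", "NR", "NR", "R"))
  d <- durations_and_bouts(h)
  expect_equal(d$total_min * 60, c(8, 12, 4))
  expect_equal(d$mean_bout_s, c(8, 12, 4))
  expect_equal(d$n_bouts, c(1L, 1L, 1L))
  # all epochs fall in the light period here; totals partition the recording
  expect_equal(sum(d$light_min) + sum(d$dark_min), 6 * 4 / 60)

  allw <- durations_and_bouts(hypnogram(rep("W", 100)))
  expect_equal(allw$n_bouts, c(1L, 0L, 0L))
  expect_equal(allw$mean_bout_s[1], 400)
  expect_true(is.na(allw$mean_bout_s[2]))
})
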