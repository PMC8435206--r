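test_that("default training selection yields 560 spread-out epochs", {
  # label oracle: a full-day ground-truth hypnogram (cheap, no signals)
  truth <- generate_hypnogram(synth_config(duration_h = 24), seed = 17)
  expect_equal(nrow(truth), 21600)
  sel <- select_training_epochs(21600, truth, seed = 3)
  expect_length(sel, 560)
  expect_equal(length(sel) / 21600 * 100, 2.6, tolerance = 0.01)
  expect_false(anyDuplicated(sel) > 0)
  # all three states are covered
  expect_setequal(unique(truth$state[sel]), sleep_states())
  # series starts spread over the day: every 2 h bin holds selected epochs
  expect_true(all(table(cut(sel, breaks = seq(0, 21600, by = 1800))) > 0))
  # deterministic under seed, different under another
  expect_identical(sel, select_training_epochs(21600, truth, seed = 3))
  expect_false(identical(sel, select_training_epochs(21600, truth, seed = 4)))
})

test_that("selection warns when REM epochs are scarce", {
  labels <- rep(c("W", "NR"), 500)
  labels[c(3, 700)] <- "R"
  expect_warning(
    sel <- select_training_epochs(1000, labels, n_series = 5,
                                  n_extra_rem = 60, seed = 2),
    "REM epochs available")
  expect_lte(sum(labels[sel] == "R"), 2 + 50)
})

test_that("oversampling balances to the majority count without new rows", {
  set.seed(21)
  ts <- tibble::tibble(
    epoch = 1:560,
    state = rep(c("W", "NR", "R"), c(300, 200, 60)),
    f1 = rnorm(560), f2 = rnorm(560))
  attr(ts, "balanced") <- FALSE
  bal <- oversample_balance(ts, seed = 5)
  expect_equal(unname(table(bal$state)[sleep_states()]),
               rep(300L, 3), ignore_attr = TRUE)
  # resampled rows duplicate existing rows of the same class
  for (st in c("NR", "R")) {
    orig <- ts[ts$state == st, ]
    expect_true(all(bal$epoch[bal$state == st] %in% orig$epoch))
    expect_setequal(unique(bal$epoch[bal$state == st]), orig$epoch)
  }
  # already balanced input is returned unchanged
  bal2 <- oversample_balance(bal, seed = 6)
  expect_equal(nrow(bal2), nrow(bal))
  ts_miss <- ts[ts$state != "R", ]
  expect_error(oversample_balance(ts_miss), "no training examples")
})

test_that("training learns a separable 3-class problem to >=99% accuracy", {
  ts <- blob_training_set(n_per_class = 100, seed = 11)
  net <- train_network(ts, network_spec(), seed = 1)
  expect_gte(tail(net$accuracy, 1), 0.99)
  # loss decreases overall
  expect_lt(tail(net$loss, 1), net$loss[1])
  # determinism under seed
  net2 <- train_network(ts, network_spec(), seed = 1)
  expect_identical(net$W, net2$W)
  expect_false(identical(net$W, train_network(ts, network_spec(), seed = 2)$W))

  # independent reference classifier solves the same problem equally well
  skip_if_not_installed("nnet")
  fit <- nnet::nnet(factor(state) ~ f1 + f2 + f3 + f4, data = ts, size = 8,
                    trace = FALSE, maxit = 200)
  expect_gte(mean(predict(fit, ts, type = "class") == ts$state), 0.99)
})

test_that("ensemble members are distinct but agree on easy data", {
  ts <- blob_training_set(n_per_class = 60, seed = 12)
  ens <- train_ensemble(ts, network_spec(passes = 40), seed = 3)
  expect_length(ens$members, 5)
  for (i in 1:4) {
    expect_false(identical(ens$members[[i]]$W, ens$members[[i + 1]]$W))
  }
  pred <- predict(ens, ts)
  expect_gte(mean(pred$state == ts$state), 0.99)
  expect_gte(mean(pred$certainty >= 0.9), 0.9)
  # mean probability vectors live on the simplex
  expect_equal(pred$p_W + pred$p_NR + pred$p_R, rep(1, nrow(pred)),
               tolerance = 1e-6)
})

test_that("prediction takes the modal vote with mean-probability tie-break", {
  # five constant members voting (W, W, W, NR, R)
  ens <- constant_ensemble(list(c(.8, .1, .1), c(.6, .3, .1), c(.5, .3, .2),
                                c(.2, .7, .1), c(.1, .2, .7)))
  pred <- predict(ens, zscored_frame(3))
  expect_equal(unique(pred$state), "W")
  # certainty = mean probability of the modal class
  expect_equal(pred$certainty, rep(mean(c(.8, .6, .5, .2, .1)), 3))
  expect_true(all(pred$uncertain))  # 0.44 < 0.90

  # 2-2-1 vote: tie between W and NR broken by higher mean probability
  ens2 <- constant_ensemble(list(c(.6, .3, .1), c(.55, .35, .1),
                                 c(.2, .75, .05), c(.25, .7, .05),
                                 c(.2, .2, .6)))
  pred2 <- predict(ens2, zscored_frame(1))
  expect_equal(pred2$state, "NR")  # mean p_NR = .46 > mean p_W = .36

  # threshold boundary: certainty exactly at threshold is not uncertain
  ens3 <- constant_ensemble(rep(list(c(.92, .05, .03)), 5))
  expect_false(predict(ens3, zscored_frame(1))$uncertain)
  expect_true(predict(ens3, zscored_frame(1),
                      certainty_threshold = 0.95)$uncertain)
})

test_that("prediction is invariant to member order and checks features", {
  ens <- constant_ensemble(list(c(.8, .1, .1), c(.1, .8, .1), c(.1, .1, .8),
                                c(.7, .2, .1), c(.2, .7, .1)))
  p1 <- predict(ens, zscored_frame(4))
  ens_rev <- ens
  ens_rev$members <- rev(ens$members)
  p2 <- predict(ens_rev, zscored_frame(4))
  expect_equal(p1$state, p2$state)
  expect_equal(p1$certainty, p2$certainty)
  bad <- zscored_frame(4, n_features = 1)
  expect_error(predict(ens, bad), "feature mismatch")
})

test_that("tidy/glance expose training trajectories and summary", {
  ts <- blob_training_set(n_per_class = 30, seed = 13)
  ens <- train_ensemble(ts, network_spec(passes = 15), seed = 4)
  td <- tidy(ens)
  expect_equal(nrow(td), 5 * 15)
  expect_named(td, c("member", "pass", "loss", "accuracy"))
  g <- glance(ens)
  expect_equal(g$n_members, 5)
  expect_equal(g$architecture, "256-128-32-3")
})

test_that("ensemble serialization round-trips predictions exactly", {
  ts <- blob_training_set(n_per_class = 30, seed = 14)
  ens <- train_ensemble(ts, network_spec(passes = 10), seed = 5)
  dir <- file.path(tempdir(), "bundle")
  save_ensemble(ens, dir)
  back <- load_ensemble(dir)
  p1 <- predict(ens, ts)
  p2 <- predict(back, ts)
  expect_equal(p1$state, p2$state)
  expect_equal(p1$certainty, p2$certainty, tolerance = 1e-12)
})
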