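test_that("REM gap filling rescores short bounded gaps only", {
  expect_equal(fill_rem_gaps(c("R", "R", "W", "W", "W", "R")),
               rep("R", 6))                      # 12 s gap: filled
  expect_equal(fill_rem_gaps(c("R", "W", "W", "W", "W", "R")),
               c("R", "W", "W", "W", "W", "R"))  # 16 s gap: kept
  # mixed W/NR gaps are filled by default ...
  expect_equal(fill_rem_gaps(c("R", "W", "NR", "R")), rep("R", 4))
  # ... but not under the conservative pure-run reading
  expect_equal(fill_rem_gaps(c("R", "W", "NR", "R"), mixed_gap_runs = FALSE),
               c("R", "W", "NR", "R"))
  expect_equal(fill_rem_gaps(c("R", "NR", "NR", "R"), mixed_gap_runs = FALSE),
               rep("R", 4))
  # boundary runs are never altered
  expect_equal(fill_rem_gaps(c("W", "R", "R")), c("W", "R", "R"))
  expect_equal(fill_rem_gaps(c("R", "R", "W")), c("R", "R", "W"))
})

test_that("wake-to-REM transitions are rescored as wake", {
  expect_equal(forbid_wake_to_rem(c("W", "R", "R", "NR")),
               c("W", "W", "W", "NR"))           # whole run rescored
  expect_equal(forbid_wake_to_rem(c("W", "R", "R", "NR"),
                                  rescore_whole_run = FALSE),
               c("W", "W", "R", "NR"))           # literal single-epoch rule
  expect_equal(forbid_wake_to_rem(c("NR", "R", "R")), c("NR", "R", "R"))
  expect_equal(forbid_wake_to_rem(c("R", "R", "W")), c("R", "R", "W"))
})

test_that("isolated single epochs are smoothed in one simultaneous pass", {
  expect_equal(smooth_isolated(c("NR", "W", "NR")), rep("NR", 3))
  expect_equal(smooth_isolated(c("NR", "W", "W", "NR")),
               c("NR", "W", "W", "NR"))          # run of 2 is not isolated
  expect_equal(smooth_isolated(c("W", "NR", "R")), c("W", "NR", "R"))
  # decisions are simultaneous on the input labels, not sequential
  expect_equal(smooth_isolated(c("W", "NR", "W", "NR", "W")),
               c("W", "W", "NR", "W", "W"))
})

test_that("composite heuristics reach an idempotent fixed point", {
  h <- hypnogram(c("R", "R", "W", "NR", "R", "W", "R", "R", "NR", "NR"))
  once <- apply_heuristics(h)
  twice <- apply_heuristics(once)
  expect_equal(once$state, twice$state)
  expect_equal(apply_heuristics(rep("NR", 20)), rep("NR", 20))
  # output scans clean: no W->R transition, no fillable REM gap, no isolates
  set.seed(40)
  for (i in 1:25) {
    s <- apply_heuristics(sample(sleep_states(), 200, replace = TRUE))
    n <- length(s)
    expect_false(any(s[-1] == "R" & s[-n] == "W"))
    expect_identical(s, fill_rem_gaps(s))
    expect_identical(s, smooth_isolated(s))
  }
})

test_that("rules preserve length/alphabet and move REM monotonically", {
  set.seed(41)
  for (i in 1:50) {
    s <- sample(sleep_states(), 60, replace = TRUE)
    f <- fill_rem_gaps(s)
    w <- forbid_wake_to_rem(s)
    expect_length(f, 60)
    expect_true(all(c(f, w) %in% sleep_states()))
    expect_gte(sum(f == "R"), sum(s == "R"))
    expect_lte(sum(w == "R"), sum(s == "R"))
  }
})

test_that("random hypnograms match the brute-force fixpoint oracle", {
  set.seed(42)
  for (i in 1:30) {
    s <- sample(sleep_states(), 200, replace = TRUE,
                prob = c(0.4, 0.4, 0.2))
    expect_identical(apply_heuristics(s), naive_heuristics(s))
  }
})

test_that("manual rescoring replaces only uncertain epochs", {
  pred <- hypnogram(c("W", "W", "NR", "R", "NR"),
                    certainty = c(.99, .5, .97, .6, .95),
                    uncertain = c(FALSE, TRUE, FALSE, TRUE, FALSE))
  merged <- merge_manual_rescore(pred, data.frame(epoch = c(2, 4),
                                                  state = c("NR", "NR")),
                                 heuristics = FALSE)
  expect_equal(merged$state, c("W", "NR", "NR", "NR", "NR"))
  expect_equal(merged$certainty[c(2, 4)], c(1, 1))
  expect_false(any(merged$uncertain))
  # labels for confident epochs violate the triage contract
  expect_error(merge_manual_rescore(pred, data.frame(epoch = 1, state = "R")),
               "not flagged")
  # no uncertain epochs and no labels: unchanged
  sure <- hypnogram(c("W", "NR"), uncertain = c(FALSE, FALSE))
  expect_equal(merge_manual_rescore(sure, data.frame(epoch = integer(0),
                                                     state = character(0)),
                                    heuristics = FALSE)$state,
               sure$state)
})
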