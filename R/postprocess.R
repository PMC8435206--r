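#' Fill short non-REM gaps inside REM sleep
#'
#' Rescores every maximal run of non-REM labels (wake and/or NREM, any
#' mixture by default) of duration at most `max_gap_s` that is bounded by
#' REM on both sides as REM, restoring REM-bout continuity. Runs touching
#' the recording boundary are never altered.
#'
#' @param h A [hypnogram()] or character state vector.
#' @param max_gap_s Maximum gap duration to fill, seconds (default 12,
#'   i.e. 3 epochs of 4 s).
#' @param mixed_gap_runs If `FALSE`, only gaps consisting of a single state
#'   (all `W` or all `NR`) are filled (the conservative reading).
#' @return Same type as `h`, with states amended.
#' @export
fill_rem_gaps <- function(h, max_gap_s = 12, mixed_gap_runs = TRUE) {
  s <- states_of(h)
  max_ep <- floor(max_gap_s / epoch_len_of(h))
  if (max_ep < 1 || length(s) < 3) return(h)
  r <- rle(s == "R")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] || r$lengths[k] > max_ep) next
    if (k == 1L || k == length(r$values)) next        # boundary gap
    gap <- starts[k]:ends[k]
    if (!mixed_gap_runs && length(unique(s[gap])) > 1L) next
    s[gap] <- "R"
  }
  set_states(h, s)
}

#' Forbid wake-to-REM transitions
#'
#' Direct wake-to-REM transitions are exceptionally rare outside pathology,
#' so REM scored immediately after waking is rescored as waking. By default
#' the whole REM run following the wake epoch is rescored (the fixpoint of
#' repeatedly applying the single-epoch rule); set
#' `rescore_whole_run = FALSE` for the literal one-epoch version. REM runs
#' preceded by NREM, or starting the recording, are untouched.
#'
#' @inheritParams fill_rem_gaps
#' @param rescore_whole_run Rescore the full REM run (default) or only its
#'   first epoch.
#' @return Same type as `h`.
#' @export
forbid_wake_to_rem <- function(h, rescore_whole_run = TRUE) {
  s <- states_of(h)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] != "R" || k == 1L) next
    if (r$values[k - 1L] != "W") next
    if (rescore_whole_run) s[starts[k]:ends[k]] <- "W" else s[starts[k]] <- "W"
  }
  set_states(h, s)
}

#' Smooth isolated single epochs
#'
#' A lone epoch whose two neighbors agree with each other but differ from it
#' is rescored to match them. All decisions are taken simultaneously on the
#' input labels (one pass); the first and last epochs are never altered.
#'
#' @inheritParams fill_rem_gaps
#' @return Same type as `h`.
#' @export
smooth_isolated <- function(h) {
  s <- states_of(h)
  n <- length(s)
  if (n < 3) return(h)
  i <- 2:(n - 1)
  iso <- s[i - 1] == s[i + 1] & s[i] != s[i - 1]
  out <- s
  out[i][iso] <- s[i - 1][iso]
  set_states(h, out)
}

#' Apply all hypnogram heuristics to a fixed point
#'
#' Runs [fill_rem_gaps()], [forbid_wake_to_rem()], then [smooth_isolated()]
#' in that order, repeating the full cycle until nothing changes. The
#' composite is therefore idempotent; a guard of `n_epochs` cycles protects
#' against (unreachable) non-termination.
#'
#' @inheritParams fill_rem_gaps
#' @inheritParams forbid_wake_to_rem
#' @param rules Character subset of `c("rem_gap", "wake_rem", "isolated")`
#'   selecting which rules run.
#' @return Same type as `h`.
#' @export
#' @examples
#' apply_heuristics(hypnogram(c("R", "R", "W", "NR", "R", "W", "R", "R")))
apply_heuristics <- function(h, max_gap_s = 12, mixed_gap_runs = TRUE,
                             rescore_whole_run = TRUE,
                             rules = c("rem_gap", "wake_rem", "isolated")) {
  rules <- match.arg(rules, several.ok = TRUE)
  s <- states_of(h)
  for (cycle in seq_len(length(s) + 1L)) {
    before <- s
    if ("rem_gap" %in% rules) s <- fill_rem_gaps(s, max_gap_s, mixed_gap_runs)
    if ("wake_rem" %in% rules) s <- forbid_wake_to_rem(s, rescore_whole_run)
    if ("isolated" %in% rules) s <- smooth_isolated(s)
    if (identical(s, before)) return(set_states(h, s))
  }
  stop("heuristic rules failed to reach a fixed point")  # unreachable
}

#' Merge manual rescoring of uncertain epochs
#'
#' Takes the automated prediction and a partial manual hypnogram covering
#' (a subset of) the uncertain-flagged epochs, replaces those epochs with the
#' manual labels (certainty 1, flag cleared), and re-applies the heuristic
#' rules. Supplying a manual label for an epoch that was not flagged
#' uncertain is an error: triage only offers the low-certainty subset for
#' rescoring.
#'
#' @param pred Predicted [hypnogram()] with `certainty` and `uncertain`
#'   columns (from [predict.sleep_ensemble()]).
#' @param manual Data frame with columns `epoch` and `state` covering
#'   uncertain epochs only.
#' @param heuristics Re-apply [apply_heuristics()] afterwards (default).
#' @param ... Passed to [apply_heuristics()].
#' @return The merged hypnogram.
#' @export
merge_manual_rescore <- function(pred, manual, heuristics = TRUE, ...) {
  stopifnot(is.data.frame(pred), "uncertain" %in% names(pred),
            is.data.frame(manual), all(c("epoch", "state") %in% names(manual)))
  assert_states(manual$state, "manual state")
  pos <- match(manual$epoch, pred$epoch)
  if (anyNA(pos)) stop("manual labels reference unknown epochs")
  not_flagged <- !pred$uncertain[pos]
  if (any(not_flagged)) {
    stop("manual labels supplied for epochs not flagged uncertain: ",
         paste(utils::head(manual$epoch[not_flagged], 5), collapse = ", "))
  }
  pred$state[pos] <- manual$state
  if ("certainty" %in% names(pred)) pred$certainty[pos] <- 1
  pred$uncertain[pos] <- FALSE
  if (heuristics) pred <- apply_heuristics(pred, ...)
  pred
}
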