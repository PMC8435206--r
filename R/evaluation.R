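#' Confusion matrix between predicted and manual hypnograms
#'
#' @param pred,truth Hypnograms (or character state vectors) of equal
#'   length. Rows of the result are manual (truth) states, columns are
#'   predicted states, in the fixed W/NR/R order.
#' @param mode `"include_artifact"` keeps every epoch;
#'   `"exclude_artifact"` drops epochs flagged as artifact in `truth`.
#' @return 3 x 3 integer matrix of class `confusion_matrix` with attributes
#'   `total` and `mode`.
#' @export
confusion <- function(pred, truth, mode = c("include_artifact", "exclude_artifact")) {
  mode <- match.arg(mode)
  p <- states_of(pred)
  t_ <- states_of(truth)
  if (length(p) != length(t_)) stop("pred and truth differ in length")
  if (mode == "exclude_artifact" && is.data.frame(truth) &&
      !is.null(truth$artifact)) {
    keep <- !truth$artifact %in% TRUE
    p <- p[keep]
    t_ <- t_[keep]
  }
  cm <- table(factor(t_, sleep_states()), factor(p, sleep_states()))
  cm <- matrix(as.integer(cm), 3, 3,
               dimnames = list(truth = sleep_states(), pred = sleep_states()))
  structure(cm, total = sum(cm), mode = mode, class = c("confusion_matrix", "matrix"))
}

#' Accuracy, sensitivity and specificity from a confusion matrix
#'
#' Overall accuracy is the percentage of identically scored epochs
#' (trace/total). Per state, one-vs-rest: sensitivity = TP/(TP + FN),
#' specificity = TN/(TN + FP), both in percent. A state absent from the
#' truth yields `NA` sensitivity (undefined, not zero).
#'
#' @param cm A [confusion()] matrix.
#' @return Tibble of class `performance_report`, one row per state with
#'   columns `state`, `sensitivity`, `specificity`, `n_truth`; attributes
#'   `accuracy` (percent), `total`, `mode`.
#' @export
metrics <- function(cm) {
  total <- attr(cm, "total") %||% sum(cm)
  if (total == 0) stop("empty confusion matrix")
  acc <- 100 * sum(diag(cm)) / total
  rows <- lapply(seq_len(3), function(s) {
    tp <- cm[s, s]
    fn <- sum(cm[s, ]) - tp
    fp <- sum(cm[, s]) - tp
    tn <- total - tp - fn - fp
    tibble(
      state = sleep_states()[s],
      sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
      n_truth = as.integer(tp + fn)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (anyNA(out$sensitivity)) {
    warning("state(s) absent from truth: sensitivity undefined (NA)",
            call. = FALSE)
  }
  attr(out, "accuracy") <- acc
  attr(out, "total") <- total
  attr(out, "mode") <- attr(cm, "mode")
  class(out) <- c("performance_report", class(out))
  out
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance_report> accuracy %.2f%% over %d epochs (%s)\n",
              attr(x, "accuracy"), attr(x, "total"),
              attr(x, "mode") %||% "include_artifact"))
  NextMethod()
}

#' Overall accuracy of a report or confusion matrix
#' @param x A `performance_report` or `confusion_matrix`.
#' @return Accuracy in percent.
#' @export
accuracy <- function(x) {
  if (inherits(x, "confusion_matrix")) return(100 * sum(diag(x)) / sum(x))
  attr(x, "accuracy")
}

#' One-row wide summary of a performance report
#' @param x A [metrics()] report.
#' @param ... Unused.
#' @export
glance.performance_report <- function(x, ...) {
  wide <- tibble(accuracy = attr(x, "accuracy"), total = attr(x, "total"))
  for (i in seq_len(nrow(x))) {
    wide[[paste0("sens_", x$state[i])]] <- x$sensitivity[i]
    wide[[paste0("spec_", x$state[i])]] <- x$specificity[i]
  }
  wide
}

#' State-dependent normalized power spectra
#'
#' Welch spectra are averaged over all epochs of each behavioral state and,
#' to remove overall signal-strength differences, divided by the mean
#' broadband (0.5-125 Hz) power of the channel across all epochs. A state
#' with no epochs is omitted with a warning.
#'
#' @inheritParams feature_matrix
#' @param hyp State labels (hypnogram or character vector), one per epoch.
#' @return Tibble of class `state_spectra`: `channel`, `state`, `frequency`,
#'   `power_norm`.
#' @export
state_spectra <- function(rec, grid, hyp,
                          segment_length = round(2 * rec$sampling_rate),
                          overlap = 0.5) {
  s <- states_of(hyp)
  stopifnot(length(s) == grid$n_epochs)
  present <- sleep_states()[sleep_states() %in% s]
  absent <- setdiff(sleep_states(), present)
  if (length(absent)) {
    warning("no epochs for state(s): ", paste(absent, collapse = ", "),
            call. = FALSE)
  }
  out <- purrr::map_dfr(seq_len(ncol(rec$brain)), function(ch) {
    res <- welch_psd_epochs(rec$brain[, ch], grid$starts,
                            grid$samples_per_epoch, rec$sampling_rate,
                            segment_length, overlap)
    bb <- band_bins(res$frequency, BROADBAND[1], BROADBAND[2], TRUE)
    norm <- mean(colSums(res$psd[bb, , drop = FALSE]) * res$df)
    purrr::map_dfr(present, function(st) {
      tibble(channel = colnames(rec$brain)[ch], state = st,
             frequency = res$frequency,
             power_norm = rowMeans(res$psd[, s == st, drop = FALSE]) / norm)
    })
  })
  class(out) <- c("state_spectra", class(out))
  out
}

# hour-of-recording (1-based) each epoch starts in, and whether it is in the
# light period, given the recording's clock metadata
epoch_light_phase <- function(rec, n_epochs, epoch_length_s) {
  t0 <- (rec$start_time %||% 0)
  onset <- (rec$light_onset %||% 0)
  hours <- (seq_len(n_epochs) - 1) * epoch_length_s / 3600
  clock <- (t0 + hours) %% 24
  since_onset <- (clock - onset) %% 24
  list(hour = floor(hours) + 1L,
       light = since_onset < (rec$light_hours %||% 12),
       light_hour = ifelse(since_onset < (rec$light_hours %||% 12),
                           floor(since_onset) + 1L, NA_integer_))
}

#' Hourly slow-wave-activity timecourse
#'
#' Slow-wave activity (SWA, 0.5-4 Hz power during NREM sleep) is the
#' canonical marker of sleep homeostasis and declines across the rest
#' (light) period. For each light-period hour this computes the mean 0.5-4 Hz
#' band power over that hour's NREM epochs (averaged across brain channels)
#' and normalizes by the light-period mean, so values average to 1 over the
#' non-missing hours. Hours without NREM yield `NA` and are excluded from
#' the normalizing mean.
#'
#' @inheritParams state_spectra
#' @param light_hours Light-period duration in hours (default 12; truncated
#'   to the recording length).
#' @return Tibble of class `swa_timecourse`: `hour`, `swa` (normalized),
#'   `n_nrem`.
#' @export
swa_timecourse <- function(rec, grid, hyp, light_hours = 12,
                           segment_length = round(2 * rec$sampling_rate),
                           overlap = 0.5) {
  s <- states_of(hyp)
  stopifnot(length(s) == grid$n_epochs)
  ph <- epoch_light_phase(rec, grid$n_epochs, grid$epoch_length_s)
  if (all(is.na(ph$light_hour))) stop("light period not within the recording")
  lh <- min(light_hours, max(ph$light_hour, na.rm = TRUE))
  swa_ep <- rep(0, grid$n_epochs)
  for (ch in seq_len(ncol(rec$brain))) {
    res <- welch_psd_epochs(rec$brain[, ch], grid$starts,
                            grid$samples_per_epoch, rec$sampling_rate,
                            segment_length, overlap)
    sel <- band_bins(res$frequency, SWA_BAND[1], SWA_BAND[2])
    swa_ep <- swa_ep + colSums(res$psd[sel, , drop = FALSE]) * res$df / ncol(rec$brain)
  }
  use <- s == "NR" & !is.na(ph$light_hour)
  if (!any(use)) stop("no NREM epochs in the light period; SWA undefined")
  hourly <- vapply(seq_len(lh), function(h) {
    v <- swa_ep[use & ph$light_hour == h]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  n_nrem <- vapply(seq_len(lh), function(h) sum(use & ph$light_hour == h), 0L)
  out <- tibble(hour = seq_len(lh), swa = hourly / mean(hourly, na.rm = TRUE),
                n_nrem = n_nrem)
  class(out) <- c("swa_timecourse", class(out))
  out
}

#' State durations and bout statistics
#'
#' Total time per state in the light and dark periods (per-epoch
#' attribution, so bouts spanning the boundary are split proportionally)
#' and mean bout duration per state over the whole recording, where a bout
#' is a maximal run of consecutive same-state epochs.
#'
#' @inheritParams swa_timecourse
#' @param hyp A hypnogram (or character state vector).
#' @param rec Optional recording supplying the light schedule; when `NULL`
#'   the recording is assumed to start at light onset.
#' @param epoch_length_s Used when `hyp` is a bare character vector.
#' @return Tibble: `state`, `light_min`, `dark_min`, `total_min`,
#'   `n_bouts`, `mean_bout_s`.
#' @export
durations_and_bouts <- function(hyp, rec = NULL, light_hours = 12,
                                epoch_length_s = 4) {
  s <- states_of(hyp)
  el <- if (is.data.frame(hyp)) epoch_len_of(hyp) else epoch_length_s
  ph <- epoch_light_phase(rec %||% list(start_time = 0, light_onset = 0,
                                        light_hours = light_hours),
                          length(s), el)
  r <- rle(s)
  purrr::map_dfr(sleep_states(), function(st) {
    in_st <- s == st
    bouts <- r$lengths[r$values == st]
    tibble(
      state = st,
      light_min = sum(in_st & ph$light) * el / 60,
      dark_min = sum(in_st & !ph$light) * el / 60,
      total_min = sum(in_st) * el / 60,
      n_bouts = length(bouts),
      mean_bout_s = if (length(bouts)) mean(bouts) * el else NA_real_
    )
  })
}

#' Apply a trained ensemble to another recording
#'
#' Cross-day / cross-animal generalization: the new recording's features are
#' computed and z-scored with its *own* statistics (keeping the feature
#' distribution comparable to the training day), the ensemble predicts every
#' epoch without retraining, the heuristic rules are applied, and the result
#' is scored against the supplied manual hypnogram.
#'
#' @param model A [train_ensemble()] model.
#' @param rec The new recording.
#' @param truth Its manual (or ground-truth) hypnogram.
#' @param heuristics Apply [apply_heuristics()] to the prediction.
#' @param mode Artifact handling, see [confusion()].
#' @param epoch_length_s Epoch length for the new recording's grid.
#' @return A [metrics()] report; the prediction hypnogram is attached as
#'   attribute `"prediction"`.
#' @export
generalize <- function(model, rec, truth, heuristics = TRUE,
                       mode = "include_artifact", epoch_length_s = 4) {
  grid <- make_epoch_grid(rec, epoch_length_s)
  fm <- feature_matrix(rec, grid)
  if (!setequal(feature_cols(fm), model$features)) {
    stop("feature mismatch: the recording yields different features than ",
         "the model was trained on (different brain-channel count?)")
  }
  fmz <- zscore_features(fm)
  pred <- predict(model, fmz)
  if (heuristics) pred <- apply_heuristics(pred)
  rep <- metrics(confusion(pred, truth, mode))
  attr(rep, "prediction") <- pred
  rep
}
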