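#' Partition a recording into fixed-length scoring epochs
#'
#' Sleep is scored in fixed windows ("epochs", conventionally 4 s in rodent
#' work). Epoch `i` covers the half-open sample range
#' `[i * L, (i + 1) * L)` (0-based), where `L = epoch_length_s * rate`.
#' A trailing partial epoch is dropped with a warning: padding would distort
#' the epoch spectra.
#'
#' @param rec A [new_recording()] object.
#' @param epoch_length_s Epoch length in seconds (default 4).
#' @return An `epoch_grid`: list with `n_epochs`, `epoch_length_s`,
#'   `samples_per_epoch`, and `starts` (0-based start sample of each epoch).
#' @export
#' @examples
#' rec <- new_recording(rnorm(2500), rnorm(2500), 250)
#' make_epoch_grid(rec)  # 2 epochs, 2 s dropped
make_epoch_grid <- function(rec, epoch_length_s = 4) {
  stopifnot(epoch_length_s > 0)
  spe <- epoch_length_s * rec$sampling_rate
  if (spe != round(spe)) stop("epoch_length_s x sampling_rate must be an integer")
  spe <- as.integer(round(spe))
  n <- n_samples(rec)
  if (spe > n) stop("epoch is longer than the recording")
  n_epochs <- n %/% spe
  dropped <- n - n_epochs * spe
  if (dropped > 0) {
    warning(sprintf("dropping trailing partial epoch: %d samples (%.3g s)",
                    dropped, dropped / rec$sampling_rate), call. = FALSE)
  }
  structure(
    list(n_epochs = n_epochs, epoch_length_s = epoch_length_s,
         samples_per_epoch = spe,
         starts = (seq_len(n_epochs) - 1L) * spe),
    class = "epoch_grid"
  )
}

#' @export
print.epoch_grid <- function(x, ...) {
  cat(sprintf("<epoch_grid> %d epochs x %g s (%d samples each)\n",
              x$n_epochs, x$epoch_length_s, x$samples_per_epoch))
  invisible(x)
}

# 1-based sample indices of epoch i (1-based epoch index).
epoch_sample_idx <- function(grid, i) {
  (grid$starts[i] + 1L):(grid$starts[i] + grid$samples_per_epoch)
}

#' Per-epoch EMG root-mean-square amplitude
#'
#' @inheritParams make_epoch_grid
#' @param grid An [make_epoch_grid()] grid.
#' @return Numeric vector, one RMS value per epoch.
#' @export
emg_rms <- function(rec, grid) {
  m <- matrix(rec$emg[seq_len(grid$n_epochs * grid$samples_per_epoch)],
              nrow = grid$samples_per_epoch)
  sqrt(colMeans(m^2))
}

#' EMG signal-quality gate
#'
#' REM sleep is recognized largely through muscle atonia, so scoring fails
#' when the EMG carries little state contrast. The gate computes the
#' coefficient of variation (CV) of per-epoch RMS EMG over the whole
#' recording -- sample SD divided by mean -- and requires it to reach an
#' empirically derived threshold of 1.67. A recording below threshold
#' triggers a warning that automated REM scoring is unlikely to succeed.
#'
#' @inheritParams emg_rms
#' @param threshold Minimum acceptable CV (default 1.67).
#' @param quiet Suppress the failure warning.
#' @return A one-row tibble of class `emg_quality`: `cv`, `threshold`,
#'   `passed`, `n_epochs`, `mean_rms`. The per-epoch RMS vector is attached
#'   as attribute `"rms"`.
#' @export
emg_quality <- function(rec, grid, threshold = 1.67, quiet = FALSE) {
  rms <- emg_rms(rec, grid)
  if (mean(rms) == 0) stop("EMG channel is all zero; quality undefined")
  cv <- stats::sd(rms) / mean(rms)
  passed <- cv >= threshold
  if (!passed && !quiet) {
    warning(sprintf(paste0(
      "EMG coefficient of variation %.3f is below %.2f: the automated ",
      "state scoring algorithm is unlikely to successfully score the REM ",
      "epochs of this recording"), cv, threshold), call. = FALSE)
  }
  out <- tibble(cv = cv, threshold = threshold, passed = passed,
                n_epochs = grid$n_epochs, mean_rms = mean(rms))
  attr(out, "rms") <- rms
  class(out) <- c("emg_quality", class(out))
  out
}
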