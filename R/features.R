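#' Canonical frequency-band table
#'
#' The eight band-limited-power bands used as classifier features. Edges are
#' half-open `[low, high)` on bin centers except the highest band, which
#' closes at 125 Hz inclusive. The printed set deliberately contains an
#' overlap (upper theta 7-9 vs alpha 8-12 Hz) and gaps (12-13, 75-76 Hz);
#' both are reproduced as-is rather than "fixed".
#'
#' @return Tibble with columns `band`, `low`, `high` (Hz).
#' @export
#' @examples
#' sleep_bands()
sleep_bands <- function() {
  tibble(
    band = c("delta", "theta", "upper_theta", "alpha", "beta",
             "low_gamma", "mid_gamma", "high_gamma"),
    low  = c(1, 4, 7, 8, 13, 30, 50, 76),
    high = c(4, 7, 9, 12, 30, 50, 75, 125)
  )
}

# broadband normalization / EMG-power range, Hz
BROADBAND <- c(0.5, 125)
# slow-wave activity band, Hz
SWA_BAND <- c(0.5, 4)

#' Welch power spectral density of one signal segment
#'
#' Averaged modified periodograms: the signal is cut into
#' Hamming-windowed segments of `segment_length` samples with fractional
#' `overlap`, and the one-sided periodograms are averaged. The density is
#' scaled so that `sum(power) * df` approximates the signal's mean square
#' (Parseval). Defaults (2 s segments, 50% overlap) give 0.5 Hz resolution
#' at 250 Hz -- enough to resolve the 0.5-4 Hz slow-wave band -- and three
#' averaged segments per 4 s epoch.
#'
#' @param x Numeric vector of samples.
#' @param rate Sampling rate, Hz.
#' @param segment_length Segment length in samples (default `2 * rate`).
#' @param overlap Fractional overlap between segments in `[0, 1)`.
#' @return Tibble with columns `frequency` (Hz) and `power` (signal^2/Hz),
#'   with attributes `rate` and `df` (bin width).
#' @export
welch_psd <- function(x, rate, segment_length = round(2 * rate), overlap = 0.5) {
  if (segment_length > length(x)) stop("segment_length exceeds signal length")
  res <- welch_psd_epochs(x, starts0 = 0L, spe = length(x), rate = rate,
                          segment_length = segment_length, overlap = overlap)
  out <- tibble(frequency = res$frequency, power = as.vector(res$psd))
  attr(out, "rate") <- rate
  attr(out, "df") <- res$df
  out
}

# Vectorized Welch PSD over many equal-length epochs of one channel.
# starts0: 0-based epoch start samples; spe: samples per epoch.
# Returns list(frequency, df, psd = n_freq x n_epochs matrix).
welch_psd_epochs <- function(x, starts0, spe, rate,
                             segment_length = round(2 * rate), overlap = 0.5,
                             chunk = 2000L) {
  segment_length <- as.integer(segment_length)
  if (segment_length > spe) stop("segment_length exceeds epoch length")
  step <- max(1L, as.integer(round(segment_length * (1 - overlap))))
  offs <- seq(0L, spe - segment_length, by = step)  # segment offsets in epoch
  nseg <- length(offs)
  w <- as.numeric(signal::hamming(segment_length))
  U <- sum(w^2)
  nf <- segment_length %/% 2L + 1L
  one_sided <- rep(2, nf)
  one_sided[1] <- 1
  if (segment_length %% 2L == 0L) one_sided[nf] <- 1
  df <- rate / segment_length
  ne <- length(starts0)
  psd <- matrix(0, nrow = nf, ncol = ne)
  for (lo in seq(1L, ne, by = chunk)) {
    hi <- min(lo + chunk - 1L, ne)
    st <- starts0[lo:hi]
    # columns ordered segment-fastest within epoch
    col_start <- as.vector(outer(offs, st, "+"))          # 0-based
    idx <- outer(seq_len(segment_length), col_start, "+") # 1-based samples
    segs <- matrix(x[idx], nrow = segment_length) * w
    P <- (Mod(stats::mvfft(segs))^2 / (rate * U))[seq_len(nf), , drop = FALSE]
    acc <- P[, seq(1L, by = nseg, length.out = hi - lo + 1L), drop = FALSE]
    if (nseg > 1L) {
      for (j in 2:nseg) {
        acc <- acc + P[, seq(j, by = nseg, length.out = hi - lo + 1L), drop = FALSE]
      }
    }
    psd[, lo:hi] <- acc / nseg * one_sided
  }
  list(frequency = (seq_len(nf) - 1) * df, df = df, psd = psd)
}

#' Band-limited power from a power spectrum
#'
#' Integrates `power * df` over bins whose center frequency `f` satisfies
#' `low <= f < high`, or `low <= f <= high` with `include_upper = TRUE`
#' (used for bands closing at 125 Hz).
#'
#' @param psd A [welch_psd()] tibble.
#' @param low,high Band edges in Hz.
#' @param include_upper Close the band at `high` inclusively.
#' @return Scalar band power (signal^2 units).
#' @export
band_power <- function(psd, low, high, include_upper = FALSE) {
  df <- attr(psd, "df") %||% diff(psd$frequency[1:2])
  sel <- band_bins(psd$frequency, low, high, include_upper)
  if (!any(sel)) stop(sprintf("no frequency bins in band [%g, %g%s", low, high,
                              if (include_upper) "]" else ")"))
  sum(psd$power[sel]) * df
}

band_bins <- function(freq, low, high, include_upper = FALSE) {
  if (include_upper) freq >= low & freq <= high else freq >= low & freq < high
}

# Names of the per-epoch feature vector for n brain channels.
feature_names <- function(n_brain) {
  per_ch <- c(sleep_bands()$band,
              "beta_delta", "beta_low_gamma", "beta_high_gamma",
              "theta_delta", "theta_mid_gamma")
  c(as.vector(t(outer(paste0("ch", seq_len(n_brain), "_"), per_ch, paste0))),
    "emg_rms", "emg_power", "emgrms_plus_mgamma", "emgpow_plus_mgamma")
}

#' Per-epoch electrophysiological feature matrix
#'
#' For every epoch, computes 13 features per brain channel -- eight
#' band-limited powers (see [sleep_bands()]) and five band ratios
#' (beta/delta, beta/low gamma, beta/high gamma, theta/delta,
#' theta/medium gamma) -- plus two EMG features (RMS of the raw samples and
#' total 0.5-125 Hz spectral power) and two EEG/EMG composites (each EMG
#' feature summed with the mean medium-gamma power across brain channels).
#' Total width: `13 * n_brain + 4`.
#'
#' Ratio denominators receive a floor of `1e-12 * mean broadband power` of
#' the channel, guarding degenerate (e.g. all-zero) synthetic inputs; real
#' spectra never hit it.
#'
#' @inheritParams emg_rms
#' @param segment_length,overlap Welch parameters, see [welch_psd()].
#' @return Tibble of class `sleep_features`: column `epoch` (1-based) plus
#'   one column per feature. Attributes: `normalization` (`"raw"`),
#'   `n_brain`, `epoch_length_s`.
#' @export
feature_matrix <- function(rec, grid, segment_length = round(2 * rec$sampling_rate),
                           overlap = 0.5) {
  feature_matrix_impl(rec, grid, seq_len(grid$n_epochs), segment_length, overlap)
}

#' Feature vector of a single epoch
#'
#' Row `epoch_index` of [feature_matrix()], computed on its own.
#'
#' @inheritParams feature_matrix
#' @param epoch_index 1-based epoch index.
#' @return One-row `sleep_features` tibble.
#' @export
epoch_features <- function(rec, grid, epoch_index,
                           segment_length = round(2 * rec$sampling_rate),
                           overlap = 0.5) {
  stopifnot(length(epoch_index) == 1L,
            epoch_index >= 1L, epoch_index <= grid$n_epochs)
  feature_matrix_impl(rec, grid, as.integer(epoch_index), segment_length, overlap)
}

feature_matrix_impl <- function(rec, grid, epochs, segment_length, overlap) {
  rate <- rec$sampling_rate
  spe <- grid$samples_per_epoch
  starts0 <- grid$starts[epochs]
  nb <- ncol(rec$brain)
  bands <- sleep_bands()

  band_mat <- function(res) {
    # bins x bands indicator weighted by df -> band powers by matrix product
    ind <- vapply(seq_len(nrow(bands)), function(b) {
      band_bins(res$frequency, bands$low[b], bands$high[b],
                include_upper = bands$high[b] >= BROADBAND[2]) * res$df
    }, numeric(length(res$frequency)))
    out <- t(res$psd) %*% ind
    colnames(out) <- bands$band
    out
  }
  broad_power <- function(res) {
    sel <- band_bins(res$frequency, BROADBAND[1], BROADBAND[2], TRUE)
    colSums(res$psd[sel, , drop = FALSE]) * res$df
  }

  cols <- list()
  mgamma <- 0
  for (ch in seq_len(nb)) {
    res <- welch_psd_epochs(rec$brain[, ch], starts0, spe, rate,
                            segment_length, overlap)
    bp <- band_mat(res)
    eps <- 1e-12 * mean(broad_power(res))
    rat <- cbind(
      beta_delta      = bp[, "beta"]  / (bp[, "delta"] + eps),
      beta_low_gamma  = bp[, "beta"]  / (bp[, "low_gamma"] + eps),
      beta_high_gamma = bp[, "beta"]  / (bp[, "high_gamma"] + eps),
      theta_delta     = bp[, "theta"] / (bp[, "delta"] + eps),
      theta_mid_gamma = bp[, "theta"] / (bp[, "mid_gamma"] + eps)
    )
    blk <- cbind(bp, rat)
    colnames(blk) <- paste0("ch", ch, "_", colnames(blk))
    cols[[ch]] <- blk
    mgamma <- mgamma + bp[, "mid_gamma"] / nb
  }

  emg <- rec$emg
  m <- matrix(emg[rep(starts0, each = spe) + seq_len(spe)], nrow = spe)
  e_rms <- sqrt(colMeans(m^2))
  res_e <- welch_psd_epochs(emg, starts0, spe, rate, segment_length, overlap)
  e_pow <- broad_power(res_e)

  mat <- do.call(cbind, c(cols, list(cbind(
    emg_rms = e_rms, emg_power = e_pow,
    emgrms_plus_mgamma = e_rms + mgamma,
    emgpow_plus_mgamma = e_pow + mgamma
  ))))
  out <- as_tibble(as.data.frame(mat))
  out <- dplyr::bind_cols(tibble(epoch = as.integer(epochs)), out)
  attr(out, "normalization") <- "raw"
  attr(out, "n_brain") <- nb
  attr(out, "epoch_length_s") <- grid$epoch_length_s
  class(out) <- c("sleep_features", class(out))
  out
}

feature_cols <- function(fm) setdiff(names(fm), c("epoch"))

#' Z-score a feature matrix
#'
#' Centers and scales every feature column to mean 0 / SD 1 (sample SD,
#' n - 1), estimating the statistics on `fit_rows` and applying them to all
#' rows. Z-scoring makes features comparable across recordings with
#' different absolute signal scales; classification inputs are always
#' z-scored.
#'
#' @param fm A [feature_matrix()] tibble.
#' @param fit_rows `"all"` or an integer vector of row positions used to
#'   estimate means and SDs.
#' @return The z-scored `sleep_features` tibble with attributes
#'   `normalization = "zscored"`, `center`, `scale`.
#' @export
zscore_features <- function(fm, fit_rows = "all") {
  fc <- feature_cols(fm)
  rows <- if (identical(fit_rows, "all")) seq_len(nrow(fm)) else as.integer(fit_rows)
  if (length(rows) < 2L) stop("need at least 2 fit rows to estimate an SD")
  mu <- vapply(fc, function(cn) mean(fm[[cn]][rows]), 0)
  sdev <- vapply(fc, function(cn) stats::sd(fm[[cn]][rows]), 0)
  zero <- sdev == 0 | !is.finite(sdev)
  if (any(zero)) {
    stop("zero-SD feature column(s) on fit rows: ", paste(fc[zero], collapse = ", "))
  }
  for (cn in fc) fm[[cn]] <- (fm[[cn]] - mu[[cn]]) / sdev[[cn]]
  attr(fm, "normalization") <- "zscored"
  attr(fm, "center") <- mu
  attr(fm, "scale") <- sdev
  fm
}
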