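#' Construct a multichannel sleep recording
#'
#' Container for one continuous recording session: one or more brain channels
#' (EEG or LFP) plus exactly one nuchal EMG channel, all sampled at a common
#' rate. Channel units are whatever the source file declares; downstream
#' features are z-scored, so absolute scale is immaterial.
#'
#' @param brain Numeric matrix (samples x channels) or a list/vector of
#'   brain-channel traces of equal length.
#' @param emg Numeric vector, the EMG trace (same length as brain channels).
#' @param sampling_rate Sampling rate in Hz. Must be at least 250 Hz so the
#'   highest analyzed band (closing at 125 Hz) sits at or below Nyquist.
#' @param start_time Clock time of the first sample, in hours (0-24).
#' @param light_onset Clock time the light period begins, in hours (0-24).
#' @param light_hours Duration of the light period in hours (default 12).
#' @param channel_names Optional names for the brain channels.
#'
#' @return An object of class `sleep_recording`: a list with elements
#'   `brain` (samples x channels matrix), `emg`, `sampling_rate`,
#'   `start_time`, `light_onset`, `light_hours`.
#' @export
new_recording <- function(brain, emg, sampling_rate,
                          start_time = 0, light_onset = 0, light_hours = 12,
                          channel_names = NULL) {
  if (is.list(brain)) brain <- do.call(cbind, brain)
  if (is.null(dim(brain))) brain <- matrix(brain, ncol = 1)
  brain <- as.matrix(brain)
  storage.mode(brain) <- "double"
  emg <- as.double(emg)
  if (ncol(brain) < 1L) stop("at least one brain channel is required")
  if (nrow(brain) != length(emg)) {
    stop("brain channels and EMG must have the same number of samples")
  }
  if (sampling_rate < 250) {
    stop("sampling_rate must be >= 250 Hz: the highest analyzed frequency ",
         "is 125 Hz and must not exceed Nyquist")
  }
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(ncol(brain)))
  colnames(brain) <- channel_names
  structure(
    list(brain = brain, emg = emg, sampling_rate = sampling_rate,
         start_time = start_time, light_onset = light_onset,
         light_hours = light_hours),
    class = "sleep_recording"
  )
}

#' @export
print.sleep_recording <- function(x, ...) {
  dur <- nrow(x$brain) / x$sampling_rate
  cat(sprintf("<sleep_recording> %d brain channel(s) + EMG, %g Hz, %.2f h\n",
              ncol(x$brain), x$sampling_rate, dur / 3600))
  cat(sprintf("  start %.2f h, lights on %.2f h for %g h\n",
              x$start_time, x$light_onset, x$light_hours))
  invisible(x)
}

n_samples <- function(rec) nrow(rec$brain)

#' Read a recording from disk
#'
#' Supported formats: EDF (`.edf`, the standard polysomnography exchange
#' format; a continuous-EDF subset with one sampling rate across signals),
#' CSV (`.csv`, one column per channel, header row naming the channels), and
#' a raw float64 binary (`.bin`) with a JSON sidecar (`<path>.json`) storing
#' the sampling rate and channel roles. The binary format round-trips sample
#' values bit-exactly; EDF quantizes to 16 bits.
#'
#' @param path File path.
#' @param format One of `"auto"`, `"edf"`, `"csv"`, `"bin"`. `"auto"` picks
#'   by file extension.
#' @param channel_map Optional named character vector mapping channel names to
#'   roles `"brain"` or `"emg"`. When `NULL`, channels whose name contains
#'   "emg" (case-insensitive) are taken as EMG and all others as brain.
#' @param sampling_rate Required for CSV (the format stores no rate).
#' @param start_time,light_onset,light_hours Light-schedule metadata for
#'   formats that do not store it (CSV); see [new_recording()].
#' @param verbose Log duration, rate and channel roles via [message()].
#'
#' @return A [new_recording()] object.
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv", "bin"),
                           channel_map = NULL, sampling_rate = NULL,
                           start_time = 0, light_onset = 0, light_hours = 12,
                           verbose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     edf = "edf", csv = "csv", bin = "bin",
                     stop("cannot infer format from extension of ", path))
  }
  out <- switch(format,
    csv = {
      if (is.null(sampling_rate)) stop("sampling_rate is required for CSV input")
      dat <- utils::read.csv(path, check.names = FALSE)
      build_recording(as.matrix(dat), colnames(dat), sampling_rate,
                      channel_map, start_time, light_onset, light_hours)
    },
    bin = read_recording_bin(path, channel_map),
    edf = read_edf(path, channel_map)
  )
  if (verbose) {
    message(sprintf("loaded %s: %d channel(s) x %d samples @ %g Hz (%.2f h); EMG = 1",
                    basename(path), ncol(out$brain) + 1L, n_samples(out),
                    out$sampling_rate, n_samples(out) / out$sampling_rate / 3600))
  }
  out
}

# Split a sample x channel matrix into brain/EMG roles.
build_recording <- function(mat, nm, rate, channel_map,
                            start_time = 0, light_onset = 0, light_hours = 12) {
  roles <- if (is.null(channel_map)) {
    ifelse(grepl("emg", nm, ignore.case = TRUE), "emg", "brain")
  } else {
    missing <- setdiff(nm, names(channel_map))
    if (length(missing)) stop("channel_map lacks roles for: ",
                              paste(missing, collapse = ", "))
    unname(channel_map[nm])
  }
  if (!all(roles %in% c("brain", "emg"))) stop("roles must be 'brain' or 'emg'")
  if (sum(roles == "emg") != 1L) stop("exactly one EMG channel is required")
  if (sum(roles == "brain") < 1L) stop("at least one brain channel is required")
  new_recording(mat[, roles == "brain", drop = FALSE], mat[, roles == "emg"],
                rate, start_time, light_onset, light_hours,
                channel_names = nm[roles == "brain"])
}

#' Write a recording to disk
#'
#' @inheritParams read_recording
#' @param rec A `sleep_recording`.
#' @return `path`, invisibly.
#' @seealso [read_recording()] for the format descriptions.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "csv", "bin")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     edf = "edf", csv = "csv", bin = "bin",
                     stop("cannot infer format from extension of ", path))
  }
  switch(format,
    csv = {
      dat <- cbind(as.data.frame(rec$brain), emg = rec$emg)
      utils::write.csv(dat, path, row.names = FALSE)
    },
    bin = write_recording_bin(rec, path),
    edf = write_edf(rec, path)
  )
  invisible(path)
}

## ---- float64 binary + JSON sidecar ----------------------------------------

write_recording_bin <- function(rec, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (j in seq_len(ncol(rec$brain))) {
    writeBin(rec$brain[, j], con, size = 8, endian = "little")
  }
  writeBin(rec$emg, con, size = 8, endian = "little")
  meta <- list(
    sampling_rate = rec$sampling_rate,
    n_samples = n_samples(rec),
    channels = c(lapply(colnames(rec$brain),
                        function(nm) list(name = nm, role = "brain")),
                 list(list(name = "emg", role = "emg"))),
    start_time = rec$start_time, light_onset = rec$light_onset,
    light_hours = rec$light_hours
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_recording_bin <- function(path, channel_map = NULL) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing sidecar config: ", sidecar)
  meta <- jsonlite::read_json(sidecar)
  n <- meta$n_samples
  nm <- vapply(meta$channels, `[[`, "", "name")
  nch <- length(nm)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n * nch, size = 8, endian = "little")
  mat <- matrix(vals, nrow = n, ncol = nch)
  if (is.null(channel_map)) {
    channel_map <- setNames(vapply(meta$channels, `[[`, "", "role"), nm)
  }
  build_recording(mat, nm, meta$sampling_rate, channel_map,
                  meta$start_time %||% 0, meta$light_onset %||% 0,
                  meta$light_hours %||% 12)
}

## ---- EDF (continuous, single rate) ----------------------------------------

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  rate <- rec$sampling_rate
  if (rate != round(rate)) stop("EDF writer requires an integer sampling rate")
  mat <- cbind(rec$brain, EMG = rec$emg)
  nrec <- floor(nrow(mat) / rate)           # 1 s data records
  mat <- mat[seq_len(nrec * rate), , drop = FALSE]
  ns <- ncol(mat)
  pmin <- apply(mat, 2, min); pmax <- apply(mat, 2, max)
  flat <- pmax <= pmin
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  h <- paste0(
    pad_field("0", 8), pad_field("X X X X", 80), pad_field("Startdate X X X X", 80),
    pad_field("01.01.01", 8), pad_field(sprintf("%02d.00.00", floor(rec$start_time) %% 24), 8),
    pad_field(256 + 256 * ns, 8), pad_field("", 44), pad_field(nrec, 8),
    pad_field(1, 8), pad_field(ns, 4)
  )
  labels <- c(colnames(rec$brain), "EMG")
  sig <- function(vals, width) paste(vapply(vals, pad_field, "", width = width),
                                     collapse = "")
  h <- paste0(h,
    sig(labels, 16), sig(rep("", ns), 80), sig(rep("uV", ns), 8),
    sig(formatC(pmin, digits = 6, format = "g"), 8),
    sig(formatC(pmax, digits = 6, format = "g"), 8),
    sig(rep(dmin, ns), 8), sig(rep(dmax, ns), 8),
    sig(rep("", ns), 80), sig(rep(rate, ns), 8), sig(rep("", ns), 32))
  writeChar(h, con, eos = NULL)
  # re-read the header's rounded physical ranges so read(write(x)) is exact
  # up to digitization only
  pmin <- as.numeric(formatC(pmin, digits = 6, format = "g"))
  pmax <- as.numeric(formatC(pmax, digits = 6, format = "g"))
  gain <- (pmax - pmin) / (dmax - dmin)
  dig <- sweep(mat, 2, pmin, "-")
  dig <- round(sweep(dig, 2, gain, "/")) + dmin
  dig <- pmin(pmax(dig, dmin), dmax)
  for (r in seq_len(nrec)) {
    rows <- ((r - 1) * rate + 1):(r * rate)
    # EDF records are signal-major: all of signal 1, then signal 2, ...
    writeBin(as.integer(dig[rows, , drop = FALSE]), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

read_edf <- function(path, channel_map = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8)
  start_str <- rd(8)
  rd(8); rd(44)
  nrec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16); fld(80); fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)
  if (length(unique(spr)) != 1L) {
    stop("EDF reader supports a single sampling rate across signals")
  }
  rate <- spr[1] / rec_dur
  mat <- matrix(0, nrow = nrec * spr[1], ncol = ns)
  gain <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    block <- readBin(con, "integer", n = ns * spr[1], size = 2,
                     signed = TRUE, endian = "little")
    rows <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (s in seq_len(ns)) {
      dig <- block[((s - 1) * spr[s] + 1):(s * spr[s])]
      mat[rows, s] <- pmin[s] + (dig - dmin[s]) * gain[s]
    }
  }
  start_h <- suppressWarnings(as.numeric(substr(start_str, 1, 2)))
  if (is.na(start_h)) start_h <- 0
  build_recording(mat, labels, rate, channel_map, start_time = start_h)
}
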