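#' Synthetic-recording configuration
#'
#' Defines a seeded generative model of a rodent sleep recording whose
#' electrophysiology carries the state-dependent structure real scorers rely
#' on: NREM shows high-amplitude delta (0.5-4 Hz) activity whose level
#' decays across the light period (sleep homeostasis); wake and REM show a
#' theta peak, wake additionally broadband gamma; the EMG is high and burst-
#' variable in wake, low in NREM, and near-atonic in REM. State sequences
#' come from a semi-Markov (bout-structured) process with lognormal bout
#' durations, light/dark modulation of bout length, and no direct wake-to-REM
#' transitions. Brain channels are spectrally shaped Gaussian noise -- only
#' band-power statistics matter to the classifier, and noise recipes are
#' seedable and fast.
#'
#' All defaults are frozen synthetic choices made once for rodent-like
#' plausibility; none are measured values.
#'
#' @param duration_h Recording length in hours.
#' @param sampling_rate Hz.
#' @param n_brain Number of brain channels.
#' @param epoch_length_s Scoring epoch, seconds.
#' @param bout_median_s,bout_sdlog Per-state lognormal bout-duration medians
#'   (s) and log-SDs, named W/NR/R.
#' @param transition 3x3 state transition matrix (rows from, cols to; zero
#'   diagonal, rows sum to 1). Default forbids W->R.
#' @param light_bout_mult Multiplier on bout durations during the light
#'   period (dark period uses its reciprocal), named W/NR/R: sleep bouts
#'   lengthen in the light phase.
#' @param spectral_exp,base_amp 1/f^a background exponent and amplitude.
#' @param delta_gain,theta_gain,gamma_gain State-specific band gains (NREM
#'   delta; wake/REM theta; wake gamma), all scaled by `separability`. The
#'   defaults put the band contrasts near the sampling variability of a
#'   3-segment Welch estimate, so classification is good but imperfect --
#'   comparable to real recordings -- rather than at ceiling. Wake and REM
#'   share the same theta peak and differ spectrally only through the modest
#'   wake gamma gain, so REM recognition leans on the EMG, as it does for
#'   human scorers.
#' @param gain_jitter_sdlog Log-SD of a per-epoch lognormal multiplier on
#'   the state-specific spectral gains: within-state heterogeneity, the
#'   analogue of waxing/waning oscillatory episodes.
#' @param quiet_wake_prob Fraction of wake epochs that are quiet
#'   wakefulness: drowsy immobility with almost no gamma
#'   (`quiet_gamma_factor`), reduced muscle tone (`quiet_emg_factor`), and
#'   no movement bursts. Quiet wake is spectrally close to REM, so telling
#'   them apart hinges on the EMG -- the overlap that makes REM scoring
#'   fail when EMG quality is poor.
#' @param quiet_gamma_factor,quiet_emg_factor Gamma-gain and EMG-level
#'   multipliers applied to quiet-wake epochs.
#' @param emg_sd Per-state EMG noise SD, named W/NR/R (W >> NR > R).
#' @param emg_jitter_sdlog Log-SD of a per-epoch lognormal multiplier on the
#'   EMG level in every state: within-state muscle-tone variability, which
#'   makes the low NREM tone and REM atonia overlap as they do in real
#'   nuchal recordings.
#' @param wake_burst_sdlog Log-SD of the per-epoch lognormal wake EMG burst
#'   factor; bursts give wake its large RMS variability and push the EMG
#'   coefficient of variation above the 1.67 quality gate.
#' @param swa_start,swa_end NREM delta-gain multiplier at light onset and
#'   light offset (linear decline emulating homeostatic SWA decay).
#' @param crossfade_s Crossfade at state transitions, seconds; creates
#'   genuinely ambiguous boundary epochs for the uncertainty mechanism.
#' @param separability Scales all state-specific gains and EMG contrast;
#'   1 is the default study condition.
#' @param light_onset,start_time,light_hours Light schedule (recording
#'   starts at light onset by default).
#' @return List of class `synth_config`.
#' @export
synth_config <- function(duration_h = 24, sampling_rate = 250, n_brain = 2,
                         epoch_length_s = 4,
                         bout_median_s = c(W = 120, NR = 160, R = 80),
                         bout_sdlog = c(W = 0.6, NR = 0.5, R = 0.4),
                         transition = matrix(c(0, 1, 0,
                                               0.6, 0, 0.4,
                                               0.7, 0.3, 0), 3, 3, byrow = TRUE,
                                             dimnames = list(sleep_states(),
                                                             sleep_states())),
                         light_bout_mult = c(W = 0.7, NR = 1.3, R = 1.3),
                         spectral_exp = 2, base_amp = 100,
                         delta_gain = 1.5, theta_gain = 1.5, gamma_gain = 0.5,
                         gain_jitter_sdlog = 0.5,
                         quiet_wake_prob = 0.3, quiet_gamma_factor = 0.1,
                         quiet_emg_factor = 0.4,
                         emg_sd = c(W = 1, NR = 0.25, R = 0.15),
                         emg_jitter_sdlog = 0.4,
                         wake_burst_sdlog = 1.0,
                         swa_start = 1.3, swa_end = 0.7,
                         crossfade_s = 0.5, separability = 1,
                         light_onset = 0, start_time = 0, light_hours = 12) {
  stopifnot(duration_h > 0, sampling_rate >= 250, n_brain >= 1,
            separability > 0, all(emg_sd > 0),
            all(abs(rowSums(transition) - 1) < 1e-9))
  if (any(diag(transition) >= 1)) stop("degenerate config: absorbing state")
  cfg <- list(duration_h = duration_h, sampling_rate = sampling_rate,
              n_brain = n_brain, epoch_length_s = epoch_length_s,
              bout_median_s = bout_median_s, bout_sdlog = bout_sdlog,
              transition = transition, light_bout_mult = light_bout_mult,
              spectral_exp = spectral_exp, base_amp = base_amp,
              delta_gain = delta_gain, theta_gain = theta_gain,
              gamma_gain = gamma_gain, gain_jitter_sdlog = gain_jitter_sdlog,
              quiet_wake_prob = quiet_wake_prob,
              quiet_gamma_factor = quiet_gamma_factor,
              quiet_emg_factor = quiet_emg_factor,
              emg_sd = emg_sd, emg_jitter_sdlog = emg_jitter_sdlog,
              wake_burst_sdlog = wake_burst_sdlog,
              swa_start = swa_start, swa_end = swa_end,
              crossfade_s = crossfade_s, separability = separability,
              light_onset = light_onset, start_time = start_time,
              light_hours = light_hours)
  class(cfg) <- "synth_config"
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> %g h @ %g Hz, %d brain channel(s), separability %g\n",
              x$duration_h, x$sampling_rate, x$n_brain, x$separability))
  invisible(x)
}

#' Generate a ground-truth hypnogram
#'
#' Semi-Markov simulation at epoch resolution: draw a bout duration from the
#' current state's lognormal (scaled by the light/dark multiplier at bout
#' onset), emit that many epochs, then move by the transition matrix.
#'
#' @param cfg A [synth_config()].
#' @param seed RNG seed.
#' @return A [hypnogram()] of `duration_h * 3600 / epoch_length_s` epochs.
#' @export
generate_hypnogram <- function(cfg, seed = 1) {
  n_epochs <- round(cfg$duration_h * 3600 / cfg$epoch_length_s)
  st_names <- sleep_states()
  with_seed(seed, {
    s <- character(0)
    state <- "W"
    while (length(s) < n_epochs) {
      t_h <- (cfg$start_time + length(s) * cfg$epoch_length_s / 3600 -
                cfg$light_onset) %% 24
      mult <- if (t_h < cfg$light_hours) cfg$light_bout_mult[state]
              else 1 / cfg$light_bout_mult[state]
      dur <- stats::rlnorm(1, log(cfg$bout_median_s[state]),
                           cfg$bout_sdlog[state]) * mult
      n_ep <- max(1L, as.integer(round(dur / cfg$epoch_length_s)))
      s <- c(s, rep(state, n_ep))
      state <- sample(st_names, 1, prob = cfg$transition[state, ])
    }
    hypnogram(s[seq_len(n_epochs)], cfg$epoch_length_s)
  })
}

# state-specific band shapes over the full-FFT frequency grid; the per-state
# gain (scaled by separability, per-epoch jitter, and for NREM the SWA decay
# factor) multiplies these before adding the 1/f background
state_profiles <- function(cfg, freq) {
  sep <- cfg$separability
  theta <- exp(-(freq - 7)^2 / (2 * 0.75^2))
  gamma <- as.numeric(freq >= 30 & freq <= 100)
  list(
    W_theta = cfg$theta_gain * sep * theta,
    W_gamma = cfg$gamma_gain * sep * gamma,
    NR = cfg$delta_gain * sep * as.numeric(freq >= 0.5 & freq < 4),
    R  = cfg$theta_gain * sep * theta
  )
}

#' Synthesize the electrophysiological signals for a hypnogram
#'
#' Every epoch of each brain channel is 1/f^a Gaussian noise spectrally
#' shaped by the state recipe (see [synth_config()]); the NREM delta gain is
#' additionally scaled by a factor declining linearly across the light
#' period. The EMG is Gaussian noise at the state's SD, with a lognormal
#' per-epoch burst factor in wake. At state transitions the first
#' `crossfade_s` seconds are crossfaded from the previous state's recipe,
#' creating ambiguous boundary epochs.
#'
#' @param truth A [generate_hypnogram()] hypnogram.
#' @param cfg The matching [synth_config()].
#' @param seed RNG seed.
#' @return A [new_recording()].
#' @export
generate_signals <- function(truth, cfg, seed = 1) {
  s <- states_of(truth)
  ne <- length(s)
  spe <- as.integer(round(cfg$epoch_length_s * cfg$sampling_rate))
  n <- ne * spe
  freq_full <- cfg$sampling_rate * c(0:(spe %/% 2), rev(seq_len(spe - spe %/% 2 - 1))) / spe
  base <- cfg$base_amp / (freq_full + 1)^cfg$spectral_exp
  prof <- state_profiles(cfg, freq_full)

  ph <- epoch_light_phase(cfg, ne, cfg$epoch_length_s)
  lf <- ((cfg$start_time + (seq_len(ne) - 1) * cfg$epoch_length_s / 3600 -
            cfg$light_onset) %% 24) / cfg$light_hours
  swa_f <- ifelse(ph$light, cfg$swa_start + (cfg$swa_end - cfg$swa_start) * lf, 1)

  # per-epoch magnitude-squared multiplier: 1 + jitter * gain * bandshape
  # (NREM scaled by the SWA decay factor; quiet wake loses its gamma)
  epoch_mult <- function(states, swa, jit, quiet) {
    m <- matrix(1, length(freq_full), length(states))
    for (st in c("NR", "R")) {
      cols <- which(states == st)
      if (!length(cols)) next
      g <- jit[cols] * if (st == "NR") swa[cols] else 1
      m[, cols] <- m[, cols] + outer(prof[[st]], g)
    }
    w <- which(states == "W")
    if (length(w)) {
      gfac <- ifelse(quiet[w], cfg$quiet_gamma_factor, 1)
      m[, w] <- m[, w] + outer(prof$W_theta, jit[w]) +
        outer(prof$W_gamma, jit[w] * gfac)
    }
    m
  }
  shape_noise <- function(white, msq) {
    Y <- stats::mvfft(white) * sqrt(base * msq)
    Re(stats::mvfft(Y, inverse = TRUE)) / spe
  }

  fade_n <- as.integer(round(cfg$crossfade_s * cfg$sampling_rate))
  fade_w <- if (fade_n > 0) seq(1, 0, length.out = fade_n) else numeric(0)
  trans <- which(s[-1] != s[-ne]) + 1L   # epochs starting a new state

  with_seed(seed, {
    jit <- stats::rlnorm(ne, 0, cfg$gain_jitter_sdlog)
    quiet <- s == "W" & stats::runif(ne) < cfg$quiet_wake_prob
    brain <- matrix(0, n, cfg$n_brain)
    chunk <- 1500L
    for (ch in seq_len(cfg$n_brain)) {
      for (lo in seq(1L, ne, by = chunk)) {
        hi <- min(lo + chunk - 1L, ne)
        idx <- lo:hi
        white <- matrix(stats::rnorm(spe * length(idx)), spe)
        x <- shape_noise(white, epoch_mult(s[idx], swa_f[idx], jit[idx],
                                           quiet[idx]))
        brain[(grid0(lo, spe) + 1L):(grid0(hi, spe) + spe), ch] <- as.vector(x)
      }
      # crossfade transition epochs toward the previous state's recipe
      if (fade_n > 0 && length(trans)) {
        for (i in trans) {
          white <- matrix(stats::rnorm(spe), spe)
          alt <- shape_noise(white, epoch_mult(s[i - 1L], swa_f[i - 1L],
                                               jit[i - 1L],
                                               quiet[i - 1L]))[seq_len(fade_n), 1]
          at <- grid0(i, spe) + seq_len(fade_n)
          brain[at, ch] <- fade_w * alt + (1 - fade_w) * brain[at, ch]
        }
      }
    }
    sd_ep <- unname(cfg$emg_sd[s]) * stats::rlnorm(ne, 0, cfg$emg_jitter_sdlog)
    sd_ep[quiet] <- sd_ep[quiet] * cfg$quiet_emg_factor
    bursts <- which(s == "W" & !quiet)   # movement bursts in active wake only
    sd_ep[bursts] <- sd_ep[bursts] * stats::rlnorm(length(bursts), 0,
                                                   cfg$wake_burst_sdlog)
    emg <- stats::rnorm(n) * rep(sd_ep, each = spe)
    if (fade_n > 0 && length(trans)) {
      for (i in trans) {
        at <- grid0(i, spe) + seq_len(fade_n)
        emg[at] <- fade_w * stats::rnorm(fade_n, 0, sd_ep[i - 1L]) +
          (1 - fade_w) * emg[at]
      }
    }
    new_recording(brain, emg, cfg$sampling_rate,
                  start_time = cfg$start_time, light_onset = cfg$light_onset,
                  light_hours = cfg$light_hours)
  })
}

grid0 <- function(epoch, spe) (epoch - 1L) * spe

#' Generate a complete seeded dataset
#'
#' Composes [generate_hypnogram()], [generate_signals()], and
#' [select_training_epochs()] (with the ground truth standing in as the
#' manual label source) into one reproducible bundle.
#'
#' @inheritParams generate_signals
#' @param cfg A [synth_config()].
#' @param n_series,series_length,n_extra_rem Training-selection parameters,
#'   see [select_training_epochs()].
#' @return List: `recording`, `truth` (hypnogram), `training` (tibble of
#'   `epoch`, `state` for the selected epochs), `config`, `seed`.
#' @export
generate_dataset <- function(cfg, seed = 1, n_series = 50, series_length = 10,
                             n_extra_rem = 60) {
  truth <- generate_hypnogram(cfg, seed)
  rec <- generate_signals(truth, cfg, seed + 1L)
  sel <- select_training_epochs(nrow(truth), truth, n_series = n_series,
                                series_length = series_length,
                                n_extra_rem = n_extra_rem,
                                epoch_length_s = cfg$epoch_length_s,
                                seed = seed + 2L)
  list(recording = rec, truth = truth,
       training = tibble(epoch = sel, state = truth$state[sel]),
       config = cfg, seed = seed)
}
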