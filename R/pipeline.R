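#' Score a recording in memory
#'
#' The core scoring pipeline on in-memory objects: feature extraction,
#' z-scoring, training-set balancing, ensemble training, prediction of every
#' epoch, substitution of the manually scored training epochs (their labels
#' are known, so they keep certainty 1), and heuristic post-processing.
#'
#' @param rec A [new_recording()].
#' @param training Data frame with `epoch` and `state`: the manually scored
#'   training epochs.
#' @param seed Integer seed driving balancing and ensemble training.
#' @param spec A [network_spec()].
#' @param epoch_length_s Scoring epoch, seconds.
#' @param certainty_threshold Uncertain-flag threshold (default 0.90).
#' @param heuristics Apply [apply_heuristics()] to the final hypnogram.
#' @param emg_cv_threshold EMG quality gate (default 1.67); failure warns
#'   and, unless `force = TRUE`, aborts.
#' @param force Proceed past a failed EMG gate.
#' @return List of class `sleep_scoring`: `hypnogram` (final), `prediction`
#'   (raw ensemble output), `ensemble`, `features` (z-scored), `emg`,
#'   `grid`, `seed`.
#' @export
score_recording <- function(rec, training, seed = 1, spec = network_spec(),
                            epoch_length_s = 4, certainty_threshold = 0.90,
                            heuristics = TRUE, emg_cv_threshold = 1.67,
                            force = FALSE) {
  grid <- make_epoch_grid(rec, epoch_length_s)
  gate <- emg_quality(rec, grid, emg_cv_threshold, quiet = TRUE)
  if (!gate$passed) {
    msg <- sprintf(paste0("EMG quality gate failed (CV %.3f < %.2f): the ",
                          "algorithm is unlikely to successfully score REM ",
                          "epochs of this recording"), gate$cv, gate$threshold)
    if (!force) stop(msg, "; rerun with force = TRUE to proceed anyway",
                     call. = FALSE)
    warning(msg, call. = FALSE)
  }
  fm <- feature_matrix(rec, grid)
  fmz <- zscore_features(fm)
  ts <- training_set(fmz, training)
  tsb <- oversample_balance(ts, seed)
  ens <- train_ensemble(tsb, spec, seed = seed,
                        certainty_threshold = certainty_threshold)
  pred <- predict(ens, fmz)
  # training epochs carry their manual labels
  pos <- match(training$epoch, pred$epoch)
  pred$state[pos] <- training$state
  pred$certainty[pos] <- 1
  pred$uncertain[pos] <- FALSE
  hyp <- if (heuristics) apply_heuristics(pred) else pred
  structure(list(hypnogram = hyp, prediction = pred, ensemble = ens,
                 features = fmz, emg = gate, grid = grid, seed = seed),
            class = "sleep_scoring")
}

#' @export
print.sleep_scoring <- function(x, ...) {
  cat(sprintf("<sleep_scoring> %d epochs; EMG CV %.2f (%s); %.1f%% epochs uncertain\n",
              nrow(x$hypnogram), x$emg$cv,
              if (x$emg$passed) "passed" else "FAILED",
              100 * mean(x$prediction$uncertain)))
  invisible(x)
}

#' Run the full scoring pipeline on files
#'
#' File-level wrapper around [score_recording()]: loads the recording and the
#' partial training hypnogram, evaluates the EMG gate, trains, predicts, and
#' writes the output bundle to `out_dir`: `hypnogram.tsv`,
#' `uncertain_epochs.tsv`, `model/` (serialized ensemble), and
#' `run_log.json` (configuration, its MD5 hash, seed, EMG CV, and the
#' training-epoch indices). Reruns with identical inputs and seed are
#' byte-identical.
#'
#' @param recording A recording path (see [read_recording()]) or a
#'   `sleep_recording`.
#' @param training_labels Path to a hypnogram TSV covering the training
#'   epochs, or a data frame with `epoch` and `state`.
#' @param out_dir Output directory (created).
#' @inheritParams score_recording
#' @param ... Passed to [read_recording()] (e.g. `sampling_rate` for CSV).
#' @return The [score_recording()] result, invisibly, with `$paths` added.
#' @export
run_score <- function(recording, training_labels, out_dir, seed = 1,
                      spec = network_spec(), epoch_length_s = 4,
                      certainty_threshold = 0.90, heuristics = TRUE,
                      emg_cv_threshold = 1.67, force = FALSE, ...) {
  rec <- if (inherits(recording, "sleep_recording")) recording
         else read_recording(recording, ...)
  training <- if (is.data.frame(training_labels)) training_labels
              else read_hypnogram(training_labels, epoch_length_s)
  res <- score_recording(rec, training, seed = seed, spec = spec,
                         epoch_length_s = epoch_length_s,
                         certainty_threshold = certainty_threshold,
                         heuristics = heuristics,
                         emg_cv_threshold = emg_cv_threshold, force = force)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    hypnogram = file.path(out_dir, "hypnogram.tsv"),
    uncertain = file.path(out_dir, "uncertain_epochs.tsv"),
    model = file.path(out_dir, "model"),
    log = file.path(out_dir, "run_log.json")
  )
  write_hypnogram(res$hypnogram, paths$hypnogram)
  write_hypnogram(res$prediction[res$prediction$uncertain, ], paths$uncertain)
  save_ensemble(res$ensemble, paths$model)
  config <- list(seed = seed, epoch_length_s = epoch_length_s,
                 certainty_threshold = certainty_threshold,
                 heuristics = heuristics, emg_cv_threshold = emg_cv_threshold,
                 force = force, network = unclass(spec))
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  log <- list(config = config, config_md5 = unname(tools::md5sum(tf)),
              emg_cv = res$emg$cv, emg_passed = res$emg$passed,
              n_epochs = res$grid$n_epochs,
              training_epochs = training$epoch,
              uncertain_fraction = mean(res$prediction$uncertain))
  unlink(tf)
  jsonlite::write_json(log, paths$log, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$paths <- paths
  invisible(res)
}

#' Seeded synthetic experiments
#'
#' Reproducible experiment grids on synthetic data, one tidy result row per
#' condition x seed:
#'
#' * `"trainsize_sweep"`: classification accuracy as a function of
#'   training-set size (series of 10 epochs plus 60 extra REM epochs; sizes
#'   are total training epochs).
#' * `"emg_sweep"`: EMG coefficient of variation and REM sensitivity across
#'   an EMG-contrast grid. `contrast = 1` is the default recording; lower
#'   values interpolate every state's EMG level toward their common
#'   geometric mean and scale the wake bursts down, so at 0 the EMG carries
#'   no state information at all -- a failed electrode, the flat-EMG
#'   condition that trips the 1.67 gate.
#' * `"generalization"`: a model trained on one synthetic day applied to (a)
#'   a new day from the same generator ("same rat, new day") and (b) a day
#'   from a perturbed generator ("different rat"), without retraining.
#'
#' @param kind Experiment name.
#' @param cfg Base [synth_config()]; experiments default to short (1.5-2 h)
#'   days so a full grid runs on one CPU in minutes.
#' @param seed Base seed; condition `i` of replicate `j` derives its own.
#' @param sizes Training-set sizes for `trainsize_sweep`.
#' @param contrasts EMG contrast levels for `emg_sweep`.
#' @param n_reps Replicates (distinct days) per condition.
#' @param spec A [network_spec()].
#' @return Tibble, one row per condition x replicate.
#' @export
run_experiment <- function(kind = c("trainsize_sweep", "emg_sweep", "generalization"),
                           cfg = synth_config(duration_h = 2), seed = 1,
                           sizes = c(100, 280, 560), contrasts = c(1, 0.5, 0),
                           n_reps = 1, spec = network_spec()) {
  kind <- match.arg(kind)
  switch(kind,
    trainsize_sweep = purrr::map_dfr(seq_len(n_reps), function(rep) {
      ds <- generate_dataset(cfg, seed + 1000L * rep)
      purrr::map_dfr(sizes, function(sz) {
        n_rem <- min(60L, sz %/% 3L)
        n_ser <- max(1L, (sz - n_rem) %/% 10L)
        sel <- select_training_epochs(nrow(ds$truth), ds$truth,
                                      n_series = n_ser, n_extra_rem = n_rem,
                                      epoch_length_s = cfg$epoch_length_s,
                                      seed = seed + 1000L * rep + sz)
        rep_ <- evaluate_split(ds, tibble(epoch = sel, state = ds$truth$state[sel]),
                               seed + 1000L * rep + sz, spec)
        tibble(rep = rep, size = length(sel), accuracy = accuracy(rep_))
      })
    }),
    emg_sweep = purrr::map_dfr(seq_len(n_reps), function(rep) {
      purrr::map_dfr(contrasts, function(co) {
        cfg_c <- cfg
        cfg_c$wake_burst_sdlog <- cfg$wake_burst_sdlog * co
        gm <- exp(mean(log(cfg$emg_sd)))
        cfg_c$emg_sd <- exp(co * log(cfg$emg_sd) + (1 - co) * log(gm))
        ds <- generate_dataset(cfg_c, seed + 1000L * rep)
        grid <- make_epoch_grid(ds$recording, cfg$epoch_length_s)
        gate <- emg_quality(ds$recording, grid, quiet = TRUE)
        rep_ <- evaluate_split(ds, ds$training, seed + 1000L * rep, spec)
        tibble(rep = rep, contrast = co, emg_cv = gate$cv,
               gate_passed = gate$passed,
               rem_sensitivity = rep_$sensitivity[rep_$state == "R"],
               accuracy = accuracy(rep_))
      })
    }),
    generalization = purrr::map_dfr(seq_len(n_reps), function(rep) {
      base_seed <- seed + 1000L * rep
      ds <- generate_dataset(cfg, base_seed)
      sc <- score_recording(ds$recording, ds$training, seed = base_seed,
                            spec = spec, epoch_length_s = cfg$epoch_length_s)
      in_day <- metrics(confusion(sc$hypnogram, ds$truth))
      same <- new_day(cfg, base_seed + 101L)
      other_cfg <- perturb_config(cfg)
      other <- new_day(other_cfg, base_seed + 202L)
      row <- function(condition, rp) {
        tibble(rep = rep, condition = condition, accuracy = accuracy(rp),
               rem_sensitivity = rp$sensitivity[rp$state == "R"])
      }
      dplyr::bind_rows(
        row("in_day", in_day),
        row("same_rat_new_day",
            generalize(sc$ensemble, same$recording, same$truth)),
        row("different_rat",
            generalize(sc$ensemble, other$recording, other$truth))
      )
    })
  )
}

# train on ds$training and report held-out performance
evaluate_split <- function(ds, training, seed, spec = network_spec()) {
  sc <- suppressWarnings(
    score_recording(ds$recording, training, seed = seed, spec = spec,
                    epoch_length_s = ds$config$epoch_length_s, force = TRUE))
  held <- setdiff(ds$truth$epoch, training$epoch)
  metrics(confusion(sc$hypnogram$state[held], ds$truth$state[held]))
}

new_day <- function(cfg, seed) {
  truth <- generate_hypnogram(cfg, seed)
  list(recording = generate_signals(truth, cfg, seed + 1L), truth = truth)
}

# a "different animal": same structure, shifted spectral and EMG parameters
perturb_config <- function(cfg) {
  cfg$delta_gain <- cfg$delta_gain * 0.5
  cfg$theta_gain <- cfg$theta_gain * 0.6
  cfg$gamma_gain <- cfg$gamma_gain * 1.8
  cfg$emg_sd <- c(W = cfg$emg_sd[["W"]] * 0.5, NR = cfg$emg_sd[["NR"]] * 1.6,
                  R = cfg$emg_sd[["R"]] * 2.5)
  cfg$spectral_exp <- cfg$spectral_exp * 0.85
  cfg$bout_median_s <- cfg$bout_median_s * 1.3
  cfg
}
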