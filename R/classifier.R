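#' Select epochs for manual scoring (the training set)
#'
#' Picks `n_series` non-overlapping series of `series_length` consecutive
#' epochs whose start times are spread across the recording (at least one
#' series start per `bin_hours` time bin when possible), resampling until
#' the selected series jointly contain all three states, then adds
#' `n_extra_rem` additional REM-labeled epochs outside the series to
#' counter the natural scarcity of REM. Defaults (50 series x 10 epochs +
#' 60 REM) give 560 epochs, about 2.6% of a 21,600-epoch day.
#'
#' In real use the experimenter scores the returned epochs by hand; in
#' synthetic experiments the ground-truth hypnogram stands in as the label
#' source.
#'
#' @param n_epochs Total epoch count, or an `epoch_grid`.
#' @param labels Optional state labels (hypnogram or character vector) used
#'   to enforce three-state coverage and find the extra REM epochs. Without
#'   labels, coverage cannot be checked and no REM top-up is possible
#'   (warned).
#' @param n_series,series_length Number and length (epochs) of the
#'   pseudorandom series.
#' @param n_extra_rem REM epochs to add outside the series.
#' @param epoch_length_s Epoch duration, seconds.
#' @param bin_hours Width of the start-time stratification bins (default 2 h).
#' @param seed RNG seed; the same seed reproduces the same selection.
#' @param max_retries Resampling attempts for the coverage requirement.
#' @return Sorted integer vector of selected 1-based epoch indices.
#' @export
select_training_epochs <- function(n_epochs, labels = NULL, n_series = 50,
                                   series_length = 10, n_extra_rem = 60,
                                   epoch_length_s = 4, bin_hours = 2,
                                   seed = 1, max_retries = 100) {
  if (inherits(n_epochs, "epoch_grid")) {
    epoch_length_s <- n_epochs$epoch_length_s
    n_epochs <- n_epochs$n_epochs
  }
  if (!is.null(labels)) {
    labels <- states_of(labels)
    stopifnot(length(labels) == n_epochs)
  }
  n_starts <- n_epochs - series_length + 1L
  if (n_starts < 1L) stop("recording shorter than one series")
  duration_h <- n_epochs * epoch_length_s / 3600
  n_bins <- max(1L, floor(duration_h / bin_hours))
  bin_of <- pmin(ceiling(seq_len(n_starts) / (n_starts / n_bins)), n_bins)

  with_seed(seed, {
    series_epochs <- NULL
    for (try in seq_len(max_retries)) {
      blocked <- rep(FALSE, n_epochs)
      starts <- integer(0)
      ok_start <- function(st) !any(blocked[st:(st + series_length - 1L)])
      # one start per time bin first (stratification), then fill at random
      want_bins <- if (n_series >= n_bins) seq_len(n_bins) else
        sort(sample.int(n_bins, n_series))
      for (b in want_bins) {
        cand <- which(bin_of == b)
        cand <- cand[vapply(cand, ok_start, TRUE)]
        if (!length(cand)) next
        st <- cand[sample.int(length(cand), 1L)]
        starts <- c(starts, st)
        blocked[st:(st + series_length - 1L)] <- TRUE
      }
      while (length(starts) < n_series) {
        cand <- which(!vapply(seq_len(n_starts), function(st)
          any(blocked[st:(st + series_length - 1L)]), TRUE))
        if (!length(cand)) break
        st <- cand[sample.int(length(cand), 1L)]
        starts <- c(starts, st)
        blocked[st:(st + series_length - 1L)] <- TRUE
      }
      if (length(starts) < n_series) {
        warning(sprintf("could only place %d of %d series", length(starts),
                        n_series), call. = FALSE)
      }
      eps <- as.integer(sort(unlist(lapply(starts, function(st)
        st:(st + series_length - 1L)))))
      if (is.null(labels) || all(sleep_states() %in% labels[eps])) {
        series_epochs <- eps
        break
      }
    }
    if (is.null(series_epochs)) {
      warning("selected series do not cover all three states after ",
              max_retries, " attempts", call. = FALSE)
      series_epochs <- eps
    }
    extra <- integer(0)
    if (n_extra_rem > 0) {
      if (is.null(labels)) {
        warning("no labels supplied: cannot seek out extra REM epochs",
                call. = FALSE)
      } else {
        rem_avail <- setdiff(which(labels == "R"), series_epochs)
        if (length(rem_avail) < n_extra_rem) {
          warning(sprintf("only %d REM epochs available outside series (%d requested)",
                          length(rem_avail), n_extra_rem), call. = FALSE)
        }
        k <- min(n_extra_rem, length(rem_avail))
        if (k > 0) extra <- sort(sample(rem_avail, k))
      }
    }
    sort(unique(c(series_epochs, extra)))
  })
}

#' Assemble a labeled training set from a feature matrix
#'
#' @param fm A z-scored [feature_matrix()].
#' @param labels State labels: a hypnogram/character vector covering all
#'   epochs of `fm`, or a data frame with `epoch` and `state` columns
#'   covering at least `epochs`.
#' @param epochs Epoch indices to include (e.g. from
#'   [select_training_epochs()]). Default: all labeled epochs.
#' @return Tibble with columns `epoch`, `state`, and the feature columns;
#'   normalization attributes of `fm` are carried along.
#' @export
training_set <- function(fm, labels, epochs = NULL) {
  if (is.data.frame(labels) && !is.null(labels$epoch)) {
    lab <- labels
  } else {
    lab <- tibble(epoch = fm$epoch, state = states_of(labels)[fm$epoch])
  }
  if (is.null(epochs)) epochs <- lab$epoch
  pos <- match(epochs, fm$epoch)
  if (anyNA(pos)) stop("epochs missing from the feature matrix")
  lpos <- match(epochs, lab$epoch)
  if (anyNA(lpos)) stop("missing labels for selected training epochs: ",
                        paste(utils::head(epochs[is.na(lpos)], 5), collapse = ", "))
  out <- dplyr::bind_cols(
    tibble(epoch = as.integer(epochs), state = as.character(lab$state[lpos])),
    fm[pos, feature_cols(fm), drop = FALSE]
  )
  assert_states(out$state)
  attr(out, "normalization") <- attr(fm, "normalization")
  attr(out, "center") <- attr(fm, "center")
  attr(out, "scale") <- attr(fm, "scale")
  attr(out, "balanced") <- FALSE
  out
}

#' Balance a training set by minority oversampling
#'
#' Resamples the minority classes with replacement up to the majority-class
#' count so the three states are equally represented; the majority class is
#' untouched and no row is ever discarded.
#'
#' @param ts A [training_set()] tibble.
#' @param seed RNG seed.
#' @return The balanced training set (attribute `balanced = TRUE`).
#' @export
oversample_balance <- function(ts, seed = 1) {
  counts <- table(factor(ts$state, sleep_states()))
  if (any(counts == 0)) {
    stop("cannot balance: no training examples for state(s) ",
         paste(names(counts)[counts == 0], collapse = ", "))
  }
  target <- max(counts)
  extra <- with_seed(seed, {
    lapply(sleep_states(), function(st) {
      rows <- which(ts$state == st)
      need <- target - length(rows)
      if (need > 0) ts[sample(rows, need, replace = TRUE), ] else NULL
    })
  })
  out <- dplyr::bind_rows(c(list(ts), extra))
  for (a in c("normalization", "center", "scale")) attr(out, a) <- attr(ts, a)
  attr(out, "balanced") <- TRUE
  out
}

#' Network hyperparameters
#'
#' The default architecture and optimizer settings of the behavioral-state
#' classifier: four fully connected layers (256, 128, 32 hidden ReLU units
#' and a 3-unit softmax output), categorical cross-entropy with an L2 weight
#' penalty (beta = 0.01, biases excluded), Adam at learning rate 0.001,
#' 100 complete passes of the training data in minibatches of 10.
#'
#' @param hidden Hidden-layer widths.
#' @param n_classes Output width (3 states).
#' @param l2 L2 penalty coefficient.
#' @param learning_rate Adam step size.
#' @param passes Complete passes over the training set.
#' @param batch_size Minibatch size.
#' @return List of class `network_spec`.
#' @export
network_spec <- function(hidden = c(256, 128, 32), n_classes = 3, l2 = 0.01,
                         learning_rate = 0.001, passes = 100, batch_size = 10) {
  stopifnot(all(hidden > 0), n_classes == length(sleep_states()),
            l2 >= 0, learning_rate > 0, passes > 0, batch_size > 0)
  structure(list(hidden = as.integer(hidden), n_classes = as.integer(n_classes),
                 l2 = l2, learning_rate = learning_rate,
                 passes = as.integer(passes), batch_size = as.integer(batch_size)),
            class = "network_spec")
}

ts_matrix <- function(ts) {
  fc <- setdiff(names(ts), c("epoch", "state"))
  list(X = as.matrix(ts[fc]), y = match(ts$state, sleep_states()) - 1L,
       features = fc)
}

#' Train a single network
#'
#' Glorot-uniform initialization and minibatch Adam, both driven by a
#' private RNG stream derived from `seed` (training is deterministic under
#' seed and leaves R's RNG untouched).
#'
#' @param ts A balanced, z-scored [training_set()].
#' @param spec A [network_spec()].
#' @param seed Integer seed.
#' @return Object of class `sleep_net`: weights, per-pass `loss` and
#'   `accuracy` trajectories, `spec`, `seed`, `features`.
#' @export
train_network <- function(ts, spec = network_spec(), seed = 1) {
  d <- ts_matrix(ts)
  seed <- as.integer(seed %% .Machine$integer.max)
  w0 <- .mlp_init(ncol(d$X), spec$hidden, spec$n_classes, seed)
  fit <- .mlp_train(d$X, d$y, w0, spec$learning_rate, spec$l2,
                    spec$passes, spec$batch_size, seed + 104729L)
  structure(list(W = fit$W, b = fit$b, loss = as.vector(fit$loss),
                 accuracy = as.vector(fit$accuracy), spec = spec,
                 seed = seed, features = d$features),
            class = "sleep_net")
}

#' Train the five-member ensemble
#'
#' Repeats [train_network()] `n_members` times on identical data with
#' distinct derived seeds (distinct initializations and batch orders),
#' yielding similar but non-identical networks whose vote and averaged
#' probabilities drive prediction and certainty.
#'
#' @inheritParams train_network
#' @param n_members Ensemble size (default 5).
#' @param certainty_threshold Mean modal-class probability below which an
#'   epoch is flagged uncertain (default 0.90).
#' @return Object of class `sleep_ensemble`.
#' @export
train_ensemble <- function(ts, spec = network_spec(), n_members = 5, seed = 1,
                           certainty_threshold = 0.90) {
  stopifnot(n_members >= 1, certainty_threshold > 0, certainty_threshold < 1)
  if (!isTRUE(attr(ts, "balanced"))) {
    warning("training set is not balanced; consider oversample_balance()",
            call. = FALSE)
  }
  if (!identical(attr(ts, "normalization"), "zscored")) {
    warning("training features are not z-scored", call. = FALSE)
  }
  members <- lapply(seq_len(n_members), function(m) {
    train_network(ts, spec, seed = seed + m * 7919L)
  })
  structure(list(members = members, spec = spec,
                 certainty_threshold = certainty_threshold,
                 features = members[[1]]$features, seed = seed,
                 center = attr(ts, "center"), scale = attr(ts, "scale")),
            class = "sleep_ensemble")
}

#' @export
print.sleep_ensemble <- function(x, ...) {
  cat(sprintf("<sleep_ensemble> %d networks (%s), %d features, certainty threshold %.2f\n",
              length(x$members),
              paste(c(x$spec$hidden, x$spec$n_classes), collapse = "-"),
              length(x$features), x$certainty_threshold))
  invisible(x)
}

#' Predict behavioral state with the ensemble
#'
#' Each member network emits softmax probabilities per epoch. The predicted
#' state is the modal (most frequent) per-member argmax, ties broken by the
#' highest mean probability; certainty is the mean probability the members
#' assign to that modal state, and epochs with certainty below the threshold
#' are flagged uncertain (candidates for manual rescoring).
#'
#' @param object A [train_ensemble()] model.
#' @param new_data A z-scored [feature_matrix()] (or plain data frame with
#'   the model's feature columns).
#' @param rows Optional integer row positions to predict (default all).
#' @param certainty_threshold Override the model's threshold.
#' @param ... Unused.
#' @return A [hypnogram()] tibble with columns `epoch`, `state`,
#'   `certainty`, `uncertain`, and mean per-state probabilities `p_W`,
#'   `p_NR`, `p_R` (summing to 1 per epoch).
#' @export
predict.sleep_ensemble <- function(object, new_data, rows = NULL,
                                   certainty_threshold = NULL, ...) {
  thr <- certainty_threshold %||% object$certainty_threshold
  missing_f <- setdiff(object$features, names(new_data))
  if (length(missing_f)) {
    stop("feature mismatch: new_data lacks ", paste(missing_f, collapse = ", "))
  }
  if (identical(attr(new_data, "normalization"), "raw")) {
    warning("new_data features are raw; the model expects z-scored input",
            call. = FALSE)
  }
  if (is.null(rows)) rows <- seq_len(nrow(new_data))
  X <- as.matrix(new_data[rows, object$features, drop = FALSE])
  n <- nrow(X)
  k <- length(sleep_states())
  p_mean <- matrix(0, n, k)
  votes <- matrix(0L, n, k)
  for (m in object$members) {
    p <- .mlp_forward(X, list(W = m$W, b = m$b))
    p_mean <- p_mean + p / length(object$members)
    am <- max.col(p, ties.method = "first")
    votes[cbind(seq_len(n), am)] <- votes[cbind(seq_len(n), am)] + 1L
  }
  # plurality vote; ties broken by the highest mean probability
  modal <- max.col(votes + p_mean, ties.method = "first")
  certainty <- p_mean[cbind(seq_len(n), modal)]
  epochs <- if (!is.null(new_data$epoch)) new_data$epoch[rows] else rows
  out <- tibble(
    epoch = as.integer(epochs), state = sleep_states()[modal],
    certainty = certainty, uncertain = certainty < thr,
    p_W = p_mean[, 1], p_NR = p_mean[, 2], p_R = p_mean[, 3]
  )
  as_hypnogram(out, attr(new_data, "epoch_length_s") %||% 4)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training trajectories of an ensemble
#'
#' @param x A `sleep_ensemble`.
#' @param ... Unused.
#' @return Tibble with columns `member`, `pass`, `loss`, `accuracy`.
#' @export
tidy.sleep_ensemble <- function(x, ...) {
  purrr::map_dfr(seq_along(x$members), function(m) {
    net <- x$members[[m]]
    tibble(member = m, pass = seq_along(net$loss),
           loss = net$loss, accuracy = net$accuracy)
  })
}

#' One-row summary of a trained ensemble
#'
#' @inheritParams tidy.sleep_ensemble
#' @return Tibble with member count, architecture, final mean training loss
#'   and accuracy.
#' @export
glance.sleep_ensemble <- function(x, ...) {
  tibble(
    n_members = length(x$members),
    architecture = paste(c(x$spec$hidden, x$spec$n_classes), collapse = "-"),
    n_features = length(x$features),
    passes = x$spec$passes,
    final_loss = mean(vapply(x$members, function(m) m$loss[length(m$loss)], 0)),
    final_accuracy = mean(vapply(x$members, function(m)
      m$accuracy[length(m$accuracy)], 0)),
    certainty_threshold = x$certainty_threshold
  )
}

#' Save / load an ensemble model bundle
#'
#' Serializes the model to a directory of portable JSON files: `spec.json`
#' (hyperparameters, seeds, feature names, normalization statistics) and
#' `member<i>.json` (per-member weights as nested arrays).
#'
#' @param model A `sleep_ensemble`.
#' @param dir Directory path (created if needed).
#' @return `save_ensemble()`: `dir` invisibly. `load_ensemble()`: the model.
#' @export
save_ensemble <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(spec = unclass(model$spec), seed = model$seed,
               certainty_threshold = model$certainty_threshold,
               features = model$features,
               center = as.list(model$center), scale = as.list(model$scale),
               n_members = length(model$members))
  jsonlite::write_json(meta, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(model$members)) {
    m <- model$members[[i]]
    jsonlite::write_json(
      list(W = lapply(m$W, identity), b = lapply(m$b, as.vector),
           seed = m$seed, loss = m$loss, accuracy = m$accuracy),
      file.path(dir, sprintf("member%d.json", i)), digits = NA)
  }
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "spec.json"), simplifyVector = TRUE)
  spec <- do.call(network_spec, meta$spec[c("hidden", "n_classes", "l2",
                                            "learning_rate", "passes",
                                            "batch_size")])
  members <- lapply(seq_len(meta$n_members), function(i) {
    raw <- jsonlite::read_json(file.path(dir, sprintf("member%d.json", i)),
                               simplifyVector = TRUE)
    structure(list(W = lapply(raw$W, as.matrix),
                   b = lapply(raw$b, as.numeric),
                   loss = raw$loss, accuracy = raw$accuracy, spec = spec,
                   seed = raw$seed, features = meta$features),
              class = "sleep_net")
  })
  structure(list(members = members, spec = spec,
                 certainty_threshold = meta$certainty_threshold,
                 features = meta$features, seed = meta$seed,
                 center = unlist(meta$center), scale = unlist(meta$scale)),
            class = "sleep_ensemble")
}
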