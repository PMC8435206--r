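# Shared fixtures, memoized so heavy synthetic runs happen once per suite.
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

# a short default-condition synthetic day (ground truth + signals + training)
short_dataset <- function() {
  memo("short_ds", generate_dataset(synth_config(duration_h = 0.5), seed = 402,
                                    n_series = 12, n_extra_rem = 15))
}

# fully scored short day (trains an ensemble; reused across tests)
short_scoring <- function() {
  memo("short_sc", {
    ds <- short_dataset()
    score_recording(ds$recording, ds$training, seed = 402)
  })
}

# well-separated 3-class Gaussian blobs as a z-scored balanced training set
blob_training_set <- function(n_per_class = 100, sep = 6, seed = 1,
                              p = 4) {
  set.seed(seed)
  centers <- matrix(0, 3, p)
  centers[2, 1] <- sep
  centers[3, 2] <- sep
  X <- do.call(rbind, lapply(1:3, function(k) {
    matrix(rnorm(n_per_class * p), n_per_class) + rep(centers[k, ], each = n_per_class)
  }))
  X <- scale(X)
  df <- tibble::as_tibble(as.data.frame(X))
  names(df) <- paste0("f", seq_len(p))
  out <- dplyr::bind_cols(
    tibble::tibble(epoch = seq_len(3 * n_per_class),
                   state = rep(sleep_states(), each = n_per_class)), df)
  attr(out, "normalization") <- "zscored"
  attr(out, "balanced") <- TRUE
  out
}

# fake ensemble whose members emit fixed softmax outputs regardless of input:
# zero weights everywhere, output biases chosen per member. probs: list of
# per-member length-3 probability vectors.
constant_ensemble <- function(probs, n_features = 2) {
  members <- lapply(probs, function(pr) {
    list(W = list(matrix(0, n_features, 3)), b = list(log(pr)))
  })
  structure(list(members = members, spec = network_spec(hidden = integer(0)),
                 certainty_threshold = 0.9,
                 features = paste0("f", seq_len(n_features)),
                 seed = 0, center = NULL, scale = NULL),
            class = "sleep_ensemble")
}

zscored_frame <- function(n, n_features = 2) {
  df <- tibble::as_tibble(as.data.frame(matrix(0, n, n_features)))
  names(df) <- paste0("f", seq_len(n_features))
  df$epoch <- seq_len(n)
  attr(df, "normalization") <- "zscored"
  df
}
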