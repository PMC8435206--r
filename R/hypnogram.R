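#' Construct a hypnogram
#'
#' A hypnogram is the per-epoch time series of behavioral-state labels
#' (`"W"`, `"NR"`, `"R"`), optionally annotated with prediction certainty,
#' an uncertain flag (certainty below threshold, eligible for manual
#' rescoring), and an artifact flag.
#'
#' @param state Character vector of per-epoch states.
#' @param epoch_length_s Epoch length in seconds (default 4).
#' @param certainty Optional numeric in `[0, 1]`, per epoch.
#' @param uncertain Optional logical, per epoch.
#' @param artifact Optional logical, per epoch.
#' @return Tibble of class `hypnogram` with column `epoch` (1-based) plus
#'   the supplied columns; attribute `epoch_length_s`.
#' @export
#' @examples
#' hypnogram(c("W", "W", "NR", "NR", "R"))
hypnogram <- function(state, epoch_length_s = 4, certainty = NULL,
                      uncertain = NULL, artifact = NULL) {
  assert_states(state)
  out <- tibble(epoch = seq_along(state), state = as.character(state))
  if (!is.null(certainty)) out$certainty <- as.numeric(certainty)
  if (!is.null(uncertain)) out$uncertain <- as.logical(uncertain)
  if (!is.null(artifact)) out$artifact <- as.logical(artifact)
  as_hypnogram(out, epoch_length_s)
}

as_hypnogram <- function(df, epoch_length_s = attr(df, "epoch_length_s") %||% 4) {
  stopifnot(all(c("epoch", "state") %in% names(df)))
  assert_states(df$state)
  attr(df, "epoch_length_s") <- epoch_length_s
  if (!inherits(df, "hypnogram")) class(df) <- c("hypnogram", class(df))
  df
}

# Character state vector of a hypnogram / character input.
states_of <- function(h) {
  if (is.character(h)) {
    assert_states(h)
    h
  } else if (is.data.frame(h)) {
    assert_states(h$state)
    h$state
  } else stop("expected a hypnogram tibble or character state vector")
}

epoch_len_of <- function(h, default = 4) {
  attr(h, "epoch_length_s") %||% default
}

# Return h with new states, preserving other columns / class.
set_states <- function(h, s) {
  if (is.character(h)) return(s)
  h$state <- s
  h
}

#' Read / write hypnogram TSV files
#'
#' The on-disk dialect is tab-separated with a header: `epoch_index`
#' (0-based), `state` (`W`/`NR`/`R`), and optional `certainty`, `uncertain`,
#' `artifact` columns. In-memory hypnograms use 1-based `epoch`.
#'
#' @param path File path.
#' @param epoch_length_s Epoch length metadata to attach on read.
#' @return `read_hypnogram()`: a [hypnogram()] tibble.
#' @export
read_hypnogram <- function(path, epoch_length_s = 4) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "state") %in% names(df))) {
    stop("hypnogram file needs columns epoch_index and state: ", path)
  }
  out <- tibble(epoch = as.integer(df$epoch_index) + 1L,
                state = as.character(df$state))
  for (cn in intersect(c("certainty", "uncertain", "artifact"), names(df))) {
    out[[cn]] <- df[[cn]]
  }
  as_hypnogram(out, epoch_length_s)
}

#' @param h A [hypnogram()] tibble.
#' @rdname read_hypnogram
#' @return `write_hypnogram()`: `path`, invisibly.
#' @export
write_hypnogram <- function(h, path) {
  df <- as.data.frame(h)
  df$epoch_index <- df$epoch - 1L
  keep <- intersect(c("epoch_index", "state", "certainty", "uncertain", "artifact"),
                    names(df))
  utils::write.table(df[keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs x %g s; states: %s\n", nrow(x),
              epoch_len_of(x),
              paste(sprintf("%s=%d", sleep_states(),
                            tabulate(factor(x$state, sleep_states()), 3)),
                    collapse = " ")))
  NextMethod()
}
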