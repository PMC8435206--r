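# Independent brute-force oracles used to cross-check the vectorized
# implementations. Written deliberately with explicit scans/loops.

# one-vs-rest metrics by direct per-epoch counting
naive_metrics <- function(pred, truth) {
  states <- sleep_states()
  n <- length(truth)
  acc <- 0
  for (i in seq_len(n)) if (pred[i] == truth[i]) acc <- acc + 1
  out <- list(accuracy = 100 * acc / n)
  for (st in states) {
    tp <- fn <- fp <- tn <- 0
    for (i in seq_len(n)) {
      if (truth[i] == st && pred[i] == st) tp <- tp + 1
      else if (truth[i] == st && pred[i] != st) fn <- fn + 1
      else if (truth[i] != st && pred[i] == st) fp <- fp + 1
      else tn <- tn + 1
    }
    out[[paste0("sens_", st)]] <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    out[[paste0("spec_", st)]] <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  }
  out
}

# literal scan versions of the three hypnogram rules
naive_fill <- function(s, max_ep = 3) {
  n <- length(s)
  i <- 1
  while (i <= n) {
    if (s[i] != "R") {
      j <- i
      while (j < n && s[j + 1] != "R") j <- j + 1
      if (i > 1 && j < n && (j - i + 1) <= max_ep &&
          s[i - 1] == "R" && s[j + 1] == "R") {
        for (k in i:j) s[k] <- "R"
      }
      i <- j + 1
    } else i <- i + 1
  }
  s
}

naive_forbid <- function(s) {
  repeat {
    changed <- FALSE
    for (i in seq_along(s)[-1]) {
      if (s[i] == "R" && s[i - 1] == "W") {
        s[i] <- "W"
        changed <- TRUE
      }
    }
    if (!changed) return(s)
  }
}

naive_smooth <- function(s) {
  out <- s
  if (length(s) >= 3) {
    for (i in 2:(length(s) - 1)) {
      if (s[i - 1] == s[i + 1] && s[i] != s[i - 1]) out[i] <- s[i - 1]
    }
  }
  out
}

naive_heuristics <- function(s, max_ep = 3) {
  repeat {
    before <- s
    s <- naive_smooth(naive_forbid(naive_fill(s, max_ep)))
    if (identical(s, before)) return(s)
  }
}

# all length-n state sequences
all_hypnograms <- function(n) {
  grid <- do.call(expand.grid,
                  c(rep(list(sleep_states()), n),
                    list(stringsAsFactors = FALSE)))
  lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, ], use.names = FALSE))
}
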