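# Independent brute-force re-implementations used as oracles.  These are
# deliberately written in the plainest possible style (per-element loops,
# nested ifs) and share no code with the package internals they check.

# staging rules, one epoch at a time
oracle_classify_one <- function(delta, sigma, gamma, ratio, emg, thr) {
  d_hi <- delta > thr$delta
  s_hi <- sigma > thr$sigma
  g_hi <- gamma > thr$gamma
  r_hi <- ratio > thr$theta_delta_ratio
  e_hi <- emg > thr$emg_power
  if (r_hi && !e_hi && !d_hi) return("R")
  if (d_hi && !r_hi && !e_hi) return("N")
  if (!e_hi && !d_hi && s_hi) return("N")
  if (!d_hi && e_hi) return("W")
  if (g_hi) return("W")
  NA_character_
}

oracle_classify <- function(features, thr) {
  out <- character(nrow(features))
  prev <- "W"
  for (i in seq_len(nrow(features))) {
    s <- oracle_classify_one(features$delta[i], features$sigma[i],
                             features$gamma[i], features$theta_delta_ratio[i],
                             features$emg_power[i], thr)
    if (is.na(s)) s <- prev
    out[i] <- s
    prev <- s
  }
  out
}

# run-length bouts by explicit scan
oracle_bouts <- function(states, epoch_s = 2.5) {
  res <- NULL
  i <- 1L
  while (i <= length(states)) {
    j <- i
    while (j < length(states) && states[j + 1L] == states[i]) j <- j + 1L
    res <- rbind(res, data.frame(state = states[i], start_epoch = i,
                                 end_epoch = j,
                                 duration_s = (j - i + 1L) * epoch_s))
    i <- j + 1L
  }
  res
}

# microarousals by explicit scan
oracle_mas <- function(states, epoch_s = 2.5, max_dur_s = 20) {
  b <- oracle_bouts(states, epoch_s)
  res <- NULL
  for (k in seq_len(nrow(b))) {
    if (b$state[k] != "W") next
    if (k == 1L || k == nrow(b)) next
    if (b$state[k - 1L] != "N" || b$state[k + 1L] != "N") next
    if (b$duration_s[k] > max_dur_s) next
    res <- rbind(res, data.frame(start_s = (b$start_epoch[k] - 1L) * epoch_s,
                                 duration_s = b$duration_s[k]))
  }
  res
}

# consolidated NREM spans by explicit epoch scan: an epoch belongs to a span
# if it is N, or part of a W run <= ma_max_s flanked by N on both sides
oracle_consolidated <- function(states, epoch_s = 2.5, min_span_s = 120,
                                ma_max_s = 20) {
  n <- length(states)
  bridgeable <- states == "N"
  b <- oracle_bouts(states, epoch_s)
  for (k in seq_len(nrow(b))) {
    if (b$state[k] == "W" && k > 1L && k < nrow(b) &&
        b$state[k - 1L] == "N" && b$state[k + 1L] == "N" &&
        b$duration_s[k] <= ma_max_s) {
      bridgeable[b$start_epoch[k]:b$end_epoch[k]] <- TRUE
    }
  }
  res <- NULL
  i <- 1L
  while (i <= n) {
    if (states[i] == "N") {
      j <- i
      while (j < n && bridgeable[j + 1L]) j <- j + 1L
      while (states[j] != "N") j <- j - 1L     # trim trailing bridged wake
      span <- (j - i + 1L) * epoch_s
      if (span >= min_span_s) {
        res <- rbind(res, data.frame(start_s = (i - 1L) * epoch_s,
                                     end_s = j * epoch_s, span_s = span))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  res
}

# brute-force candidate-run merging for the spindle assembler
oracle_assemble <- function(candidate, step_ms = 100, fuse_gap_ms = 300,
                            min_dur_ms = 200) {
  events <- NULL
  i <- 1L
  n <- length(candidate)
  while (i <= n) {
    if (candidate[i]) {
      j <- i
      while (j < n && candidate[j + 1L]) j <- j + 1L
      events <- rbind(events, c(i, j))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (is.null(events)) return(NULL)
  merged <- events[1, , drop = FALSE]
  for (k in seq_len(nrow(events))[-1]) {
    gap_ms <- (events[k, 1] - merged[nrow(merged), 2] - 1L) * step_ms
    if (gap_ms < fuse_gap_ms) {
      merged[nrow(merged), 2] <- events[k, 2]
    } else {
      merged <- rbind(merged, events[k, , drop = FALSE])
    }
  }
  keep <- (merged[, 2] - merged[, 1] + 1L) * step_ms > min_dur_ms
  merged <- merged[keep, , drop = FALSE]
  if (!nrow(merged)) NULL else merged
}

# O(n*m) transient/MA coincidence check
oracle_overlap <- function(times, ma, window_s) {
  hits <- 0L
  for (tt in times) {
    inside <- FALSE
    for (j in seq_len(nrow(ma))) {
      if (tt >= ma$start_s[j] - window_s &&
          tt <= ma$start_s[j] + ma$duration_s[j] + window_s) inside <- TRUE
    }
    if (inside) hits <- hits + 1L
  }
  if (length(times)) hits / length(times) else NaN
}

random_hypnogram <- function(n, prob = c(W = 0.3, N = 0.5, R = 0.2)) {
  new_hypnogram(sample(c("W", "N", "R"), n, replace = TRUE, prob = prob))
}

# a small spectrogram object with given power matrix, for feature tests
make_spectrogram <- function(power, freqs, step_s = 2.5) {
  structure(list(times = (seq_len(nrow(power)) - 1) * step_s, freqs = freqs,
                 power = power, fs = NA_real_, window_s = 2 * step_s,
                 step_s = step_s),
            class = "sleep_spectrogram")
}

random_features <- function(n) {
  f <- data.frame(delta = rexp(n), theta = rexp(n), sigma = rexp(n),
                  gamma = rexp(n), theta_delta_ratio = rexp(n),
                  emg_power = rexp(n))
  attr(f, "epoch_s") <- 2.5
  class(f) <- c("stage_features", "data.frame")
  f
}
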