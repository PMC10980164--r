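# Sleep-architecture statistics on top of the hypnogram: maximal-run bouts,
# microarousals, consolidated NREM bouts, state percentages, episode
# statistics, duration distributions, and the spatial-object-recognition
# behavioural metrics.

#' Maximal-run bouts of a hypnogram
#'
#' Run-length encodes the hypnogram into maximal same-state runs.  The bouts
#' partition the hypnogram: concatenating them reconstructs it exactly.
#'
#' @param hypnogram a `hypnogram`.
#' @return data.frame with columns `state`, `start_epoch`, `end_epoch`
#'   (1-based, inclusive), `start_s`, `duration_s`.
#' @export
detect_bouts <- function(hypnogram) {
  stopifnot(length(hypnogram) >= 1)
  ep <- attr(hypnogram, "epoch_s") %||% 2.5
  r <- rle(as.character(hypnogram))
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  data.frame(state = r$values, start_epoch = start, end_epoch = end,
             start_s = (start - 1L) * ep, duration_s = r$lengths * ep)
}

#' Microarousals: brief wake intrusions inside NREM
#'
#' A microarousal (MA) is a maximal wake run of duration at most `max_dur_s`
#' (default 20 s) immediately flanked by NREM epochs on both sides.  Wake
#' runs at the recording edge or adjacent to REM do not qualify.  The MA
#' rate is reported per hour of NREM time.
#'
#' @param hypnogram a `hypnogram`.
#' @param max_dur_s maximum MA duration in seconds (inclusive).
#' @return data.frame with columns `start_s`, `duration_s`, `start_epoch`,
#'   `end_epoch`; attributes `rate_per_h_nrem` and `nrem_hours`.
#' @export
detect_microarousals <- function(hypnogram, max_dur_s = 20) {
  ep <- attr(hypnogram, "epoch_s") %||% 2.5
  b <- detect_bouts(hypnogram)
  n <- nrow(b)
  is_ma <- b$state == "W" & b$duration_s <= max_dur_s &
    seq_len(n) > 1L & seq_len(n) < n &
    c("", b$state[-n]) == "N" & c(b$state[-1], "") == "N"
  ma <- b[is_ma, c("start_s", "duration_s", "start_epoch", "end_epoch")]
  rownames(ma) <- NULL
  nrem_hours <- sum(as.character(hypnogram) == "N") * ep / 3600
  attr(ma, "nrem_hours") <- nrem_hours
  attr(ma, "rate_per_h_nrem") <- if (nrem_hours > 0) nrow(ma) / nrem_hours else NaN
  ma
}

#' Consolidated NREM bouts
#'
#' NREM runs bridged across embedded microarousals (wake runs of at most
#' `ma_max_s` seconds flanked by NREM).  Any REM epoch, or a wake run longer
#' than `ma_max_s`, terminates a span.  Spans shorter than `min_span_s`
#' (default 120 s) are dropped.  The span duration INCLUDES the bridged MA
#' time.  These bouts are the unit over which infraslow sigma-power spectra
#' are computed.
#'
#' @param hypnogram a `hypnogram`.
#' @param min_span_s minimum bridged span in seconds.
#' @param ma_max_s maximum bridgeable wake-run duration in seconds.
#' @return data.frame with columns `start_s`, `end_s`, `span_s`,
#'   `start_epoch`, `end_epoch`, `n_ma`; attribute `ma_events` holding the
#'   embedded MAs per bout (list of data.frames).
#' @export
consolidate_nrem <- function(hypnogram, min_span_s = 120, ma_max_s = 20) {
  ep <- attr(hypnogram, "epoch_s") %||% 2.5
  b <- detect_bouts(hypnogram)
  n <- nrow(b)
  bridge <- b$state == "W" & b$duration_s <= ma_max_s &
    seq_len(n) > 1L & seq_len(n) < n &
    c("", b$state[-n]) == "N" & c(b$state[-1], "") == "N"
  spans <- list(); mas <- list()
  i <- 1L
  while (i <= n) {
    if (b$state[i] == "N") {
      j <- i
      ma_here <- list()
      while (j + 2L <= n && bridge[j + 1L] && b$state[j + 2L] == "N") {
        ma_here[[length(ma_here) + 1L]] <- b[j + 1L, ]
        j <- j + 2L
      }
      spans[[length(spans) + 1L]] <-
        data.frame(start_s = b$start_s[i],
                   end_s = b$start_s[j] + b$duration_s[j],
                   start_epoch = b$start_epoch[i], end_epoch = b$end_epoch[j],
                   n_ma = length(ma_here))
      mas[[length(mas) + 1L]] <- if (length(ma_here)) {
        do.call(rbind, ma_here)[, c("start_s", "duration_s")]
      } else data.frame(start_s = numeric(), duration_s = numeric())
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(spans)) {
    out <- data.frame(start_s = numeric(), end_s = numeric(),
                      span_s = numeric(), start_epoch = integer(),
                      end_epoch = integer(), n_ma = integer())
    attr(out, "ma_events") <- list()
    return(out)
  }
  out <- do.call(rbind, spans)
  out$span_s <- out$end_s - out$start_s
  keep <- out$span_s >= min_span_s
  out <- out[keep, c("start_s", "end_s", "span_s", "start_epoch",
                     "end_epoch", "n_ma")]
  rownames(out) <- NULL
  attr(out, "ma_events") <- mas[keep]
  out
}

#' Time-in-state percentages
#'
#' @param hypnogram a `hypnogram`.
#' @param interval optional `c(from_s, to_s)` half-open interval restricting
#'   the computation; default is the whole recording.
#' @return named numeric vector, percentages for `W`, `N`, `R` (summing to
#'   100 up to floating tolerance).
#' @export
state_percentages <- function(hypnogram, interval = NULL) {
  ep <- attr(hypnogram, "epoch_s") %||% 2.5
  st <- as.character(hypnogram)
  if (!is.null(interval)) {
    t0 <- (seq_along(st) - 1L) * ep
    st <- st[t0 >= interval[1] & t0 < interval[2]]
    if (!length(st)) stop("interval contains no epochs")
  }
  tab <- table(factor(st, levels = c("W", "N", "R")))
  p <- as.numeric(tab) / length(st) * 100
  names(p) <- c("W", "N", "R")
  p
}

#' Episode duration and frequency for one state
#'
#' @param bouts output of [detect_bouts()].
#' @param state one of `"W"`, `"N"`, `"R"`.
#' @param total_hours recording duration in hours (frequency denominator).
#' @return list with `mean_duration_s` (NaN when no bouts) and
#'   `frequency_per_h`.
#' @export
episode_stats <- function(bouts, state, total_hours) {
  stopifnot(total_hours > 0)
  d <- bouts$duration_s[bouts$state == state]
  list(mean_duration_s = if (length(d)) mean(d) else NaN,
       frequency_per_h = length(d) / total_hours)
}

#' Distribution of bout durations over bins
#'
#' @param bouts output of [detect_bouts()].
#' @param state state whose bouts are binned.
#' @param bin_edges_s increasing vector of bin edges in seconds; bin `j`
#'   is `[edges[j], edges[j+1])`.
#' @return numeric vector of proportions, one per bin (all zero when the
#'   state has no bouts).
#' @export
bout_duration_distribution <- function(bouts, state, bin_edges_s) {
  stopifnot(all(diff(bin_edges_s) > 0), length(bin_edges_s) >= 2)
  d <- bouts$duration_s[bouts$state == state]
  counts <- vapply(seq_len(length(bin_edges_s) - 1L), function(j) {
    sum(d >= bin_edges_s[j] & d < bin_edges_s[j + 1L])
  }, numeric(1))
  if (!length(d)) counts else counts / length(d)
}

#' Spatial-object-recognition preference metrics
#'
#' Preference (%) = T_novel / (T_familiar + T_novel) x 100 and
#' discrimination ratio = (T_novel - T_familiar) / (T_familiar + T_novel).
#' A session with total exploration below 2 s is flagged excluded and its
#' metrics are undefined (NaN).
#'
#' @param t_novel_s,t_familiar_s exploration times in seconds (>= 0).
#' @return list with `preference_pct`, `discrimination_ratio`, `excluded`.
#' @export
sor_metrics <- function(t_novel_s, t_familiar_s) {
  stopifnot(t_novel_s >= 0, t_familiar_s >= 0)
  total <- t_novel_s + t_familiar_s
  excluded <- total < 2
  if (total == 0) {
    return(list(preference_pct = NaN, discrimination_ratio = NaN,
                excluded = TRUE))
  }
  list(preference_pct = t_novel_s / total * 100,
       discrimination_ratio = (t_novel_s - t_familiar_s) / total,
       excluded = excluded)
}
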