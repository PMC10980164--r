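# Sound-evoked arousal analysis: trial eligibility (tone delivered during
# consolidated NREM), arousal vs sleep-through outcome, and the pre-tone
# sigma-power time course per outcome class.

#' Classify tone presentations into arousal and sleep-through trials
#'
#' A trial is eligible when the animal is in NREM at tone onset and the
#' NREM time accumulated up to the onset — bridged across microarousals
#' (wake runs of at most `ma_max_s` seconds flanked by NREM) — exceeds
#' `min_nrem_s`.  With `eligibility = "episode"` the TOTAL bridged episode
#' span containing the onset is measured instead.  An eligible trial is an
#' arousal when any wake epoch occurs within `[onset, onset + tone_dur_s]`,
#' otherwise a sleep-through.
#'
#' @param hypnogram a `hypnogram`.
#' @param tone_onsets tone onset times in seconds.
#' @param tone_dur_s tone duration (s).
#' @param min_nrem_s minimum (bridged) NREM duration for eligibility;
#'   strict >.
#' @param ma_max_s maximum bridgeable wake-run duration (s).
#' @param eligibility `"pre_onset"` (default) measures NREM up to the
#'   onset; `"episode"` measures the whole bridged episode.
#' @return data.frame of class `tone_trials` with columns `onset_s`,
#'   `eligible`, `outcome` (`"arousal"`, `"sleep_through"` or
#'   `"ineligible"`), `nrem_before_s`; attribute `arousal_pct` (percentage
#'   of eligible trials with arousal outcome).
#' @export
classify_tone_trials <- function(hypnogram, tone_onsets, tone_dur_s = 20,
                                 min_nrem_s = 120, ma_max_s = 20,
                                 eligibility = c("pre_onset", "episode")) {
  eligibility <- match.arg(eligibility)
  ep <- attr(hypnogram, "epoch_s") %||% 2.5
  st <- as.character(hypnogram)
  n <- length(st)
  spans <- consolidate_nrem(hypnogram, min_span_s = 0, ma_max_s = ma_max_s)
  trials <- lapply(tone_onsets, function(onset) {
    epo <- floor(onset / ep) + 1L
    if (epo < 1L || epo > n) {
      return(data.frame(onset_s = onset, eligible = FALSE,
                        outcome = "ineligible", nrem_before_s = NA_real_))
    }
    if (st[epo] != "N") {
      return(data.frame(onset_s = onset, eligible = FALSE,
                        outcome = "ineligible", nrem_before_s = 0))
    }
    sp <- which(spans$start_s <= onset & spans$end_s > onset)
    measured <- if (length(sp)) {
      if (eligibility == "pre_onset") onset - spans$start_s[sp[1]]
      else spans$span_s[sp[1]]
    } else 0
    if (measured <= min_nrem_s) {
      return(data.frame(onset_s = onset, eligible = FALSE,
                        outcome = "ineligible", nrem_before_s = measured))
    }
    win <- epo:min(n, floor((onset + tone_dur_s) / ep) + 1L)
    outcome <- if (any(st[win] == "W")) "arousal" else "sleep_through"
    data.frame(onset_s = onset, eligible = TRUE, outcome = outcome,
               nrem_before_s = measured)
  })
  out <- do.call(rbind, trials)
  rownames(out) <- NULL
  elig <- out$eligible
  attr(out, "arousal_pct") <- if (any(elig))
    mean(out$outcome[elig] == "arousal") * 100 else NaN
  class(out) <- c("tone_trials", "data.frame")
  out
}

#' @export
print.tone_trials <- function(x, ...) {
  cat("<tone_trials> ", nrow(x), " tones, ", sum(x$eligible),
      " eligible; arousal ", round(attr(x, "arousal_pct"), 1), "%\n", sep = "")
  invisible(x)
}

#' Mean pre-tone sigma-power trace per outcome class
#'
#' For each eligible trial the normalized sigma-power time course is aligned
#' to tone onset over `[-pre_window_s, 0)` and averaged within outcome
#' class.  Classes without trials are omitted with a warning.
#'
#' @param sigma_tc a `sigma_timecourse`.
#' @param trials output of [classify_tone_trials()].
#' @param pre_window_s pre-tone window length (s).
#' @return list, one element per available class (`arousal`,
#'   `sleep_through`), each a list with `lag_s` (negative, bin starts),
#'   `mean` and `n` (trials contributing per time point).
#' @export
peri_tone_sigma <- function(sigma_tc, trials, pre_window_s = 60) {
  stopifnot(inherits(sigma_tc, "sigma_timecourse"))
  dt <- sigma_tc$step_s
  nlag <- floor(pre_window_s / dt)
  lag_s <- -rev(seq_len(nlag)) * dt
  out <- list()
  for (cls in c("arousal", "sleep_through")) {
    sel <- trials$eligible & trials$outcome == cls
    if (!any(sel)) {
      warning("no ", cls, " trials; class omitted")
      next
    }
    traces <- vapply(trials$onset_s[sel], function(onset) {
      idx <- round((onset + lag_s) / dt) + 1L
      v <- rep(NA_real_, nlag)
      ok <- idx >= 1L & idx <= length(sigma_tc$values)
      v[ok] <- sigma_tc$values[idx[ok]]
      v
    }, numeric(nlag))
    traces <- matrix(traces, nrow = nlag)
    out[[cls]] <- list(lag_s = lag_s,
                       mean = rowMeans(traces, na.rm = TRUE),
                       n = rowSums(!is.na(traces)))
  }
  out
}

#' Slope of a mean pre-tone sigma trace
#'
#' Ordinary least-squares slope of the class-mean trace over the final
#' `fit_window_s` seconds before onset — the window over which the
#' descending-phase signature is expressed.
#'
#' @param peri one class element from [peri_tone_sigma()].
#' @param fit_window_s window before onset to fit (s).
#' @return slope in normalized sigma power per second.
#' @export
pre_tone_slope <- function(peri, fit_window_s = 15) {
  sel <- peri$lag_s >= -fit_window_s
  unname(stats::coef(stats::lm(peri$mean[sel] ~ peri$lag_s[sel]))[2])
}
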