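#' Sleep-architecture summary
#'
#' Computes the standard whole-night summary from a 30-s-epoch hypnogram.
#' Total sleep duration spans the first wake-to-sleep transition to the last
#' sleep-to-wake transition; total sleep time (TST) is the time in any
#' non-wake stage; wake after sleep onset (WASO) is wake inside that span;
#' stage percentages are expressed relative to TST (NREM counts N2 and N3
#' only); sleep efficiency is TST as a percentage of the total sleep
#' duration; sleep latency runs from the record start to the first non-wake
#' epoch; REM segments are maximal runs of R epochs.
#'
#' @param hypnogram A [hypnogram()].
#' @return A one-row tibble: `recording_min`, `tsd_min` (total sleep
#'   duration), `tst_min`, `latency_min`, `waso_min`, `efficiency_pct`,
#'   `n1_pct`, `n2_pct`, `n3_pct`, `nrem_pct`, `rem_pct` (all on TST),
#'   `rem_min`, `n_rem_segments`, `arousal_count`, `all_wake` (flag for the
#'   degenerate all-wake night, in which the sleep quantities are NA).
#' @examples
#' sleep_summary(hypnogram(c("W", "N2", "N2", "R", "W")))
#' @export
sleep_summary <- function(hypnogram) {
  stopifnot(inherits(hypnogram, "hypnogram"))
  st <- hypnogram$stages
  el_min <- hypnogram$epoch_len_s / 60
  rec_min <- length(st) * el_min
  sleep <- st != "W"
  if (!any(sleep)) {
    return(tibble(recording_min = rec_min, tsd_min = NA_real_,
                  tst_min = NA_real_, latency_min = NA_real_,
                  waso_min = NA_real_, efficiency_pct = NA_real_,
                  n1_pct = NA_real_, n2_pct = NA_real_, n3_pct = NA_real_,
                  nrem_pct = NA_real_, rem_pct = NA_real_, rem_min = NA_real_,
                  n_rem_segments = 0L,
                  arousal_count = nrow(hypnogram$arousals),
                  all_wake = TRUE))
  }
  first_sleep <- which(sleep)[1]
  last_sleep <- tail(which(sleep), 1)
  span <- first_sleep:last_sleep
  tsd_min <- length(span) * el_min
  tst_min <- sum(sleep) * el_min
  waso_min <- sum(!sleep[span]) * el_min
  pct <- function(stage_set) {
    100 * sum(st %in% stage_set) * el_min / tst_min
  }
  runs <- rle(st)
  tibble(recording_min = rec_min, tsd_min = tsd_min, tst_min = tst_min,
         latency_min = (first_sleep - 1) * el_min, waso_min = waso_min,
         efficiency_pct = 100 * tst_min / tsd_min,
         n1_pct = pct("N1"), n2_pct = pct("N2"), n3_pct = pct("N3"),
         nrem_pct = pct(c("N2", "N3")), rem_pct = pct("R"),
         rem_min = sum(st == "R") * el_min,
         n_rem_segments = sum(runs$values == "R"),
         arousal_count = nrow(hypnogram$arousals),
         all_wake = FALSE)
}

#' Offline eye-movement detection
#'
#' Re-applies the online amplitude-threshold rule offline: the EOG is
#' band-limited with the zero-phase offline EOG filter, and threshold
#' crossings during R epochs are collected with a 0.5 s refractory so one
#' biphasic saccade is not counted twice. Events outside R epochs are
#' discarded.
#'
#' @param eog A [psg_signal()] (raw; filtering is applied internally unless
#'   `prefiltered`).
#' @param hypnogram A [hypnogram()].
#' @param threshold_uv Detection threshold in (0, 500].
#' @param refractory_s Minimum separation between detected events.
#' @param prefiltered Set `TRUE` if `eog` is already filtered.
#' @return A tibble of events: `onset_s`, `peak_uv` (signed peak within the
#'   0.5 s after onset), `epoch`.
#' @export
detect_em_offline <- function(eog, hypnogram, threshold_uv = 50,
                              refractory_s = 0.5, prefiltered = FALSE) {
  stopifnot(inherits(eog, "psg_signal"), inherits(hypnogram, "hypnogram"))
  if (threshold_uv <= 0 || threshold_uv > 500) {
    abort("threshold_uv must be in (0, 500].",
          class = "remstim_invalid_parameter")
  }
  x <- eog$samples
  if (!prefiltered) {
    d <- design_cheby2_bandpass(filter_spec("offline_eog"), eog$fs)
    x <- apply_filter(d, x, mode = "zero_phase")
  }
  t_axis <- signal_times(eog)
  cand <- which(abs(x) >= threshold_uv)
  onsets <- numeric(0)
  peaks <- numeric(0)
  last <- -Inf
  for (i in cand) {
    ti <- t_axis[i]
    if (ti >= last + refractory_s) {
      j <- i:min(i + round(0.5 * eog$fs), length(x))
      onsets <- c(onsets, ti)
      peaks <- c(peaks, x[j][which.max(abs(x[j]))])
      last <- ti
    }
  }
  keep <- !is.na(stage_at(hypnogram, onsets)) & stage_at(hypnogram, onsets) == "R"
  tibble(onset_s = onsets[keep], peak_uv = peaks[keep],
         epoch = epoch_at(hypnogram, onsets[keep]))
}

#' Classify REM epochs as phasic or tonic
#'
#' An R epoch is phasic if at least one eye-movement onset falls inside it,
#' tonic otherwise; non-R epochs are unlabelled (NA).
#'
#' @param hypnogram A [hypnogram()].
#' @param em_events Tibble with an `onset_s` column (e.g. from
#'   [detect_em_offline()]) or a numeric vector of onset times.
#' @return A tibble: `epoch`, `stage`, `rem_type` (`"phasic"`, `"tonic"`, or
#'   NA).
#' @export
classify_rem_epochs <- function(hypnogram, em_events) {
  stopifnot(inherits(hypnogram, "hypnogram"))
  onsets <- if (is.numeric(em_events)) em_events else em_events$onset_s
  if (is.unsorted(onsets)) {
    abort("Eye-movement events must be time-sorted.",
          class = "remstim_invalid_parameter")
  }
  h <- as_tibble(hypnogram)
  em_ep <- epoch_at(hypnogram, onsets)
  h$rem_type <- ifelse(h$stage != "R", NA_character_,
                       ifelse(h$epoch %in% em_ep, "phasic", "tonic"))
  h[c("epoch", "stage", "rem_type")]
}

#' Eye-movement statistics
#'
#' Computes eye-movement density (events per minute of REM), the mean
#' inter-movement interval within REM segments (gaps spanning a non-REM
#' interruption are not counted), and the probability that a click is
#' followed by at least one eye-movement onset within `window_s`.
#'
#' @param em_events Event tibble (or numeric onset vector).
#' @param click_events Click times: event tibble from [run_em_detector()]
#'   (its `click` rows are used) or a numeric vector; may be empty.
#' @param hypnogram A [hypnogram()].
#' @param window_s Post-click detection window (seconds).
#' @return A one-row tibble: `total_em`, `rem_min`, `em_density_per_min`,
#'   `inter_em_interval_s`, `n_clicks`, `p_em_after_click`,
#'   `rem_undefined` (flag: no REM time, density NA).
#' @export
em_statistics <- function(em_events, click_events = NULL, hypnogram,
                          window_s = 2.5) {
  stopifnot(inherits(hypnogram, "hypnogram"))
  onsets <- if (is.numeric(em_events) || is.null(em_events)) {
    as.numeric(em_events)
  } else {
    em_events$onset_s
  }
  clicks <- if (is.null(click_events)) {
    numeric(0)
  } else if (is.numeric(click_events)) {
    click_events
  } else {
    click_events$t_s[click_events$type == "click"]
  }
  rem_min <- sum(hypnogram$stages == "R") * hypnogram$epoch_len_s / 60
  density <- if (rem_min > 0) length(onsets) / rem_min else NA_real_
  # inter-EM gaps within the same maximal REM run
  seg <- cumsum(c(1, diff(hypnogram$stages == "R") != 0))
  em_seg <- seg[epoch_at(hypnogram, onsets)]
  gaps <- unlist(lapply(split(onsets, em_seg), function(v) diff(v)))
  iei <- if (length(gaps) > 0) mean(gaps) else NA_real_
  p_after <- if (length(clicks) > 0) {
    mean(vapply(clicks, function(tc) {
      any(onsets > tc & onsets <= tc + window_s)
    }, logical(1)))
  } else {
    NA_real_
  }
  if (length(onsets) == 0) p_after <- if (length(clicks) > 0) 0 else NA_real_
  tibble(total_em = length(onsets), rem_min = rem_min,
         em_density_per_min = if (length(onsets) == 0 && rem_min > 0) 0 else density,
         inter_em_interval_s = iei, n_clicks = length(clicks),
         p_em_after_click = p_after, rem_undefined = rem_min <= 0)
}
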