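#' Stimulator configuration
#'
#' Parameters of the semi-automatic eye-movement-locked click stimulator:
#' the EOG amplitude threshold (tuned per night between 50 and 100 uV), the
#' fixed 100 ms delay between threshold crossing and click onset, the
#' detection pause after each stimulus, and whether clicks are muted (the
#' control night runs the identical detection protocol with muted clicks).
#'
#' The detection pause defaults to 2 s; the alternative 2.5 s convention is
#' available through the `refractory_s` knob.
#'
#' @param threshold_uv Detection threshold on absolute filtered EOG
#'   amplitude, microvolts.
#' @param click_delay_s Delay from threshold crossing to click onset.
#' @param refractory_s Detection pause after each stimulus, seconds.
#' @param muted Logical: `TRUE` for the control (CNT) condition.
#' @param fs Sampling rate the detector expects.
#' @param prefiltered Logical: `TRUE` if the EOG passed to the detector is
#'   already band-limited by the online EOG filter; if `FALSE` the detector
#'   applies that filter causally itself.
#' @return A `stimulator_config` object.
#' @export
stimulator_config <- function(threshold_uv = 75, click_delay_s = 0.100,
                              refractory_s = 2.0, muted = FALSE, fs = 500,
                              prefiltered = TRUE) {
  check_scalar(threshold_uv, "threshold_uv")
  check_scalar(refractory_s, "refractory_s")
  check_scalar(fs, "fs")
  if (click_delay_s < 0) {
    abort("click_delay_s must be >= 0.", class = "remstim_invalid_parameter")
  }
  structure(list(threshold_uv = threshold_uv, click_delay_s = click_delay_s,
                 refractory_s = refractory_s, muted = isTRUE(muted), fs = fs,
                 prefiltered = isTRUE(prefiltered)),
            class = "stimulator_config")
}

#' Pink-noise click waveform
#'
#' The auditory stimulus: 50 ms of pink (1/f-power) noise with linear rising
#' and falling ramps of 5 ms each, identical on both stereo channels.
#'
#' @param fs Audio sampling rate, >= 8000 Hz.
#' @param duration_s,ramp_s Click duration and ramp length (seconds).
#' @param seed Integer seed for the noise.
#' @return A numeric matrix with `round(duration_s * fs)` rows and two
#'   identical columns (left, right), peak-normalized to 1.
#' @export
make_click_waveform <- function(fs = 44100, duration_s = 0.050,
                                ramp_s = 0.005, seed = NULL) {
  if (fs < 8000) {
    abort("Audio sampling rate must be >= 8000 Hz.",
          class = "remstim_invalid_parameter")
  }
  n <- round(duration_s * fs)
  with_seed(seed, {
    x <- pink_noise(n, fs, rms = 1)
    nr <- round(ramp_s * fs)
    env <- rep(1, n)
    env[seq_len(nr)] <- seq(0, 1, length.out = nr)
    env[(n - nr + 1):n] <- seq(1, 0, length.out = nr)
    x <- x * env
    x <- x / max(abs(x))
    cbind(left = x, right = x)
  })
}

#' Operator gating surrogate: enable stimulation in stable REM
#'
#' Deterministic stand-in for the human operator who switched detection on
#' after a stretch of stable REM and off at any stage change or sign of
#' arousal: emits `stim_on` when `stable_epochs` consecutive R epochs have
#' accrued and `stim_off` at the next non-R epoch or at the onset of an
#' annotated arousal inside REM.
#'
#' @param hypnogram A [hypnogram()].
#' @param stable_epochs Consecutive R epochs required before enabling.
#' @return A tibble of gate events: columns `t_s`, `type`
#'   (`stim_on`/`stim_off`), `stage`.
#' @export
gate_stimulation <- function(hypnogram, stable_epochs = 2) {
  stopifnot(inherits(hypnogram, "hypnogram"))
  st <- hypnogram$stages
  el <- hypnogram$epoch_len_s
  t0 <- hypnogram$record_start_s
  ev_t <- numeric(0)
  ev_type <- character(0)
  on <- FALSE
  run <- 0L
  for (i in seq_along(st)) {
    ep_start <- t0 + (i - 1) * el
    if (st[i] == "R") {
      run <- run + 1L
      if (!on && run >= stable_epochs) {
        on <- TRUE
        ev_t <- c(ev_t, ep_start)
        ev_type <- c(ev_type, "stim_on")
      }
      if (on) {
        ar <- hypnogram$arousals
        hit <- ar$onset_s >= ep_start & ar$onset_s < ep_start + el
        if (any(hit)) {
          ev_t <- c(ev_t, min(ar$onset_s[hit]))
          ev_type <- c(ev_type, "stim_off")
          on <- FALSE
          run <- 0L
        }
      }
    } else {
      run <- 0L
      if (on) {
        ev_t <- c(ev_t, ep_start)
        ev_type <- c(ev_type, "stim_off")
        on <- FALSE
      }
    }
  }
  if (on) {
    ev_t <- c(ev_t, t0 + length(st) * el)
    ev_type <- c(ev_type, "stim_off")
  }
  tibble(t_s = ev_t, type = ev_type, stage = stage_at(hypnogram, ev_t))
}

# enabled intervals (start, end) from a gate-event tibble
gate_intervals <- function(gate_events, t_end) {
  if (is.null(gate_events) || nrow(gate_events) == 0) {
    return(tibble(start_s = numeric(0), end_s = numeric(0)))
  }
  if (is.unsorted(gate_events$t_s)) {
    abort("Gate events must be time-sorted.",
          class = "remstim_invalid_parameter")
  }
  starts <- numeric(0)
  ends <- numeric(0)
  open <- NA_real_
  for (i in seq_len(nrow(gate_events))) {
    if (gate_events$type[i] == "stim_on" && is.na(open)) {
      open <- gate_events$t_s[i]
    } else if (gate_events$type[i] == "stim_off" && !is.na(open)) {
      starts <- c(starts, open)
      ends <- c(ends, gate_events$t_s[i])
      open <- NA_real_
    }
  }
  if (!is.na(open)) {
    starts <- c(starts, open)
    ends <- c(ends, t_end)
  }
  tibble(start_s = starts, end_s = ends)
}

#' Run the streaming eye-movement detector
#'
#' Simulates the online detection algorithm sample by sample in time order:
#' while stimulation is enabled (per the gate events) and the detector is
#' not in its refractory pause, the first sample whose absolute amplitude
#' reaches the threshold triggers an `em_detected` event at the crossing
#' time and a `click` event `click_delay_s` later; detection then pauses for
#' `refractory_s`. The muted (control) condition logs identical events with
#' the `muted` flag set. The implementation scans threshold crossings with a
#' forward-greedy pass, which is exactly equivalent to the per-sample state
#' machine and therefore causal: output up to time t never depends on
#' samples after t.
#'
#' @param eog A [psg_signal()]; already band-limited by the online EOG
#'   filter when `config$prefiltered` is `TRUE`, raw otherwise.
#' @param config A [stimulator_config()].
#' @param gate_events Gate tibble from [gate_stimulation()], or `NULL` to
#'   treat the whole record as enabled.
#' @param hypnogram Optional [hypnogram()] used to tag events with their
#'   sleep stage.
#' @return An event log tibble: columns `t_s`, `type`, `stage`, `muted`.
#' @export
run_em_detector <- function(eog, config = stimulator_config(),
                            gate_events = NULL, hypnogram = NULL) {
  stopifnot(inherits(eog, "psg_signal"), inherits(config, "stimulator_config"))
  x <- eog$samples
  fs <- eog$fs
  if (!config$prefiltered) {
    d <- design_cheby2_bandpass(filter_spec("online_eog"), fs)
    x <- apply_filter(d, x, mode = "causal")
  }
  t_end <- eog$start_s + length(x) / fs
  iv <- if (is.null(gate_events)) {
    tibble(start_s = eog$start_s, end_s = t_end)
  } else {
    gate_intervals(gate_events, t_end)
  }
  t_axis <- signal_times(eog)
  enabled <- rep(FALSE, length(x))
  for (i in seq_len(nrow(iv))) {
    enabled <- enabled | (t_axis >= iv$start_s[i] & t_axis < iv$end_s[i])
  }
  cand <- which(abs(x) >= config$threshold_uv & enabled)
  det_t <- numeric(0)
  pause_until <- -Inf                     # detection paused after each stimulus
  for (i in cand) {                       # forward-greedy over candidates
    ti <- t_axis[i]
    if (ti >= pause_until) {
      det_t <- c(det_t, ti)
      pause_until <- ti + config$click_delay_s + config$refractory_s
    }
  }
  if (length(det_t) == 0) {
    return(tibble(t_s = numeric(0), type = character(0),
                  stage = character(0), muted = logical(0)))
  }
  ev <- tibble(
    t_s = c(det_t, det_t + config$click_delay_s),
    type = rep(c("em_detected", "click"), each = length(det_t))
  ) |>
    dplyr::arrange(.data$t_s, .data$type)
  ev$stage <- if (is.null(hypnogram)) NA_character_ else stage_at(hypnogram, ev$t_s)
  ev$muted <- config$muted
  ev
}

#' Stimulation accuracy report
#'
#' Summarizes how well clicks were locked to REM sleep and to the triggering
#' eye movement: the percentage of clicks whose onset lies inside an R
#' epoch, and the percentage of clicks falling within the extent of a
#' ground-truth eye movement (onset to onset + `window_s`).
#'
#' @param events Event tibble from [run_em_detector()].
#' @param hypnogram A [hypnogram()].
#' @param true_em_times Ground-truth saccade onset times, seconds.
#' @param window_s Saccade extent used for the on-EM criterion (defaults to
#'   the generator's saccade width, 0.3 s).
#' @return A one-row tibble: `n_clicks`, `n_in_rem`, `pct_in_rem`,
#'   `n_on_em`, `pct_on_em`, `empty` (flag set when there were no clicks and
#'   the percentages are undefined).
#' @export
stimulation_accuracy <- function(events, hypnogram, true_em_times = NULL,
                                 window_s = 0.3) {
  check_scalar(window_s, "window_s")
  clicks <- events$t_s[events$type == "click"]
  n <- length(clicks)
  if (n == 0) {
    return(tibble(n_clicks = 0L, n_in_rem = 0L, pct_in_rem = NA_real_,
                  n_on_em = 0L, pct_on_em = NA_real_, empty = TRUE))
  }
  in_rem <- stage_at(hypnogram, clicks) == "R"
  in_rem[is.na(in_rem)] <- FALSE
  on_em <- if (is.null(true_em_times) || length(true_em_times) == 0) {
    rep(FALSE, n)
  } else {
    vapply(clicks, function(tc) {
      any(tc >= true_em_times & tc <= true_em_times + window_s)
    }, logical(1))
  }
  tibble(n_clicks = n, n_in_rem = sum(in_rem),
         pct_in_rem = 100 * mean(in_rem),
         n_on_em = sum(on_em), pct_on_em = 100 * mean(on_em),
         empty = FALSE)
}
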