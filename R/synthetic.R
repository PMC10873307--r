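#' Generate a synthetic hypnogram
#'
#' Draws a bout-structured stage sequence: bout stages are sampled from
#' `stage_fractions` and bout lengths from a shifted Poisson with the given
#' mean, so empirical stage fractions converge to the request as the night
#' grows. The night starts with a short wake bout (sleep latency) and ends
#' with a wake epoch so that sleep-summary transition definitions are always
#' well formed. Arousals are placed in sleep, artifacts anywhere.
#'
#' Default fractions follow the control-night sleep architecture the
#' generator is meant to emulate (about 18% of sleep time in REM, with wake
#' making up the complement of a ~92% sleep efficiency).
#'
#' @param duration_min Recording length in minutes; must be a multiple of
#'   0.5 (30-s epochs).
#' @param stage_fractions Named numeric over `W`, `N1`, `N2`, `N3`, `R`,
#'   summing to 1.
#' @param mean_bout_len_s Mean bout length in seconds.
#' @param arousal_rate_per_h,artifact_rate_per_h Annotation rates.
#' @param seed Integer seed; identical seeds give identical hypnograms.
#' @return A [hypnogram()].
#' @examples
#' h <- generate_hypnogram(120, seed = 1)
#' sleep_summary(h)
#' @export
generate_hypnogram <- function(duration_min,
                               stage_fractions = c(W = 0.0822, N1 = 0.0980,
                                                   N2 = 0.3893, N3 = 0.2567,
                                                   R = 0.1738),
                               mean_bout_len_s = 300,
                               arousal_rate_per_h = 8,
                               artifact_rate_per_h = 4,
                               seed = NULL) {
  check_scalar(duration_min, "duration_min")
  n_epoch <- duration_min * 60 / 30
  if (abs(n_epoch - round(n_epoch)) > 1e-9) {
    abort("duration_min must be a multiple of 0.5 (whole 30-s epochs).",
          class = "remstim_invalid_parameter")
  }
  n_epoch <- as.integer(round(n_epoch))
  stages_all <- c("W", "N1", "N2", "N3", "R")
  if (!all(stages_all %in% names(stage_fractions)) ||
      abs(sum(stage_fractions) - 1) > 1e-9) {
    abort("stage_fractions must cover W, N1, N2, N3, R and sum to 1.",
          class = "remstim_invalid_parameter")
  }
  fr <- stage_fractions[stages_all]
  mean_bout_ep <- max(mean_bout_len_s / 30, 1)
  with_seed(seed, {
    seq_st <- character(0)
    if (fr[["W"]] > 0 && fr[["W"]] < 1) {
      seq_st <- rep("W", 1 + rpois(1, 1))   # sleep latency
    }
    # remaining-quota bout sampling: bout stages are drawn in proportion to
    # the unfilled share of each stage's target epoch count, so empirical
    # fractions converge to the request as the night grows
    target <- fr * n_epoch
    counts <- stats::setNames(numeric(5), stages_all)
    counts["W"] <- length(seq_st)
    while (length(seq_st) < n_epoch) {
      remq <- pmax(target - counts, 0)
      pr <- if (sum(remq) > 0) remq else fr
      st <- sample(stages_all, 1, prob = pr)
      len <- 1 + rpois(1, mean_bout_ep - 1)
      if (remq[st] > 0) len <- min(len, max(1, round(remq[st])))
      seq_st <- c(seq_st, rep(st, len))
      counts[st] <- counts[st] + len
    }
    seq_st <- seq_st[seq_len(n_epoch)]
    if (n_epoch > 1 && fr[["W"]] > 0 && fr[["W"]] < 1) {
      seq_st[n_epoch] <- "W"                # final awakening
    }
    dur_s <- n_epoch * 30
    sleep_idx <- which(seq_st != "W")
    draw_ann <- function(rate_per_h, idx_pool, dmin, dmax) {
      n_ann <- rpois(1, rate_per_h * dur_s / 3600)
      if (n_ann == 0 || length(idx_pool) == 0) {
        return(tibble(onset_s = numeric(0), duration_s = numeric(0)))
      }
      ep <- sample(idx_pool, n_ann, replace = TRUE)
      dur <- runif(n_ann, dmin, dmax)
      onset <- (ep - 1) * 30 + runif(n_ann, 0, pmax(30 - dur, 0.1))
      tibble(onset_s = sort(onset), duration_s = dur[order(onset)])
    }
    ar <- draw_ann(arousal_rate_per_h, sleep_idx, 3, 15)
    af <- draw_ann(artifact_rate_per_h, seq_len(n_epoch), 1, 10)
    hypnogram(seq_st, arousals = ar, artifacts = af)
  })
}

# biphasic raised-cosine saccade pulse: +A lobe then -A lobe, total width w
saccade_pulse <- function(width_s, fs) {
  n <- max(round(width_s * fs), 4)
  half <- floor(n / 2)
  rest <- n - half
  lobe1 <- 0.5 * (1 - cos(2 * pi * seq_len(half) / (half + 1)))
  lobe2 <- 0.5 * (1 - cos(2 * pi * seq_len(rest) / (rest + 1)))
  p <- c(lobe1, -lobe2)
  p / max(abs(p))
}

# 1/f-amplitude-shaped ("pink") Gaussian noise with a target RMS
pink_noise <- function(n, fs, rms, exponent = 1) {
  nf <- 2^ceiling(log2(max(n, 2)))
  wh <- rnorm(nf)
  sp <- fft(wh)
  f <- c(0, seq_len(nf - 1)) * fs / nf
  f <- pmin(f, fs - f)
  shape <- ifelse(f > 0, f^(-exponent / 2), 0)
  x <- Re(fft(sp * shape, inverse = TRUE))[seq_len(n)]
  x * rms / sd(x)
}

#' Generate synthetic REM-sleep EOG with ground-truth saccades
#'
#' Places biphasic raised-cosine saccade deflections at Poisson times
#' restricted to REM epochs of the hypnogram, on top of low-amplitude pink
#' background noise. Returned saccade onset times are the exact ground truth
#' used by detector recall/precision checks. Saccades closer than 0.6 s to
#' the previous one are thinned so individual deflections stay resolvable.
#'
#' @param hypnogram A [hypnogram()].
#' @param saccade_rate_per_min Poisson rate of saccades during REM.
#' @param amp_range_uv Length-2 amplitude range in microvolts (absolute
#'   saccade amplitude drawn uniformly); must lie in (0, 500].
#' @param fs Sampling rate in Hz.
#' @param noise_rms_uv Background noise RMS (well below the amplitudes).
#' @param width_s Saccade pulse width in seconds.
#' @param label Channel label.
#' @param seed Integer seed.
#' @return A list with `signal` (a [psg_signal()]) and `em_times_s` (numeric
#'   vector of true saccade onset times).
#' @export
generate_rem_eog <- function(hypnogram, saccade_rate_per_min = 6,
                             amp_range_uv = c(50, 100), fs = 500,
                             noise_rms_uv = 5, width_s = 0.3,
                             label = "EOG-L", seed = NULL) {
  stopifnot(inherits(hypnogram, "hypnogram"))
  check_scalar(fs, "fs")
  if (saccade_rate_per_min < 0) {
    abort("saccade_rate_per_min must be >= 0.",
          class = "remstim_invalid_parameter")
  }
  if (any(amp_range_uv <= 0) || any(amp_range_uv > 500) ||
      amp_range_uv[1] > amp_range_uv[2]) {
    abort("amp_range_uv must lie in (0, 500].",
          class = "remstim_invalid_parameter")
  }
  dur_s <- hyp_duration_s(hypnogram)
  n <- round(dur_s * fs)
  with_seed(seed, {
    x <- pink_noise(n, fs, noise_rms_uv)
    rem_ep <- which(hypnogram$stages == "R")
    times <- numeric(0)
    for (ep in rem_ep) {
      k <- rpois(1, saccade_rate_per_min / 2)    # per 30-s epoch
      if (k > 0) {
        t0 <- hypnogram$record_start_s + (ep - 1) * 30
        times <- c(times, sort(t0 + runif(k, 0, 30 - width_s)))
      }
    }
    times <- sort(times)
    if (length(times) > 1) {                      # thin unresolvable overlaps
      keep <- c(TRUE, diff(times) >= 0.6)
      while (!all(keep)) {
        times <- times[keep]
        keep <- c(TRUE, diff(times) >= 0.6)
      }
    }
    times <- times[times > 0.5 & times < dur_s - width_s - 0.5]
    pulse <- saccade_pulse(width_s, fs)
    for (tt in times) {
      i0 <- round((tt - hypnogram$record_start_s) * fs) + 1
      idx <- i0:(i0 + length(pulse) - 1)
      amp <- runif(1, amp_range_uv[1], amp_range_uv[2]) *
        sample(c(-1, 1), 1)
      x[idx] <- x[idx] + amp * pulse
    }
    list(signal = psg_signal(x, fs, label = label, kind = "EOG",
                             start_s = hypnogram$record_start_s),
         em_times_s = times)
  })
}

#' Click-locked effect parameters for the EEG generator
#'
#' Ground-truth description of what each click injects into the synthetic
#' EEG: an additive evoked potential (a delayed P2 bump and a sustained
#' negativity) and multiplicative band-power modulations (a beta-band
#' increase and a theta-band decrease), with windows relative to click onset.
#' The defaults mirror the response morphology the analysis pipeline is
#' designed to detect: P2 near 275 ms, negativity from 0.5 to 1.5 s, +1 dB
#' of 15-25 Hz power from 0.2 to 1.4 s and -1 dB of 4-8 Hz power from 0.7 to
#' 1.5 s. Set amplitudes to zero for a null (background-only) record.
#'
#' @param p2_latency_s,p2_amp_uv,p2_sd_s P2 bump latency, amplitude, width.
#' @param negativity_window_s,negativity_amp_uv Sustained negativity window
#'   (s, relative to click) and amplitude (microvolts, typically negative).
#' @param beta_band_hz,beta_window_s,beta_db Beta modulation band, window,
#'   and amplitude in dB (positive = power increase).
#' @param theta_band_hz,theta_window_s,theta_db Theta modulation.
#' @param channel_gains Optional named numeric of per-channel multipliers on
#'   all effect amplitudes (dB amplitudes are scaled on the dB scale);
#'   channels not named get gain 1.
#' @return A `click_effects` object.
#' @export
click_effects <- function(p2_latency_s = 0.275, p2_amp_uv = 8,
                          p2_sd_s = 0.045,
                          negativity_window_s = c(0.5, 1.5),
                          negativity_amp_uv = -3,
                          beta_band_hz = c(15, 25),
                          beta_window_s = c(0.2, 1.4), beta_db = 1,
                          theta_band_hz = c(4, 8),
                          theta_window_s = c(0.7, 1.5), theta_db = -1,
                          channel_gains = NULL) {
  for (w in list(negativity_window_s, beta_window_s, theta_window_s)) {
    if (w[1] < 0 || w[2] > 2.5 || w[1] >= w[2]) {
      abort("Effect windows must lie within 0-2.5 s after the click.",
            class = "remstim_invalid_parameter")
    }
  }
  structure(list(p2_latency_s = p2_latency_s, p2_amp_uv = p2_amp_uv,
                 p2_sd_s = p2_sd_s,
                 negativity_window_s = negativity_window_s,
                 negativity_amp_uv = negativity_amp_uv,
                 beta_band_hz = beta_band_hz, beta_window_s = beta_window_s,
                 beta_db = beta_db,
                 theta_band_hz = theta_band_hz,
                 theta_window_s = theta_window_s, theta_db = theta_db,
                 channel_gains = channel_gains),
            class = "click_effects")
}

#' @rdname click_effects
#' @export
null_click_effects <- function() {
  click_effects(p2_amp_uv = 0, negativity_amp_uv = 0, beta_db = 0,
                theta_db = 0)
}

# smooth 0/1 window with raised-cosine ramps, sampled on a time grid
smooth_window <- function(t, w, ramp = 0.1) {
  up <- pmin(pmax((t - (w[1] - ramp)) / ramp, 0), 1)
  dn <- pmin(pmax(((w[2] + ramp) - t) / ramp, 0), 1)
  env <- pmin(up, dn)
  0.5 - 0.5 * cos(pi * env)
}

# split a signal into an exact FFT band component and its remainder
band_split <- function(x, fs, band) {
  nf <- 2^ceiling(log2(max(length(x), 2)))
  sp <- fft(c(x, rep(0, nf - length(x))))
  f <- c(0, seq_len(nf - 1)) * fs / nf
  f <- pmin(f, fs - f)
  inb <- f >= band[1] & f <= band[2]
  comp <- Re(fft(sp * inb, inverse = TRUE) / nf)[seq_along(x)]
  list(band = comp, rest = x - comp)
}

#' Generate synthetic EEG with click-locked responses
#'
#' Produces, per channel, 1/f-coloured Gaussian background (30 uV RMS by
#' default, with mildly elevated theta during REM epochs) and injects, for
#' every click, the additive evoked potential and multiplicative band-power
#' modulations described by a [click_effects()] object. Band modulations are
#' applied by exactly partitioning the background into the target band and
#' its complement with an FFT mask and scaling the band component inside the
#' effect window, so the decibel transform of the analysis recovers the
#' injected dB directly.
#'
#' @param hypnogram A [hypnogram()].
#' @param click_times_s Click onset times (s); must lie inside the record.
#' @param effects A [click_effects()] object.
#' @param channels Character vector of channel labels (defaults to the full
#'   21-site montage, see [montage_1020()]).
#' @param fs Sampling rate (Hz).
#' @param background_rms_uv Background RMS per channel.
#' @param rem_theta_gain Amplitude multiplier on the theta band during R
#'   epochs (stage-dependent background).
#' @param seed Integer seed.
#' @return A named list of [psg_signal()] objects, one per channel.
#' @export
generate_eeg_with_responses <- function(hypnogram, click_times_s,
                                        effects = click_effects(),
                                        channels = montage_1020()$label,
                                        fs = 500, background_rms_uv = 30,
                                        rem_theta_gain = 1.3,
                                        seed = NULL) {
  stopifnot(inherits(hypnogram, "hypnogram"), inherits(effects, "click_effects"))
  dur_s <- hyp_duration_s(hypnogram)
  t0 <- hypnogram$record_start_s
  if (length(click_times_s) &&
      (any(click_times_s < t0) || any(click_times_s > t0 + dur_s))) {
    abort("Click times must lie inside the record.",
          class = "remstim_invalid_parameter")
  }
  n <- round(dur_s * fs)
  t_axis <- t0 + (seq_len(n) - 1) / fs
  rem_mask <- stage_at(hypnogram, t_axis) == "R"
  rem_mask[is.na(rem_mask)] <- FALSE

  # per-click envelopes and the additive ERP template, shared across channels
  erp <- numeric(n)
  log_beta <- numeric(n)   # log amplitude gain
  log_theta <- numeric(n)
  for (tc in click_times_s) {
    rel <- t_axis - tc
    win <- rel > -0.5 & rel < 3
    r <- rel[win]
    if (effects$p2_amp_uv != 0) {
      erp[win] <- erp[win] + effects$p2_amp_uv *
        exp(-0.5 * ((r - effects$p2_latency_s) / effects$p2_sd_s)^2)
    }
    if (effects$negativity_amp_uv != 0) {
      erp[win] <- erp[win] + effects$negativity_amp_uv *
        smooth_window(r, effects$negativity_window_s)
    }
    if (effects$beta_db != 0) {
      log_beta[win] <- log_beta[win] +
        log(10^(effects$beta_db / 20)) * smooth_window(r, effects$beta_window_s)
    }
    if (effects$theta_db != 0) {
      log_theta[win] <- log_theta[win] +
        log(10^(effects$theta_db / 20)) *
        smooth_window(r, effects$theta_window_s)
    }
  }

  with_seed(seed, {
    out <- lapply(channels, function(ch) {
      g <- 1
      if (!is.null(effects$channel_gains) &&
          ch %in% names(effects$channel_gains)) {
        g <- effects$channel_gains[[ch]]
      }
      bg <- pink_noise(n, fs, background_rms_uv)
      th <- band_split(bg, fs, effects$theta_band_hz)
      be <- band_split(th$rest, fs, effects$beta_band_hz)
      theta_env <- exp(g * log_theta) *
        ifelse(rem_mask, rem_theta_gain, 1)
      x <- be$rest + th$band * theta_env + be$band * exp(g * log_beta) +
        g * erp
      psg_signal(x, fs, label = ch, kind = "EEG", start_s = t0)
    })
    names(out) <- channels
    out
  })
}

#' Standard 21-site 10-20 montage with unit-sphere positions
#'
#' Electrode labels and idealized spherical positions (radius 1) for the
#' 21-channel scalp montage used throughout: Fpz, Fp1, Fp2, Fz, F3, F4, F7,
#' F8, Cz, C3, C4, Pz, P3, P4, P7, P8, Oz, O1, O2, T7, T8. Positions follow
#' the idealized 10-20 angular layout (vertex at the pole) and are intended
#' for spherical-spline interpolation, not anatomical accuracy.
#'
#' @return A tibble with columns `label`, `x`, `y`, `z`.
#' @export
montage_1020 <- function() {
  # (inclination from vertex, azimuth from nasion, degrees)
  ang <- tibble::tribble(
    ~label, ~incl, ~az,
    "Fpz", 90,   0,   "Fp1", 90, -18,  "Fp2", 90,  18,
    "Fz",  45,   0,   "F3",  49, -29,  "F4",  49,  29,
    "F7",  90, -54,   "F8",  90,  54,
    "Cz",   0,   0,   "C3",  45, -90,  "C4",  45,  90,
    "Pz",  45, 180,   "P3",  49, -151, "P4",  49,  151,
    "P7",  90, -126,  "P8",  90,  126,
    "Oz",  90, 180,   "O1",  90, -162, "O2",  90,  162,
    "T7",  90, -90,   "T8",  90,  90
  )
  th <- ang$incl * pi / 180
  ph <- ang$az * pi / 180
  tibble(label = ang$label,
         x = sin(th) * sin(ph),
         y = sin(th) * cos(ph),
         z = cos(th))
}

#' Generate a synthetic chin EMG channel
#'
#' Broadband muscle-tone noise whose amplitude drops to atonia during REM
#' epochs, with intermediate tone in NREM and full tone in wake.
#'
#' @param hypnogram A [hypnogram()].
#' @param fs Sampling rate (Hz).
#' @param wake_rms_uv,nrem_rms_uv,atonia_rms_uv Stage-dependent RMS levels.
#' @param seed Integer seed.
#' @return A [psg_signal()] of kind EMG.
#' @export
generate_emg <- function(hypnogram, fs = 500, wake_rms_uv = 20,
                         nrem_rms_uv = 8, atonia_rms_uv = 2, seed = NULL) {
  stopifnot(inherits(hypnogram, "hypnogram"))
  n <- round(hyp_duration_s(hypnogram) * fs)
  t_axis <- hypnogram$record_start_s + (seq_len(n) - 1) / fs
  st <- stage_at(hypnogram, t_axis)
  rms <- ifelse(st == "R", atonia_rms_uv,
                ifelse(st == "W", wake_rms_uv, nrem_rms_uv))
  rms[is.na(rms)] <- nrem_rms_uv
  with_seed(seed, {
    psg_signal(rnorm(n) * rms, fs, label = "EMG", kind = "EMG",
               start_s = hypnogram$record_start_s)
  })
}

#' Simulate a complete stimulation night
#'
#' Convenience wrapper chaining the generators and the closed-loop
#' simulator: hypnogram, ground-truth EOG saccades, operator gating, the
#' streaming detector (whose clicks then drive the EEG response injection),
#' EEG channels, and a chin EMG. Clicks are injected into the EEG only in
#' the unmuted (STM) condition; the muted control logs identical events but
#' the EEG receives no click-locked effects.
#'
#' @param duration_min Night length in minutes.
#' @param config A [stimulator_config()].
#' @param effects A [click_effects()].
#' @param channels EEG channel labels.
#' @param fs Sampling rate for all signals.
#' @param seed Integer seed driving every random component.
#' @param ... Passed to [generate_hypnogram()].
#' @return A list: `hypnogram`, `signals` (named list, EEG + EOG-L + EMG),
#'   `events`, `em_times_s`, `gates`, `config`, `effects`, `seed`.
#' @export
synthetic_night <- function(duration_min = 30,
                            config = stimulator_config(threshold_uv = 50),
                            effects = click_effects(),
                            channels = c("Fz", "Cz", "Pz", "C3", "C4", "Oz"),
                            fs = 250, seed = 1, ...) {
  h <- generate_hypnogram(duration_min, seed = seed, ...)
  eog <- generate_rem_eog(h, fs = fs, seed = seed + 1)
  gates <- gate_stimulation(h)
  d <- design_cheby2_bandpass(filter_spec("online_eog"), fs)
  eog_f <- apply_filter(d, eog$signal, mode = "causal")
  cfg <- config
  cfg$fs <- fs
  ev <- run_em_detector(eog_f, cfg, gates, h)
  clicks <- ev$t_s[ev$type == "click"]
  eff <- if (cfg$muted) null_click_effects() else effects
  eeg <- generate_eeg_with_responses(h, clicks, eff, channels = channels,
                                     fs = fs, seed = seed + 2)
  emg <- generate_emg(h, fs = fs, seed = seed + 3)
  signals <- c(eeg, list(`EOG-L` = eog$signal, EMG = emg))
  list(hypnogram = h, signals = signals, events = ev,
       em_times_s = eog$em_times_s, gates = gates, config = cfg,
       effects = eff, seed = seed)
}
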