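#' Epoch click-locked trials with exclusion rules
#'
#' Cuts one candidate trial per click from continuous (offline-filtered)
#' signals, spanning 2 s before to 3 s after the click, and applies the
#' exclusion rules: clicks in any stage other than R are dropped
#' (`non_rem`), trials overlapping or closer than `artifact_margin_s` to an
#' annotated arousal or artifact are dropped (`near_artifact`), and clicks
#' too close to the record edge are dropped (`edge`). Exclusion bookkeeping
#' is retained on the result.
#'
#' @param signals Named list of [psg_signal()]s sharing one sampling rate.
#' @param click_events Event tibble from [run_em_detector()] (its `click`
#'   rows) or a numeric vector of click times.
#' @param hypnogram A [hypnogram()].
#' @param window_s Trial window relative to click, seconds.
#' @param artifact_margin_s Minimum distance from trial to any annotation.
#' @return A `trial_set`: list with `data` (trials x channels x time array),
#'   `time_s`, `channels`, `fs`, `click_times_s`, and `excluded` (tibble of
#'   dropped candidates with their single primary reason).
#' @export
epoch_trials <- function(signals, click_events, hypnogram,
                         window_s = c(-2, 3), artifact_margin_s = 2) {
  stopifnot(inherits(hypnogram, "hypnogram"))
  if (inherits(signals, "psg_signal")) signals <- list(signals)
  fs <- signals[[1]]$fs
  stopifnot(all(vapply(signals, function(s) abs(s$fs - fs) < 1e-9, logical(1))))
  clicks <- if (is.numeric(click_events)) {
    click_events
  } else {
    click_events$t_s[click_events$type == "click"]
  }
  labels <- vapply(seq_along(signals), function(i) {
    if (!is.null(names(signals)) && nzchar(names(signals)[i])) {
      names(signals)[i]
    } else {
      signals[[i]]$label
    }
  }, character(1))
  start_s <- signals[[1]]$start_s
  n_samp <- length(signals[[1]]$samples)
  rel_idx <- round(window_s[1] * fs):round(window_s[2] * fs)
  time_s <- rel_idx / fs
  ann <- dplyr::bind_rows(hypnogram$arousals, hypnogram$artifacts)
  reasons <- character(length(clicks))
  for (k in seq_along(clicks)) {
    tc <- clicks[k]
    st <- stage_at(hypnogram, tc)
    w0 <- tc + window_s[1]
    w1 <- tc + window_s[2]
    i0 <- round((w0 - start_s) * fs) + 1
    if (i0 < 1 || i0 + length(rel_idx) - 1 > n_samp) {
      reasons[k] <- "edge"
    } else if (is.na(st) || st != "R") {
      reasons[k] <- "non_rem"
    } else if (nrow(ann) > 0 &&
               any(ann$onset_s < w1 + artifact_margin_s &
                   ann$onset_s + ann$duration_s > w0 - artifact_margin_s)) {
      reasons[k] <- "near_artifact"
    }
  }
  keep <- which(reasons == "")
  data <- array(NA_real_, dim = c(length(keep), length(labels),
                                  length(rel_idx)))
  for (j in seq_along(keep)) {
    tc <- clicks[keep[j]]
    i0 <- round((tc + window_s[1] - start_s) * fs) + 1
    for (c in seq_along(signals)) {
      data[j, c, ] <- signals[[c]]$samples[i0:(i0 + length(rel_idx) - 1)]
    }
  }
  structure(list(data = data, time_s = time_s, channels = labels, fs = fs,
                 click_times_s = clicks[keep],
                 excluded = tibble(click_t_s = clicks[reasons != ""],
                                   reason = reasons[reasons != ""])),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set: %d trials x %d channels x %d samples @ %g Hz; %d excluded>\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
              nrow(x$excluded)))
  invisible(x)
}

# Legendre polynomial values P_1..P_L at x (vector), as length(x) x L matrix
legendre_upto <- function(x, L) {
  out <- matrix(0, length(x), L)
  pm1 <- rep(1, length(x))
  p <- x
  out[, 1] <- p
  for (l in 1:(L - 1)) {
    pn <- ((2 * l + 1) * x * p - l * pm1) / (l + 1)
    pm1 <- p
    p <- pn
    out[, l + 1] <- p
  }
  out
}

# spherical-spline kernel g(cos angle), order m, L Legendre terms
spline_g <- function(cosang, m = 4, L = 50) {
  P <- legendre_upto(pmin(pmax(cosang, -1), 1), L)
  l <- seq_len(L)
  w <- (2 * l + 1) / (l * (l + 1))^m
  as.numeric(P %*% w) / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces bad channels in a single trial (channels x time matrix) with
#' spherical-spline estimates (spline order 4, 50 Legendre terms, ridge
#' regularization 1e-5) computed from the good channels. If the bad
#' channels account for 25% or more of the electrodes the trial is rejected
#' instead and `NULL` is returned.
#'
#' @param trial Numeric matrix, channels x time; rownames or `channels` give
#'   the labels.
#' @param bad_channels Character vector of bad channel labels.
#' @param montage Tibble with `label`, `x`, `y`, `z` unit-sphere positions
#'   (defaults to [montage_1020()]).
#' @param channels Channel labels for the rows of `trial` (defaults to
#'   `rownames(trial)`).
#' @param m,n_legendre,lambda Spline order, Legendre truncation,
#'   regularization.
#' @return The trial matrix with bad rows replaced, or `NULL` when the bad
#'   fraction is >= 25%.
#' @export
interpolate_channels <- function(trial, bad_channels,
                                 montage = montage_1020(),
                                 channels = rownames(trial),
                                 m = 4, n_legendre = 50, lambda = 1e-5) {
  stopifnot(is.matrix(trial))
  if (is.null(channels)) {
    abort("Channel labels are required (rownames or `channels`).",
          class = "remstim_invalid_parameter")
  }
  unknown <- setdiff(c(channels, bad_channels), montage$label)
  if (length(unknown) > 0) {
    abort(paste0("Unknown channel label(s): ", paste(unknown, collapse = ", ")),
          class = "remstim_invalid_parameter")
  }
  bad_channels <- intersect(bad_channels, channels)
  if (length(bad_channels) == 0) return(trial)
  if (length(bad_channels) / length(channels) >= 0.25) return(NULL)
  pos <- as.matrix(montage[match(channels, montage$label), c("x", "y", "z")])
  good <- !(channels %in% bad_channels)
  G <- spline_g(tcrossprod(pos[good, , drop = FALSE]), m, n_legendre)
  G <- matrix(G, sum(good), sum(good)) + diag(lambda, sum(good))
  ng <- sum(good)
  A <- rbind(cbind(G, rep(1, ng)), c(rep(1, ng), 0))
  rhs <- rbind(trial[good, , drop = FALSE], 0)
  sol <- solve(A, rhs)
  Gb <- matrix(spline_g(pos[!good, , drop = FALSE] %*% t(pos[good, , drop = FALSE]),
                        m, n_legendre),
               sum(!good), ng)
  est <- Gb %*% sol[seq_len(ng), , drop = FALSE] +
    matrix(sol[ng + 1, ], sum(!good), ncol(trial), byrow = TRUE)
  trial[!good, ] <- est
  trial
}

#' Event-related potential
#'
#' Pointwise mean across trials per channel and time, with a 95% t-interval.
#' When per-trial subject identifiers are supplied the interval is computed
#' on per-subject means (the group-level ERP), otherwise on trials.
#'
#' @param trialset A `trial_set` from [epoch_trials()].
#' @param subject_id Optional vector of subject ids, one per trial.
#' @param average_channels If `TRUE`, average across channels first and
#'   return a single `all` channel.
#' @return A tibble: `channel`, `time_s`, `mean_uv`, `ci_lo`, `ci_hi`, of
#'   class `remstim_erp`.
#' @export
compute_erp <- function(trialset, subject_id = NULL,
                        average_channels = FALSE) {
  stopifnot(inherits(trialset, "trial_set"))
  nt <- dim(trialset$data)[1]
  if (nt < 2) {
    abort("At least two retained trials are required.",
          class = "remstim_invalid_parameter")
  }
  dat <- trialset$data
  chans <- trialset$channels
  if (average_channels) {
    dat <- array(apply(dat, c(1, 3), mean), dim = c(nt, 1, dim(dat)[3]))
    chans <- "all"
  }
  units <- if (!is.null(subject_id)) {
    ids <- unique(subject_id)
    arr <- array(NA_real_, dim = c(length(ids), dim(dat)[2], dim(dat)[3]))
    for (i in seq_along(ids)) {
      sel <- which(subject_id == ids[i])
      arr[i, , ] <- apply(dat[sel, , , drop = FALSE], c(2, 3), mean)
    }
    arr
  } else {
    dat
  }
  n <- dim(units)[1]
  mu <- apply(units, c(2, 3), mean)
  se <- apply(units, c(2, 3), sd) / sqrt(n)
  tq <- if (n > 1) qt(0.975, n - 1) else 0
  out <- purrr::map_dfr(seq_along(chans), function(c) {
    tibble(channel = chans[c], time_s = trialset$time_s,
           mean_uv = mu[c, ], ci_lo = mu[c, ] - tq * se[c, ],
           ci_hi = mu[c, ] + tq * se[c, ])
  })
  class(out) <- c("remstim_erp", class(out))
  out
}

# frequency-domain unit-gain analytic Morlet bank: nfreq x nfft matrix
morlet_bank <- function(freqs, n_cycles, fs, nfft) {
  fgrid <- (0:(nfft - 1)) * fs / nfft
  W <- matrix(0, length(freqs), nfft)
  for (i in seq_along(freqs)) {
    s <- n_cycles / (2 * pi * freqs[i])
    W[i, ] <- exp(-0.5 * s^2 * (2 * pi * (fgrid - freqs[i]))^2)
  }
  # suppress the mirrored negative-frequency half (analytic signal)
  W[, fgrid > fs / 2] <- 0
  W
}

#' Morlet-wavelet event-related spectral perturbation
#'
#' Computes per-trial time-frequency power with a complex Morlet wavelet of
#' `n_cycles` cycles on a 0.25-30 Hz grid, trims the trial to -1 to +2.5 s
#' around the click to discard wavelet edge effects, and applies a
#' single-trial baseline: linear power is divided by its mean over the
#' baseline window (-1 to 0 s) per trial, channel, and frequency, then
#' converted to decibels (10 log10 power/baseline). By construction the dB
#' of the mean baseline power is exactly 0 and the dB map is invariant to
#' scaling the raw trace. Single-sample log power carries a constant
#' negative bias relative to mean power, shared by the baseline and
#' post-stimulus portions of the map alike; stimulus-locked modulation is
#' therefore read as the change relative to the same map's baseline rows
#' (see [ersp_band_change()]), which is unbiased under stationarity. Frequencies whose 6-cycle wavelet outlasts the
#' pre-click buffer (below about 1.2 Hz) are computed but flagged as
#' unreliable.
#'
#' @param trialset A `trial_set` from [epoch_trials()].
#' @param freqs Frequency grid in Hz (must stay below Nyquist).
#' @param n_cycles Morlet cycles.
#' @param keep_s Retained time window relative to the click.
#' @param baseline_s Baseline window.
#' @param t_step_s Output time resolution (the power envelope is smooth, so
#'   the map is stored on a decimated time grid).
#' @param keep_trials If `TRUE` return the trials x channels x freqs x times
#'   array; otherwise (default) the trial-averaged channels x freqs x times
#'   dB map.
#' @return A `remstim_ersp` object: list with `values`, `freqs`, `times`,
#'   `channels`, `baseline_window`, `unreliable_freqs`.
#' @export
compute_ersp <- function(trialset, freqs = seq(0.25, 30, by = 0.25),
                         n_cycles = 6, keep_s = c(-1, 2.5),
                         baseline_s = c(-1, 0), t_step_s = 0.02,
                         keep_trials = FALSE) {
  stopifnot(inherits(trialset, "trial_set"))
  fs <- trialset$fs
  if (max(freqs) >= fs / 2) {
    abort("Frequency grid exceeds the Nyquist frequency.",
          class = "remstim_invalid_parameter")
  }
  nt <- dim(trialset$data)[1]
  nc <- dim(trialset$data)[2]
  ns <- dim(trialset$data)[3]
  nfft <- 2^ceiling(log2(2 * ns))
  W <- morlet_bank(freqs, n_cycles, fs, nfft)
  step <- max(1L, round(t_step_s * fs))
  keep_idx <- which(trialset$time_s >= keep_s[1] - 1e-9 &
                      trialset$time_s <= keep_s[2] + 1e-9)
  keep_idx <- keep_idx[seq(1, length(keep_idx), by = step)]
  times <- trialset$time_s[keep_idx]
  bl <- times >= baseline_s[1] - 1e-9 & times < baseline_s[2] - 1e-9
  if (!any(bl)) {
    abort("Baseline window contains no samples.",
          class = "remstim_invalid_parameter")
  }
  out <- if (keep_trials) {
    array(NA_real_, dim = c(nt, nc, length(freqs), length(times)))
  } else {
    array(0, dim = c(nc, length(freqs), length(times)))
  }
  tw <- t(W)                      # nfft x nfreq
  for (tr in seq_len(nt)) {
    for (ch in seq_len(nc)) {
      sp <- fft(c(trialset$data[tr, ch, ], rep(0, nfft - ns)))
      coef <- stats::mvfft(tw * sp, inverse = TRUE)[keep_idx, , drop = FALSE]
      pow <- (Mod(coef) / nfft)^2                     # times x freqs
      base <- colMeans(pow[bl, , drop = FALSE])
      db <- 10 * log10(sweep(pow, 2, base, "/"))
      if (keep_trials) {
        out[tr, ch, , ] <- t(db)
      } else {
        out[ch, , ] <- out[ch, , ] + t(db) / nt
      }
    }
  }
  structure(list(values = out, freqs = freqs, times = times,
                 channels = trialset$channels, baseline_window = baseline_s,
                 keep_trials = keep_trials,
                 # below ~1.2 Hz a 6-cycle wavelet outlasts the 1 s edge
                 # buffer left by the trim, so those rows leak edge effects
                 unreliable_freqs = freqs[freqs < 1.2 * n_cycles / 6]),
            class = "remstim_ersp")
}

#' @export
print.remstim_ersp <- function(x, ...) {
  cat(sprintf("<remstim_ersp: %s; %d freqs (%.2g-%.4g Hz) x %d times (%.3g to %.3g s)>\n",
              if (x$keep_trials) "per-trial" else "trial-averaged",
              length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
#' @method as_tibble remstim_ersp
as_tibble.remstim_ersp <- function(x, ...) {
  if (x$keep_trials) {
    abort("Convert a trial-averaged map (keep_trials = FALSE) to a tibble.",
          class = "remstim_invalid_parameter")
  }
  purrr::map_dfr(seq_along(x$channels), function(c) {
    tidyr::expand_grid(channel = x$channels[c], freq_hz = x$freqs,
                       time_s = x$times) |>
      dplyr::mutate(db = as.vector(t(x$values[c, , ])))
  })
}

#' Band-limited post-stimulus power change of an ERSP map
#'
#' Mean dB inside a frequency band and post-stimulus time window minus the
#' mean dB of the same band over the baseline window, i.e. the
#' stimulus-locked modulation the map encodes. Using the in-map baseline as
#' the reference cancels the constant log-power bias of single-trial dB
#' values.
#'
#' @param ersp A trial-averaged `remstim_ersp` (or per-trial; trials are
#'   averaged first).
#' @param band_hz Length-2 frequency band.
#' @param window_s Length-2 post-stimulus window.
#' @param channel Channel label or index (default: average all channels).
#' @return Scalar dB change.
#' @export
ersp_band_change <- function(ersp, band_hz, window_s, channel = NULL) {
  stopifnot(inherits(ersp, "remstim_ersp"))
  v <- ersp$values
  if (ersp$keep_trials) v <- apply(v, c(2, 3, 4), mean)
  if (!is.null(channel)) {
    c_idx <- if (is.character(channel)) match(channel, ersp$channels) else channel
    v <- v[c_idx, , , drop = FALSE]
  }
  m <- apply(v, c(2, 3), mean)              # freqs x times
  fi <- ersp$freqs >= band_hz[1] & ersp$freqs <= band_hz[2]
  wi <- ersp$times >= window_s[1] & ersp$times <= window_s[2]
  bi <- ersp$times >= ersp$baseline_window[1] &
    ersp$times < ersp$baseline_window[2]
  mean(m[fi, wi]) - mean(m[fi, bi])
}
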