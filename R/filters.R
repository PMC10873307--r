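#' Named band-pass filter specifications
#'
#' The four Chebyshev type II band-pass specifications used throughout the
#' stimulation and analysis pipeline, addressable by name:
#'
#' * `online_eog`: 3 dB edges 0.3 and 5 Hz; >= 50 dB below 0.1 Hz and above
#'   15 Hz. Used causally by the online eye-movement detector.
#' * `offline_eeg`: 3 dB edges 0.16 and 35.8 Hz; >= 100 dB below 0.05 Hz and
#'   above 45 Hz. Zero-phase, applied to EEG before epoching.
#' * `offline_eog`: 3 dB edges 0.36 and 8.2 Hz; >= 100 dB below 0.26 Hz and
#'   above 10 Hz. Zero-phase, for offline EOG checks.
#' * `offline_emg`: 3 dB edges 9.56 and 100.35 Hz; >= 100 dB below 8.97 Hz
#'   and above 105 Hz. Zero-phase, for chin EMG.
#'
#' Specifications are single-pass design targets; zero-phase (forward plus
#' backward) application doubles the attenuation in dB.
#'
#' @param name One of `"online_eog"`, `"offline_eeg"`, `"offline_eog"`,
#'   `"offline_emg"`; or omit to list all four.
#' @param mode `"causal"` or `"zero_phase"` application mode recorded on the
#'   spec (the online EOG spec defaults to causal, the rest to zero-phase).
#' @return `filter_spec()` returns a `filter_spec` object (a list with
#'   `passband_3db_hz`, `stopband_hz`, `stopband_atten_db`, `mode`, `name`).
#'   `filter_specs()` returns a tibble with one row per named spec.
#' @examples
#' filter_specs()
#' filter_spec("online_eog")
#' @export
filter_spec <- function(name = c("online_eog", "offline_eeg", "offline_eog",
                                 "offline_emg"),
                        mode = NULL) {
  name <- match.arg(name)
  reg <- .filter_registry()
  s <- reg[[name]]
  if (!is.null(mode)) {
    s$mode <- match.arg(mode, c("causal", "zero_phase"))
  }
  s
}

.filter_registry <- function() {
  mk <- function(name, pass, stop, atten, mode) {
    structure(list(name = name, passband_3db_hz = pass, stopband_hz = stop,
                   stopband_atten_db = atten, passband_ripple_db = 3,
                   mode = mode),
              class = "filter_spec")
  }
  list(
    online_eog  = mk("online_eog",  c(0.30, 5.00),   c(0.10, 15.0), 50,  "causal"),
    offline_eeg = mk("offline_eeg", c(0.16, 35.80),  c(0.05, 45.0), 100, "zero_phase"),
    offline_eog = mk("offline_eog", c(0.36, 8.20),   c(0.26, 10.0), 100, "zero_phase"),
    offline_emg = mk("offline_emg", c(9.56, 100.35), c(8.97, 105.0), 100, "zero_phase")
  )
}

#' @rdname filter_spec
#' @export
filter_specs <- function() {
  purrr::map_dfr(.filter_registry(), function(s) {
    tibble(name = s$name,
           pass_lo_hz = s$passband_3db_hz[1], pass_hi_hz = s$passband_3db_hz[2],
           stop_lo_hz = s$stopband_hz[1], stop_hi_hz = s$stopband_hz[2],
           stop_atten_db = s$stopband_atten_db, mode = s$mode)
  })
}

#' Custom band-pass filter specification
#'
#' @param passband_3db_hz Length-2 numeric, 3 dB passband edges (Hz).
#' @param stopband_hz Length-2 numeric, stopband edges (Hz); must bracket the
#'   passband.
#' @param stopband_atten_db Minimum stopband attenuation (dB, single pass).
#' @param mode `"causal"` or `"zero_phase"`.
#' @param name Optional label.
#' @return A `filter_spec` object.
#' @export
new_filter_spec <- function(passband_3db_hz, stopband_hz, stopband_atten_db,
                            mode = c("zero_phase", "causal"),
                            name = "custom") {
  mode <- match.arg(mode)
  if (length(passband_3db_hz) != 2L || length(stopband_hz) != 2L ||
      !all(is.finite(c(passband_3db_hz, stopband_hz)))) {
    abort("Band edges must be length-2 finite numerics.",
          class = "remstim_invalid_parameter")
  }
  if (!(stopband_hz[1] < passband_3db_hz[1] &&
        passband_3db_hz[1] < passband_3db_hz[2] &&
        passband_3db_hz[2] < stopband_hz[2])) {
    abort("Edges must satisfy stop_lo < pass_lo < pass_hi < stop_hi.",
          class = "remstim_invalid_parameter")
  }
  check_scalar(stopband_atten_db, "stopband_atten_db")
  structure(list(name = name, passband_3db_hz = as.numeric(passband_3db_hz),
                 stopband_hz = as.numeric(stopband_hz),
                 stopband_atten_db = stopband_atten_db,
                 passband_ripple_db = 3, mode = mode),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec '%s' (%s)>\n", x$name, x$mode))
  cat(sprintf("  passband (3 dB): %.3g-%.4g Hz\n",
              x$passband_3db_hz[1], x$passband_3db_hz[2]))
  cat(sprintf("  stopband (>=%g dB): <%.3g Hz, >%.4g Hz\n",
              x$stopband_atten_db, x$stopband_hz[1], x$stopband_hz[2]))
  invisible(x)
}

# ---- analog prototype and transforms (zero-pole-gain form) ------------------

# Chebyshev type II analog lowpass prototype: unit stopband edge frequency,
# attenuation rs dB at and beyond it.
cheb2_prototype <- function(n, rs) {
  de <- 1 / sqrt(10^(0.1 * rs) - 1)
  mu <- asinh(1 / de) / n
  m <- seq(-n + 1, n - 1, by = 2)
  z <- -Conj(1i / sin(m * pi / (2 * n)))
  z <- z[is.finite(z)]                       # odd order drops the zero at Inf
  p <- -exp(1i * pi * m / (2 * n))
  p <- complex(real = sinh(mu) * Re(p), imaginary = cosh(mu) * Im(p))
  p <- 1 / p
  k <- Re(prod(-p) / prod(-z))
  list(z = z, p = p, k = k)
}

# lowpass (cutoff 1) -> bandpass centred at wo with bandwidth bw, analog
lp_to_bp_zpk <- function(zpk, wo, bw) {
  z <- zpk$z; p <- zpk$p
  degree <- length(p) - length(z)
  zl <- z * bw / 2
  pl <- p * bw / 2
  zb <- c(zl + sqrt(as.complex(zl^2 - wo^2)), zl - sqrt(as.complex(zl^2 - wo^2)))
  pb <- c(pl + sqrt(as.complex(pl^2 - wo^2)), pl - sqrt(as.complex(pl^2 - wo^2)))
  zb <- c(zb, rep(0 + 0i, degree))
  list(z = zb, p = pb, k = zpk$k * bw^degree)
}

# bilinear transform, analog -> digital at sampling rate fs
bilinear_zpk <- function(zpk, fs) {
  fs2 <- 2 * fs
  z <- zpk$z; p <- zpk$p
  degree <- length(p) - length(z)
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  kd <- Re(zpk$k * prod(fs2 - z) / prod(fs2 - p))
  list(z = c(zd, rep(-1 + 0i, degree)), p = pd, k = kd)
}

# pair digital zeros/poles into second-order sections. Poles closest to the
# unit circle come first and are matched with the nearest zero pair, the
# standard ordering that keeps cascaded biquads well conditioned.
zpk_to_sos <- function(zpk) {
  pair_up <- function(v) {
    v <- v[order(Im(v))]          # conjugates adjacent after sorting by |Im|
    cplx <- v[abs(Im(v)) > 1e-10]
    re <- Re(v[abs(Im(v)) <= 1e-10])
    cp <- cplx[Im(cplx) > 0]
    pairs <- lapply(cp, function(x) c(x, Conj(x)))
    re <- sort(re)
    while (length(re) >= 2) {
      pairs <- c(pairs, list(as.complex(re[1:2])))
      re <- re[-(1:2)]
    }
    if (length(re) == 1) pairs <- c(pairs, list(as.complex(re[1])))
    pairs
  }
  zp <- pair_up(zpk$z)
  pp <- pair_up(zpk$p)
  # pad zero pairs so every pole section has a zero section
  while (length(zp) < length(pp)) zp <- c(zp, list(complex(0)))
  ord <- order(-vapply(pp, function(p) max(abs(p)), numeric(1)))
  pp <- pp[ord]
  used <- logical(length(zp))
  sos <- matrix(0, nrow = length(pp), ncol = 6)
  for (i in seq_along(pp)) {
    pc <- mean(pp[[i]])
    d <- vapply(seq_along(zp), function(j) {
      if (used[j]) return(Inf)
      if (length(zp[[j]]) == 0) return(1e9)  # empty sections matched last
      min(abs(zp[[j]] - pc))
    }, numeric(1))
    j <- which.min(d)
    used[j] <- TRUE
    b <- Re(poly_from_roots(zp[[j]]))
    a <- Re(poly_from_roots(pp[[i]]))
    sos[i, ] <- c(c(b, rep(0, 3 - length(b))), c(a, rep(0, 3 - length(a))))
  }
  # distribute the overall gain evenly across sections
  g <- abs(zpk$k)^(1 / nrow(sos)) * ifelse(zpk$k < 0, 1, 1)
  sos[, 1:3] <- sos[, 1:3] * g
  if (zpk$k < 0) sos[1, 1:3] <- -sos[1, 1:3]
  sos
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Design a Chebyshev type II band-pass filter
#'
#' Designs the minimum-order Chebyshev type II digital band-pass filter
#' meeting a [filter_spec()]: at most 3 dB attenuation inside the passband
#' edges and at least the specified attenuation at and beyond the stopband
#' edges, evaluated single-pass. The filter is designed in zero-pole-gain
#' form (analog prototype, lowpass-to-bandpass transform, bilinear transform)
#' and realized as second-order sections; transfer-function polynomial form
#' is numerically unusable at sub-hertz edges and 500 Hz sampling.
#'
#' @param spec A `filter_spec` (see [filter_spec()]) or a spec name.
#' @param fs Sampling rate in Hz; the upper stopband edge must lie below the
#'   Nyquist frequency.
#' @return A `filter_design` object: list with `spec`, `fs`, `order` (the
#'   prototype order; the band-pass has twice as many poles), `sos`
#'   (second-order sections, columns b0 b1 b2 a0 a1 a2) and `zpk`.
#' @examples
#' d <- design_cheby2_bandpass("online_eog", fs = 500)
#' magnitude_response(d, c(0.1, 0.3, 1.2, 5, 15))
#' @export
design_cheby2_bandpass <- function(spec, fs) {
  if (is.character(spec)) spec <- filter_spec(spec)
  stopifnot(inherits(spec, "filter_spec"))
  check_scalar(fs, "fs")
  if (spec$stopband_hz[2] >= fs / 2) {
    abort("Upper stopband edge must be below Nyquist for this sampling rate.",
          class = "remstim_design_error")
  }
  rp <- spec$passband_ripple_db
  rs <- spec$stopband_atten_db
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  wp <- warp(spec$passband_3db_hz)
  ws <- warp(spec$stopband_hz)
  bw <- wp[2] - wp[1]
  wo <- sqrt(wp[1] * wp[2])
  sel <- min(abs((ws^2 - wo^2) / (bw * ws)))   # binding stopband selectivity
  if (sel <= 1) {
    abort("Infeasible specification: stopband edges inside the passband.",
          class = "remstim_design_error")
  }
  n <- ceiling(acosh(sqrt((10^(0.1 * rs) - 1) / (10^(0.1 * rp) - 1))) /
                 acosh(sel))
  # scale the prototype so the attenuation reaches rs just inside the binding
  # printed stopband edge; the 0.999 margin keeps both specs strictly met in
  # floating point
  proto <- cheb2_prototype(n, rs)
  scale <- sel * 0.999
  proto <- list(z = proto$z * scale, p = proto$p * scale,
                k = proto$k * scale^(length(proto$p) - length(proto$z)))
  dig <- bilinear_zpk(lp_to_bp_zpk(proto, wo, bw), fs)
  if (max(abs(dig$p)) >= 1) {
    abort("Design produced an unstable filter.", class = "remstim_design_error")
  }
  structure(list(spec = spec, fs = fs, order = n, zpk = dig,
                 sos = zpk_to_sos(dig)),
            class = "filter_design")
}

#' @export
print.filter_design <- function(x, ...) {
  cat(sprintf("<filter_design '%s', prototype order %d (%d poles), fs %g Hz>\n",
              x$spec$name, x$order, length(x$zpk$p), x$fs))
  invisible(x)
}

#' Single-pass magnitude response of a filter design
#'
#' Evaluates the transfer function exactly from its zero-pole-gain form and
#' returns attenuation in dB (positive values mean the frequency is
#' attenuated).
#'
#' @param design A `filter_design`.
#' @param freqs_hz Frequencies in Hz, each below Nyquist.
#' @return A tibble with columns `freq_hz` and `attenuation_db`.
#' @export
magnitude_response <- function(design, freqs_hz) {
  stopifnot(inherits(design, "filter_design"))
  if (any(freqs_hz >= design$fs / 2) || any(freqs_hz < 0)) {
    abort("Frequencies must lie in [0, fs/2).",
          class = "remstim_invalid_parameter")
  }
  w <- exp(1i * 2 * pi * freqs_hz / design$fs)
  zz <- design$zpk$z
  pp <- design$zpk$p
  mag <- vapply(w, function(wi) {
    abs(design$zpk$k) * exp(sum(log(abs(wi - zz))) - sum(log(abs(wi - pp))))
  }, numeric(1))
  tibble(freq_hz = as.numeric(freqs_hz), attenuation_db = -20 * log10(mag))
}

# steady-state initial conditions for one biquad (direct form II transposed),
# so that a constant input x produces a constant output from the first sample
biquad_zi <- function(b, a) {
  # solve (I - A') zi = B where A is the companion form of a, per section
  A <- rbind(c(-a[2], 1), c(-a[3], 0))
  B <- c(b[2] - a[2] * b[1], b[3] - a[3] * b[1])
  solve(diag(2) - A, B)
}

#' Apply a designed filter to a signal
#'
#' Causal mode runs the second-order-section cascade forward only; zero-phase
#' mode runs it forward and backward (doubling the attenuation in dB and
#' cancelling the phase), with odd-reflection edge padding and steady-state
#' initial conditions to suppress startup transients.
#'
#' @param design A `filter_design`.
#' @param signal A [psg_signal()] or a bare numeric vector (then `fs` is taken
#'   from the design).
#' @param mode Override the spec's mode: `"causal"` or `"zero_phase"`.
#' @return Filtered signal of the same type as the input.
#' @export
apply_filter <- function(design, signal, mode = NULL) {
  stopifnot(inherits(design, "filter_design"))
  is_rec <- inherits(signal, "psg_signal")
  x <- if (is_rec) signal$samples else as.numeric(signal)
  if (is_rec && abs(signal$fs - design$fs) > 1e-9) {
    abort("Signal sampling rate does not match the filter design.",
          class = "remstim_invalid_parameter")
  }
  mode <- mode %||% design$spec$mode
  mode <- match.arg(mode, c("causal", "zero_phase"))
  y <- if (mode == "causal") {
    sosfilt_cpp(design$sos, x, matrix(0, nrow(design$sos), 2))
  } else {
    sos_filtfilt(design$sos, x)
  }
  if (is_rec) {
    signal$samples <- y
    signal
  } else {
    y
  }
}

sos_filtfilt <- function(sos, x) {
  n <- length(x)
  npad <- min(max(3L * 2L * nrow(sos), 100L), n - 1L)
  xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  run <- function(v) {
    zi <- t(vapply(seq_len(nrow(sos)), function(i) {
      b <- sos[i, 1:3]; a <- sos[i, 4:6]
      biquad_zi(b, a)
    }, numeric(2)))
    # scale each section's steady state by the DC gain accumulated upstream
    lev <- v[1]
    for (i in seq_len(nrow(sos))) {
      zi[i, ] <- zi[i, ] * lev
      lev <- lev * sum(sos[i, 1:3]) / sum(sos[i, 4:6])
    }
    sosfilt_cpp(sos, v, zi)
  }
  y <- run(xp)
  y <- rev(run(rev(y)))
  y[(npad + 1):(npad + n)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
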