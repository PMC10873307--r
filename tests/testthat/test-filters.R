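test_that("the four named specs carry the printed edge and attenuation figures", {
  reg <- filter_specs()
  expect_equal(nrow(reg), 4)
  s <- filter_spec("online_eog")
  expect_equal(s$passband_3db_hz, c(0.3, 5))
  expect_equal(s$stopband_hz, c(0.1, 15))
  expect_equal(s$stopband_atten_db, 50)
  s <- filter_spec("offline_eeg")
  expect_equal(s$passband_3db_hz, c(0.16, 35.8))
  expect_equal(s$stopband_hz, c(0.05, 45))
  expect_equal(s$stopband_atten_db, 100)
  s <- filter_spec("offline_eog")
  expect_equal(s$passband_3db_hz, c(0.36, 8.2))
  expect_equal(s$stopband_hz, c(0.26, 10))
  s <- filter_spec("offline_emg")
  expect_equal(s$passband_3db_hz, c(9.56, 100.35))
  expect_equal(s$stopband_hz, c(8.97, 105))
})

test_that("designs are stable and meet spec at band edges for every named filter", {
  for (nm in c("online_eog", "offline_eeg", "offline_eog", "offline_emg")) {
    s <- filter_spec(nm)
    d <- design_cheby2_bandpass(s, 500)
    expect_lt(max(abs(d$zpk$p)), 1)
    att <- magnitude_response(d, c(s$stopband_hz, s$passband_3db_hz))
    expect_true(all(att$attenuation_db[1:2] >= s$stopband_atten_db),
                label = paste(nm, "stopband"))
    expect_true(all(att$attenuation_db[3:4] <= 3), label = paste(nm, "passband"))
    # geometric mid-band is essentially transparent
    mid <- sqrt(prod(s$passband_3db_hz))
    expect_lt(magnitude_response(d, mid)$attenuation_db, 3)
    # a band-pass blocks DC
    expect_gte(magnitude_response(d, 1e-4)$attenuation_db,
               s$stopband_atten_db)
  }
})

test_that("stopband attenuation holds on a dense grid (equiripple floor)", {
  s <- filter_spec("online_eog")
  d <- design_cheby2_bandpass(s, 500)
  hi <- magnitude_response(d, seq(15, 249, by = 0.25))
  expect_true(all(hi$attenuation_db >= 50))
  lo <- magnitude_response(d, seq(0.005, 0.1, by = 0.005))
  expect_true(all(lo$attenuation_db >= 50))
})

test_that("design matches signal::cheby2 for a mild band-pass placed identically", {
  skip_if_not_installed("signal")
  fs <- 200
  n <- 4
  rs <- 40
  ws <- c(2, 30)
  # my pipeline with the prototype stopband mapped exactly to ws
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  wsa <- warp(ws)
  zpk <- remstim:::bilinear_zpk(
    remstim:::lp_to_bp_zpk(remstim:::cheb2_prototype(n, rs),
                           sqrt(prod(wsa)), diff(wsa)), fs)
  ba <- signal::cheby2(n, rs, ws / (fs / 2), type = "pass")
  f <- c(0.5, 1, 2, 5, 10, 20, 30, 60, 90)
  h_sig <- signal::freqz(ba$b, ba$a, 2 * pi * f / fs)
  mine <- vapply(f, function(fi) {
    w <- exp(2i * pi * fi / fs)
    abs(zpk$k) * prod(abs(w - zpk$z)) / prod(abs(w - zpk$p))
  }, numeric(1))
  expect_equal(mine, Mod(h_sig$h), tolerance = 1e-6)
})

test_that("filtering is linear, scale-equivariant, and zero maps to zero", {
  d <- design_cheby2_bandpass("online_eog", 200)
  set.seed(1)
  x <- rnorm(2000)
  y <- rnorm(2000)
  for (mode in c("causal", "zero_phase")) {
    expect_equal(apply_filter(d, numeric(2000), mode = mode), numeric(2000))
    f1 <- apply_filter(d, x, mode = mode)
    expect_equal(apply_filter(d, 3.7 * x, mode = mode), 3.7 * f1,
                 tolerance = 1e-9)
    expect_equal(apply_filter(d, x + y, mode = mode),
                 f1 + apply_filter(d, y, mode = mode), tolerance = 1e-8)
  }
})

test_that("zero-phase mode has no lag at mid-band and doubles stopband attenuation", {
  fs <- 500
  d <- design_cheby2_bandpass("online_eog", fs)
  t <- seq(0, 60, by = 1 / fs)
  mid <- seq(10000, 20000)
  # mid-band sinusoid: in phase, unit gain
  xm <- sin(2 * pi * 1.2 * t)
  ym <- apply_filter(d, xm, mode = "zero_phase")
  cc <- ccf(xm[mid], ym[mid], lag.max = 30, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_equal(max(abs(ym[mid])), 1, tolerance = 0.02)
  # stopband sinusoid at 15 Hz: amplitude after two passes is the single-pass
  # amplitude squared (attenuation doubled in dB), measured by projection
  xs <- sin(2 * pi * 15 * t)
  single <- magnitude_response(d, 15)$attenuation_db
  ys <- apply_filter(d, xs, mode = "zero_phase")
  amp <- 2 * sqrt(mean(ys[mid] * sin(2 * pi * 15 * t[mid]))^2 +
                    mean(ys[mid] * cos(2 * pi * 15 * t[mid]))^2)
  measured <- -20 * log10(amp)
  expect_gt(measured, 2 * single - 8)
})

test_that("causal mode delays but zero-phase does not distort a pulse position", {
  fs <- 250
  d <- design_cheby2_bandpass("online_eog", fs)
  x <- numeric(2500)
  pulse <- remstim:::saccade_pulse(0.3, fs)
  x[1000:(999 + length(pulse))] <- pulse
  yz <- apply_filter(d, x, mode = "zero_phase")
  yc <- apply_filter(d, x, mode = "causal")
  lag_of <- function(y) {
    cc <- ccf(x, y, lag.max = 60, plot = FALSE)
    cc$lag[which.max(cc$acf)]
  }
  expect_lt(abs(lag_of(yz)), 3)
  expect_lt(lag_of(yc), 0)   # causal output trails the input
})

test_that("invalid specifications and mismatches are rejected", {
  expect_error(new_filter_spec(c(5, 1), c(0.5, 30), 40),
               class = "remstim_invalid_parameter")
  expect_error(new_filter_spec(c(1, 5), c(2, 30), 40),
               class = "remstim_invalid_parameter")
  expect_error(design_cheby2_bandpass("offline_emg", 180),
               class = "remstim_design_error")
  d <- design_cheby2_bandpass("online_eog", 500)
  expect_error(magnitude_response(d, 300), class = "remstim_invalid_parameter")
  sig <- psg_signal(rnorm(100), fs = 250)
  expect_error(apply_filter(d, sig), class = "remstim_invalid_parameter")
})
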