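test_that("epoching applies the stage, artifact, and edge exclusion rules", {
  fs <- 50
  h <- hypnogram(c("R", "N2", "R", "R", "R", "R"),
                 artifacts = tibble::tibble(onset_s = 96.5, duration_s = 1))
  sig <- psg_signal(rnorm(180 * fs), fs)
  # clicks: one clean REM, one in N2, one whose trial ends 1.5 s before the
  # artifact, one too close to the record edge
  clicks <- c(20, 40, 91.99, 179)
  ts <- epoch_trials(list(Cz = sig), clicks, h)
  expect_equal(dim(ts$data)[1], 1L)
  expect_equal(ts$click_times_s, 20)
  expect_equal(dim(ts$data)[3], 5 * fs + 1)
  expect_setequal(ts$excluded$reason, c("non_rem", "near_artifact", "edge"))
  exr <- setNames(ts$excluded$reason, ts$excluded$click_t_s)
  expect_equal(unname(exr["40"]), "non_rem")
  expect_equal(unname(exr["91.99"]), "near_artifact")
  expect_equal(unname(exr["179"]), "edge")
  # time axis contains 0 and the click sample matches the raw signal
  expect_true(0 %in% ts$time_s)
  i0 <- which(ts$time_s == 0)
  expect_equal(ts$data[1, 1, i0], sig$samples[20 * fs + 1])
})

test_that("an artifact ending just under the 2 s margin excludes the trial", {
  fs <- 50
  h <- hypnogram(rep("R", 6),
                 artifacts = tibble::tibble(onset_s = 10, duration_s = 2))
  # trial start = 15.5: artifact ends at 12, 3.5 s before -> retained
  ts_far <- epoch_trials(psg_signal(rnorm(180 * fs), fs), 17.5, h)
  expect_equal(dim(ts_far$data)[1], 1L)
  # trial start = 13.5: gap 1.5 s -> excluded
  ts_near <- epoch_trials(psg_signal(rnorm(180 * fs), fs), 15.5, h)
  expect_equal(ts_near$excluded$reason, "near_artifact")
})

test_that("spherical-spline interpolation reproduces smooth fields and enforces the 25% rule", {
  mont <- montage_1020()
  chans <- mont$label
  # constant field: interpolation is exact
  tr <- matrix(5, 21, 8, dimnames = list(chans, NULL))
  out <- interpolate_channels(tr, "Cz")
  expect_equal(out["Cz", ], rep(5, 8), tolerance = 1e-9)
  # smooth dipolar field: interpolated value close to truth
  field <- 10 * mont$z + 4 * mont$x
  tr2 <- matrix(field, 21, 3, dimnames = list(chans, NULL))
  out2 <- interpolate_channels(tr2, "C3")
  truth <- field[chans == "C3"]
  expect_lt(abs(out2["C3", 1] - truth), 0.15 * (max(field) - min(field)))
  # 4 of 21 (19%) interpolated; 6 of 21 (28.6%) rejected
  expect_false(is.null(interpolate_channels(tr, c("Cz", "C3", "C4", "Fz"))))
  expect_null(interpolate_channels(tr, c("Cz", "C3", "C4", "Fz", "Pz", "Oz")))
  expect_error(interpolate_channels(tr, "Nope"),
               class = "remstim_invalid_parameter")
})

test_that("ERP mean and interval behave on degenerate inputs", {
  template <- sin(seq(0, 2 * pi, length.out = 26))
  mk <- function(trials) {
    structure(list(data = trials, time_s = seq(-1, 1.5, length.out = 26),
                   channels = "Cz", fs = 10, click_times_s = numeric(0),
                   excluded = tibble::tibble()), class = "trial_set")
  }
  # identical trials: ERP equals the template with zero-width interval
  arr <- array(rep(template, each = 3), dim = c(3, 1, 26))
  erp <- compute_erp(mk(arr))
  expect_equal(erp$mean_uv, template)
  expect_equal(erp$ci_hi - erp$ci_lo, rep(0, 26))
  # (x, -x) pairs cancel
  arr2 <- array(c(template, -template), dim = c(2, 1, 26))
  arr2[1, 1, ] <- template
  arr2[2, 1, ] <- -template
  expect_equal(compute_erp(mk(arr2))$mean_uv, rep(0, 26))
  expect_error(compute_erp(mk(array(0, dim = c(1, 1, 26)))),
               class = "remstim_invalid_parameter")
  # subject-level intervals use per-subject means
  arr3 <- array(rnorm(8 * 26), dim = c(8, 1, 26))
  erp3 <- compute_erp(mk(arr3), subject_id = rep(1:4, each = 2))
  expect_equal(nrow(erp3), 26)
})

test_that("ERSP honours baseline, scale-invariance, and stationarity contracts", {
  ts <- make_rem_trialset(4, effects = null_click_effects(), fs = 125,
                          seed = 31)
  freqs <- seq(2, 30, by = 2)
  ep <- compute_ersp(ts, freqs = freqs, keep_trials = TRUE)
  # dB of the mean linear baseline power is 0 for every trial and frequency
  bl <- ep$times >= -1 & ep$times < 0
  for (tr in 1:2) {
    for (f in c(1, 5, 10)) {
      expect_equal(10 * log10(mean(10^(ep$values[tr, 1, f, bl] / 10))), 0,
                   tolerance = 1e-10)
    }
  }
  # scaling the raw data leaves the dB map untouched
  ts10 <- ts
  ts10$data <- ts$data * 10
  e1 <- compute_ersp(ts, freqs = freqs)
  e2 <- compute_ersp(ts10, freqs = freqs)
  expect_equal(e1$values, e2$values, tolerance = 1e-12)
  # stationary record: post-stimulus change stays near 0
  ts_big <- make_rem_trialset(12, effects = null_click_effects(), fs = 125,
                              seed = 32)
  e0 <- compute_ersp(ts_big, freqs = freqs)
  expect_lt(abs(ersp_band_change(e0, c(2, 30), c(0, 2))), 0.2)
  # grid above Nyquist refused
  expect_error(compute_ersp(ts, freqs = c(10, 70)),
               class = "remstim_invalid_parameter")
  expect_true(all(e1$unreliable_freqs < 1.2 + 1e-9))
})

test_that("an injected oscillatory burst appears at its time-frequency location", {
  fs <- 125
  ts <- make_rem_trialset(4, effects = null_click_effects(), fs = fs,
                          seed = 33)
  t_rel <- ts$time_s
  burst <- 40 * exp(-0.5 * ((t_rel - 0.6) / 0.08)^2) * sin(2 * pi * 20 * t_rel)
  for (tr in seq_len(dim(ts$data)[1])) {
    ts$data[tr, 1, ] <- ts$data[tr, 1, ] + burst
  }
  e <- compute_ersp(ts, freqs = seq(4, 30, by = 1))
  m <- e$values[1, , ]
  peak <- which(m == max(m), arr.ind = TRUE)
  expect_lt(abs(e$freqs[peak[1]] - 20), 3)
  expect_lt(abs(e$times[peak[2]] - 0.6), 0.2)
})
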