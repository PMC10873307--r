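test_that("hypnogram generation honours degenerate, seeded, and calibrated requests", {
  # degenerate request: everything REM
  h <- generate_hypnogram(10, stage_fractions = c(W = 0, N1 = 0, N2 = 0,
                                                  N3 = 0, R = 1), seed = 1)
  expect_equal(h$stages, rep("R", 20))
  # determinism
  h1 <- generate_hypnogram(120, seed = 42)
  h2 <- generate_hypnogram(120, seed = 42)
  expect_identical(h1$stages, h2$stages)
  expect_identical(h1$arousals, h2$arousals)
  # a full night reproduces the requested REM share of sleep time
  h3 <- generate_hypnogram(450, seed = 7)
  expect_lt(abs(sleep_summary(h3)$rem_pct - 18.34), 2)
  # validation
  expect_error(generate_hypnogram(10, stage_fractions = c(W = 0.5, N1 = 0.2,
                                                          N2 = 0.2, N3 = 0.2,
                                                          R = 0.2)),
               class = "remstim_invalid_parameter")
  expect_error(generate_hypnogram(10.01), class = "remstim_invalid_parameter")
})

test_that("EOG saccades are REM-restricted with exact ground truth", {
  # zero rate: no saccade, noise never near threshold
  h <- rem_hypnogram(10)
  g0 <- generate_rem_eog(h, saccade_rate_per_min = 0, fs = 100, seed = 1)
  expect_length(g0$em_times_s, 0)
  expect_lt(max(abs(g0$signal$samples)), 50)
  # pure-REM rate: Poisson-scale count (99% interval around the mean after
  # 0.6 s thinning: P(gap < 0.6) thins ~6% of a rate-0.1/s stream)
  g1 <- generate_rem_eog(rem_hypnogram(20), saccade_rate_per_min = 6,
                         fs = 100, seed = 2)
  expect_gte(length(g1$em_times_s), qpois(0.005, 60))
  expect_lte(length(g1$em_times_s), qpois(0.995, 60))
  # no saccades outside REM
  hm <- hypnogram(rep(c("N2", "R"), 10))
  gm <- generate_rem_eog(hm, fs = 100, seed = 3)
  expect_true(all(stage_at(hm, gm$em_times_s) == "R"))
  expect_length(generate_rem_eog(hypnogram(rep("N2", 10)), fs = 100,
                                 seed = 4)$em_times_s, 0)
  # saccade amplitudes land in the requested band
  pk <- vapply(gm$em_times_s, function(t) {
    idx <- round(t * 100):(round(t * 100) + 30)
    max(abs(gm$signal$samples[idx]))
  }, numeric(1))
  expect_true(all(pk > 40 & pk < 120))
  expect_error(generate_rem_eog(h, amp_range_uv = c(0, 50)),
               class = "remstim_invalid_parameter")
})

test_that("EEG generator injects the P2 latency recoverable by the ERP", {
  ts <- make_rem_trialset(40, effects = click_effects(), fs = 125, seed = 5,
                          click_step_s = 5)
  erp <- compute_erp(ts, average_channels = TRUE)
  sub <- erp[erp$time_s > 0.1 & erp$time_s < 0.5, ]
  peak_t <- sub$time_s[which.max(sub$mean_uv)]
  expect_gte(peak_t, 0.25)
  expect_lte(peak_t, 0.30)
})

test_that("null injection leaves the post-click spectrum flat", {
  ts <- make_rem_trialset(8, effects = null_click_effects(), fs = 125,
                          seed = 6)
  e <- compute_ersp(ts, freqs = seq(2, 30, by = 1))
  expect_lt(abs(ersp_band_change(e, c(2, 30), c(0, 2))), 0.15)
})

test_that("clicks outside the record are rejected", {
  h <- rem_hypnogram(2)
  expect_error(generate_eeg_with_responses(h, click_times_s = 100,
                                           channels = "Cz", fs = 50),
               class = "remstim_invalid_parameter")
})

test_that("behavioural generator encodes effects and is seed-stable", {
  t1 <- generate_behavioural_dataset(3, seed = 9)
  t2 <- generate_behavioural_dataset(3, seed = 9)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_setequal(unique(t1$task), c("PVT", "VDT", "MTT"))
  expect_equal(nrow(dplyr::distinct(t1, subject_id, condition, session)), 12)
  # VDT trials follow the printed SOA block ladder
  soa <- sort(unique(t1$soa_ms[t1$task == "VDT"]))
  expect_equal(soa, c(40, 60, 80, 100, 120, 160, 200, 300, 400))
  counts <- table(t1$soa_ms[t1$task == "VDT" & t1$subject_id == 1 &
                              t1$condition == "CNT" & t1$session == "pre"])
  expect_true(all(counts[c("400", "300", "200", "160")] == 100))
  expect_true(all(counts[c("120", "100", "80", "60", "40")] == 150))
})

test_that("zero behavioural effects give no condition difference (PVT and MTT)", {
  tr <- generate_behavioural_dataset(
    100, effects = c(pvt = 0, vdt = 0, mtt = 0),
    base_gain = c(pvt = 0, vdt = 0, mtt = 0), seed = 10)
  sc <- score_behaviour(tr[tr$task != "VDT", ])
  for (tk in c("PVT", "MTT")) {
    wide <- tidyr::pivot_wider(sc[sc$task == tk, c("subject_id", "condition",
                                                   "gain_pct")],
                               names_from = "condition",
                               values_from = "gain_pct")
    pv <- t.test(wide$STM, wide$CNT, paired = TRUE)$p.value
    expect_gt(pv, 0.01)
  }
})

test_that("the VDT condition effect is recovered by the full scoring path", {
  tr <- generate_behavioural_dataset(18, seed = 11)
  sc <- score_behaviour(tr[tr$task == "VDT", ])
  wide <- tidyr::pivot_wider(sc[, c("subject_id", "condition", "gain_pct")],
                             names_from = "condition",
                             values_from = "gain_pct")
  d <- wide$STM - wide$CNT
  ci <- t.test(d)$conf.int
  expect_gt(20.71, ci[1])
  expect_lt(20.71, ci[2])
})

test_that("EMG shows REM atonia", {
  h <- hypnogram(rep(c("N2", "R"), 6))
  emg <- generate_emg(h, fs = 100, seed = 12)
  st <- remstim:::stage_at(h, remstim:::signal_times(emg))
  expect_lt(sd(emg$samples[st == "R"]), 0.5 * sd(emg$samples[st == "N2"]))
})

test_that("EDF round-trips within 16-bit quantization and fixtures are complete", {
  h <- hypnogram(rep(c("R", "N2"), 4),
                 arousals = tibble::tibble(onset_s = 33, duration_s = 5))
  eog <- generate_rem_eog(h, fs = 100, seed = 13)
  emg <- generate_emg(h, fs = 100, seed = 14)
  dir <- withr::local_tempdir()
  ev <- run_em_detector(eog$signal,
                        stimulator_config(threshold_uv = 50, fs = 100),
                        hypnogram = h)
  tr <- generate_behavioural_dataset(2, seed = 15)
  man <- write_fixture_dataset(list(`EOG-L` = eog$signal, EMG = emg), h, ev,
                               tr, out_dir = dir, seed = 13)
  expect_true(all(file.exists(file.path(dir, man$file))))
  expect_true(all(man$seed == 13))
  back <- read_edf(file.path(dir, "signals.edf"))
  q <- max(abs(eog$signal$samples)) / 32767
  expect_lt(max(abs(back[["EOG-L"]]$samples - eog$signal$samples)), 2 * q)
  expect_equal(back[["EOG-L"]]$fs, 100)
  expect_equal(back[["EMG"]]$kind, "EMG")
  hyp_tab <- utils::read.delim(file.path(dir, "hypnogram.tsv"))
  expect_equal(nrow(hyp_tab), length(h$stages))
  expect_equal(hyp_tab$stage, h$stages)
  # byte-identical rewrite under the same seed (determinism of the writer)
  dir2 <- withr::local_tempdir()
  write_fixture_dataset(list(`EOG-L` = eog$signal, EMG = emg), h, ev, tr,
                        out_dir = dir2, seed = 13)
  for (f in man$file) {
    expect_identical(readBin(file.path(dir, f), "raw", 1e6),
                     readBin(file.path(dir2, f), "raw", 1e6),
                     label = f)
  }
})
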