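# Shared small fixtures, built in code at test time.

# all-REM hypnogram of n 30-s epochs (no annotations)
rem_hypnogram <- function(n_epochs = 6) {
  hypnogram(rep("R", n_epochs))
}

# a small click-locked trial set from the EEG generator, single channel,
# band-passed with the offline EEG filter as the analysis contract requires
make_rem_trialset <- function(n_epochs = 6, effects = click_effects(),
                              fs = 125, seed = 1, channel = "Cz",
                              click_step_s = 6, prefilter = TRUE) {
  h <- rem_hypnogram(n_epochs)
  clicks <- seq(8, n_epochs * 30 - 8, by = click_step_s)
  eeg <- generate_eeg_with_responses(h, clicks, effects, channels = channel,
                                     fs = fs, seed = seed)
  if (prefilter) {
    d <- design_cheby2_bandpass("offline_eeg", fs)
    eeg <- lapply(eeg, function(s) apply_filter(d, s, mode = "zero_phase"))
  }
  epoch_trials(eeg, clicks, h)
}

# brute-force 4-connected component sizes of a logical matrix (oracle)
oracle_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue) > 0) {
      ij <- queue[[1]]
      queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ni <- ij[1] + d[1]
        nj <- ij[2] + d[2]
        if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
            mask[ni, nj] && lab[ni, nj] == 0) {
          lab[ni, nj] <- cur
          queue <- c(queue, list(c(ni, nj)))
        }
      }
    }
  }
  if (cur == 0) integer(0) else tabulate(lab[lab > 0])
}

# independent max-cluster-size statistic used by enumeration oracles
oracle_max_cluster <- function(a, b, alpha = 0.05) {
  n1 <- dim(a)[1]
  n2 <- dim(b)[1]
  shape <- dim(a)[-1]
  am <- matrix(a, n1)
  bm <- matrix(b, n2)
  mx <- 0L
  tt <- pp <- numeric(ncol(am))
  for (k in seq_len(ncol(am))) {
    tv <- t.test(am[, k], bm[, k])
    tt[k] <- unname(tv$statistic)
    pp[k] <- tv$p.value
  }
  for (sgn in c(1, -1)) {
    m <- matrix(pp < alpha & sign(tt) == sgn, shape[1], shape[2])
    sz <- oracle_components(m)
    if (length(sz) > 0) mx <- max(mx, max(sz))
  }
  mx
}
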