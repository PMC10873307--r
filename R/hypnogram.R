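#' Hypnogram objects
#'
#' A hypnogram holds 30-s-epoch sleep stage labels (AASM: W, N1, N2, N3, R)
#' together with arousal and artifact annotation intervals.
#'
#' @param stages Character vector of stage labels, one per 30-s epoch.
#' @param arousals,artifacts Tibbles (or data frames) with columns `onset_s`
#'   and `duration_s`, or `NULL` for none.
#' @param epoch_len_s Epoch length in seconds (fixed at 30 in this design).
#' @param record_start_s Clock offset of the first epoch, seconds.
#' @return A `hypnogram` object.
#' @examples
#' h <- hypnogram(c("W", "N1", "N2", "R", "R", "W"))
#' as_tibble(h)
#' @export
hypnogram <- function(stages, arousals = NULL, artifacts = NULL,
                      epoch_len_s = 30, record_start_s = 0) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), c("W", "N1", "N2", "N3", "R"))
  if (length(bad) > 0) {
    abort(paste0("Unknown stage labels: ", paste(bad, collapse = ", ")),
          class = "remstim_invalid_parameter")
  }
  dur <- epoch_len_s * length(stages)
  norm_ann <- function(x, what) {
    if (is.null(x) || nrow(as.data.frame(x)) == 0) {
      return(tibble(onset_s = numeric(0), duration_s = numeric(0)))
    }
    x <- as_tibble(x)[c("onset_s", "duration_s")]
    if (any(x$duration_s < 0) || any(x$onset_s < record_start_s) ||
        any(x$onset_s + x$duration_s > record_start_s + dur + 1e-9)) {
      abort(sprintf("%s intervals must be non-negative and inside the record.",
                    what), class = "remstim_invalid_parameter")
    }
    x
  }
  structure(list(epoch_len_s = epoch_len_s, stages = stages,
                 arousals = norm_ann(arousals, "Arousal"),
                 artifacts = norm_ann(artifacts, "Artifact"),
                 record_start_s = record_start_s),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram: %d epochs of %g s (%.1f min), %d arousals, %d artifacts>\n",
              length(x$stages), x$epoch_len_s,
              length(x$stages) * x$epoch_len_s / 60,
              nrow(x$arousals), nrow(x$artifacts)))
  tab <- table(factor(x$stages, levels = c("W", "N1", "N2", "N3", "R")))
  cat("  epochs:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' @export
#' @method as_tibble hypnogram
as_tibble.hypnogram <- function(x, ...) {
  n <- length(x$stages)
  tibble(epoch = seq_len(n),
         onset_s = x$record_start_s + (seq_len(n) - 1) * x$epoch_len_s,
         stage = x$stages)
}

# seconds covered by the hypnogram
hyp_duration_s <- function(h) length(h$stages) * h$epoch_len_s

# stage label at given times (seconds); NA outside the record
stage_at <- function(h, t_s) {
  idx <- floor((t_s - h$record_start_s) / h$epoch_len_s) + 1
  out <- rep(NA_character_, length(t_s))
  ok <- idx >= 1 & idx <= length(h$stages)
  out[ok] <- h$stages[idx[ok]]
  out
}

# epoch index containing each time, NA outside
epoch_at <- function(h, t_s) {
  idx <- floor((t_s - h$record_start_s) / h$epoch_len_s) + 1
  idx[idx < 1 | idx > length(h$stages)] <- NA_integer_
  as.integer(idx)
}

#' Single-channel polysomnography signal
#'
#' @param samples Numeric vector of samples in microvolts.
#' @param fs Sampling rate in Hz.
#' @param label Channel label (10-20 site, `EOG-L`, `EOG-R`, or `EMG`).
#' @param kind One of `"EEG"`, `"EOG"`, `"EMG"`.
#' @param start_s Time of the first sample, seconds.
#' @return A `psg_signal` object.
#' @export
psg_signal <- function(samples, fs, label = "EEG", kind = c("EEG", "EOG", "EMG"),
                       start_s = 0) {
  kind <- match.arg(kind)
  check_scalar(fs, "fs")
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) {
    abort("Samples must be finite.", class = "remstim_invalid_parameter")
  }
  structure(list(label = label, kind = kind, fs = fs, samples = samples,
                 start_s = start_s),
            class = "psg_signal")
}

#' @export
print.psg_signal <- function(x, ...) {
  cat(sprintf("<psg_signal '%s' (%s): %d samples @ %g Hz (%.1f min)>\n",
              x$label, x$kind, length(x$samples), x$fs,
              length(x$samples) / x$fs / 60))
  invisible(x)
}

# time axis of a signal
signal_times <- function(s) s$start_s + (seq_along(s$samples) - 1) / s$fs
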