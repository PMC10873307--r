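#' Write signals to a European Data Format (EDF) file
#'
#' Minimal EDF writer for continuous polysomnography channels: one-second
#' data records, 16-bit samples scaled channel-wise to a symmetric physical
#' range. Signals may have different sampling rates but must share their
#' duration; durations are padded to whole seconds with zeros.
#'
#' @param signals A named list of [psg_signal()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(signals, path) {
  if (inherits(signals, "psg_signal")) signals <- list(signals)
  stopifnot(length(signals) > 0,
            all(vapply(signals, inherits, logical(1), "psg_signal")))
  ns <- length(signals)
  dur_s <- vapply(signals, function(s) length(s$samples) / s$fs, numeric(1))
  n_rec <- as.integer(ceiling(max(dur_s)))
  spr <- vapply(signals, function(s) {
    if (abs(s$fs - round(s$fs)) > 1e-9) {
      abort("EDF writer requires integer sampling rates.",
            class = "remstim_invalid_parameter")
    }
    as.integer(round(s$fs))
  }, integer(1))
  pad_field <- function(x, width) {
    x <- substr(as.character(x), 1, width)
    sprintf(paste0("%-", width, "s"), x)
  }
  phys_max <- vapply(signals, function(s) {
    m <- max(abs(s$samples), 1e-6)
    signif(m * 1.0001, 7)
  }, numeric(1))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    pad_field("Startdate X X X X", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field("1", 8),
    pad_field(ns, 4))
  field <- function(f, width) {
    paste0(vapply(signals, function(s) pad_field(f(s), width), character(1)),
           collapse = "")
  }
  labels <- vapply(signals, function(s) s$label, character(1))
  hdr <- paste0(hdr,
    paste0(vapply(labels, pad_field, character(1), width = 16), collapse = ""),
    field(function(s) "", 80),
    field(function(s) "uV", 8),
    paste0(vapply(-phys_max, pad_field, character(1), width = 8), collapse = ""),
    paste0(vapply(phys_max, pad_field, character(1), width = 8), collapse = ""),
    pad_field(paste0(rep(pad_field(-32768, 8), ns), collapse = ""), 8 * ns),
    pad_field(paste0(rep(pad_field(32767, 8), ns), collapse = ""), 8 * ns),
    field(function(s) "", 80),
    paste0(vapply(spr, pad_field, character(1), width = 8), collapse = ""),
    field(function(s) "", 32))
  writeChar(hdr, con, eos = NULL)
  dig <- lapply(seq_len(ns), function(i) {
    x <- signals[[i]]$samples
    x <- c(x, rep(0, n_rec * spr[i] - length(x)))
    as.integer(round(x / phys_max[i] * 32767))
  })
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1) * spr[i] + 1):(r * spr[i])
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Parses the standard EDF header and 16-bit data records and reconstructs
#' the physical (microvolt) samples. Channel kinds are inferred from labels
#' (`EOG*` -> EOG, `EMG*` -> EMG, otherwise EEG).
#'
#' @param path EDF file path.
#' @return A named list of [psg_signal()] objects.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  per_sig <- function(width) vapply(seq_len(ns), function(i) rd(width),
                                    character(1))
  labels <- per_sig(16)
  per_sig(80)
  per_sig(8)
  pmin_ <- as.numeric(per_sig(8))
  pmax_ <- as.numeric(per_sig(8))
  dmin_ <- as.numeric(per_sig(8))
  dmax_ <- as.numeric(per_sig(8))
  per_sig(80)
  spr <- as.integer(per_sig(8))
  per_sig(32)
  raw <- lapply(seq_len(ns), function(i) integer(0))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw[[i]] <- c(raw[[i]], readBin(con, integer(), n = spr[i], size = 2,
                                      endian = "little"))
    }
  }
  out <- lapply(seq_len(ns), function(i) {
    scale <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
    x <- (raw[[i]] - dmin_[i]) * scale + pmin_[i]
    kind <- if (grepl("^EOG", labels[i])) "EOG"
            else if (grepl("^EMG", labels[i])) "EMG" else "EEG"
    psg_signal(x, fs = spr[i] / rec_dur, label = labels[i], kind = kind)
  })
  names(out) <- labels
  out
}

#' Write a complete synthetic fixture dataset to disk
#'
#' Serializes a synthetic night: signals to one EDF file, hypnogram,
#' annotations, detector events, and behavioural trials to tab-separated
#' files with header rows, plus a manifest listing every written file and
#' the generator seed.
#'
#' @param signals Named list of [psg_signal()]s (or `NULL` to skip).
#' @param hypnogram A [hypnogram()] (or `NULL`).
#' @param events Event tibble as returned by [run_em_detector()] (or `NULL`).
#' @param trials Behavioural trial tibble (or `NULL`).
#' @param out_dir Output directory (created if missing).
#' @param seed The generator seed, recorded in the manifest.
#' @return A tibble manifest (columns `file`, `what`, `seed`), also written
#'   to `manifest.tsv`.
#' @export
write_fixture_dataset <- function(signals = NULL, hypnogram = NULL,
                                  events = NULL, trials = NULL,
                                  out_dir, seed = NA_integer_) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort("Cannot create output directory.", class = "remstim_io_error")
  }
  files <- character(0)
  what <- character(0)
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, name)
    what <<- c(what, sub("[.]tsv$", "", name))
  }
  if (!is.null(signals)) {
    write_edf(signals, file.path(out_dir, "signals.edf"))
    files <- c(files, "signals.edf")
    what <- c(what, "signals")
  }
  if (!is.null(hypnogram)) {
    tsv(as_tibble(hypnogram), "hypnogram.tsv")
    tsv(dplyr::bind_rows(
      dplyr::mutate(hypnogram$arousals, kind = "arousal"),
      dplyr::mutate(hypnogram$artifacts, kind = "artifact")),
      "annotations.tsv")
  }
  if (!is.null(events)) tsv(events, "events.tsv")
  if (!is.null(trials)) tsv(trials, "behaviour.tsv")
  manifest <- tibble(file = files, what = what, seed = seed)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}
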