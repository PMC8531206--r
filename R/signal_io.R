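# Preprocessing of polysomnography into labeled 30 s epochs: hypnogram
# reading, R&K -> AASM stage mapping, Butterworth filtering, resampling to
# the 100 Hz working rate, and epoching with a bad-segment rejection rule.

#' Read a recording (alias with explicit channel request)
#'
#' Thin wrapper over [read_edf()] matching the ingestion contract: all
#' requested channels must be present, native sampling rates are preserved,
#' and values are in physical units (uV).
#'
#' @inheritParams read_edf
#' @return a `psg_recording`
#' @export
read_recording <- function(path, channel_names) {
  read_edf(path, channel_names = channel_names)
}

#' Read a hypnogram (scored stage events)
#'
#' Accepts an EDF+ annotation file or a plain-text scored-events table
#' (CSV/TSV with columns onset, duration, label). Events are returned sorted
#' by onset with raw labels verbatim; overlapping scored intervals trigger a
#' warning and the later event is truncated out (keep-first policy).
#'
#' @param path EDF+ annotation file, or .csv/.tsv events table
#' @return data.frame with onset (s), duration (s), label (character)
#' @export
read_hypnogram <- function(path) {
  if (!file.exists(path))
    .err(paste0("hypnogram file not found: ", path),
         "sleepfusion_missing_file")
  ev <- if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    .read_edf_annotations(path)
  } else {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    d <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
    if (!all(c("onset", "duration", "label") %in% names(d)))
      .err("events table needs onset, duration, label columns",
           "sleepfusion_bad_header")
    d[c("onset", "duration", "label")]
  }
  ev <- ev[!is.na(ev$duration) & ev$duration > 0, , drop = FALSE]
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  if (nrow(ev) > 1L) {
    keep <- rep(TRUE, nrow(ev))
    end_prev <- ev$onset[1L] + ev$duration[1L]
    for (i in 2L:nrow(ev)) {
      if (ev$onset[i] < end_prev - 1e-9) {
        warning("overlapping scored intervals at ", ev$onset[i],
                " s; keeping the earlier event")
        keep[i] <- FALSE
      } else end_prev <- ev$onset[i] + ev$duration[i]
    }
    ev <- ev[keep, , drop = FALSE]
    rownames(ev) <- NULL
  }
  ev
}

#' Map a raw scoring label to an AASM stage
#'
#' Maps the Sleep-EDF / R&K vocabulary onto the five AASM stages: stages 3
#' and 4 are merged into N3 (the AASM rule), "Sleep stage R" becomes REM,
#' and unscorable epochs ("Sleep stage ?", "Movement time") map to `NA` so
#' they are dropped upstream. Unrecognized tokens are an error naming the
#' token.
#'
#' @param raw_label character scalar or vector of raw scoring tokens
#' @return character vector of stage names ("W","REM","N1","N2","N3") with
#'   `NA` for dropped labels
#' @export
#' @examples
#' map_stage_label("Sleep stage 4")  # "N3"
map_stage_label <- function(raw_label) {
  vocab <- c("Sleep stage W" = "W",
             "Sleep stage 1" = "N1", "Sleep stage 2" = "N2",
             "Sleep stage 3" = "N3", "Sleep stage 4" = "N3",
             "Sleep stage R" = "REM",
             "Sleep stage N1" = "N1", "Sleep stage N2" = "N2",
             "Sleep stage N3" = "N3",
             "Sleep stage ?" = NA_character_,
             "Movement time" = NA_character_)
  bad <- setdiff(unique(raw_label), names(vocab))
  if (length(bad) > 0L)
    .err(paste0("unrecognized stage label(s): ",
                paste(bad, collapse = ", ")), "sleepfusion_bad_label")
  unname(vocab[raw_label])
}

#' Zero-phase Butterworth bandpass filter
#'
#' Order-`order` Butterworth bandpass applied forward-backward
#' (`signal::filtfilt`), so the magnitude response is squared and the phase
#' is zero -- waveform morphology that sleep scorers rely on is preserved.
#'
#' @param x numeric signal
#' @param fs sampling rate (Hz)
#' @param low,high band edges, 0 < low < high < fs/2
#' @param order filter order (default 3)
#' @return filtered signal, same length as input
#' @export
bandpass <- function(x, fs, low, high, order = 3L) {
  if (!(low > 0 && low < high && high < fs / 2))
    .err("bandpass: need 0 < low < high < fs/2", "sleepfusion_bad_band")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, as.numeric(x)))
}

#' Resample a signal down to the 100 Hz working rate
#'
#' Rational-ratio resampling: zero-stuff by the numerator, zero-phase FIR
#' anti-alias low-pass (applied forward-backward, so no group delay), then
#' decimate by the denominator. Works for any rational input rate
#' >= 100 Hz; the output length is `round(length(x) * 100 / fs_in)`.
#'
#' @param x numeric signal
#' @param fs_in input sampling rate in Hz (>= 100)
#' @return resampled signal at 100 Hz
#' @export
resample_to_100hz <- function(x, fs_in) {
  if (fs_in < 100)
    .err("resample_to_100hz: no upsampling (fs_in < 100)",
         "sleepfusion_bad_rate")
  x <- as.numeric(x)
  if (fs_in == 100) return(x)
  frac <- .simplify_ratio(100, fs_in)
  p <- frac[1L]; q <- frac[2L]
  up <- if (p > 1L) {
    u <- numeric(length(x) * p)
    u[seq(1L, length(u), by = p)] <- x * p      # gain compensation
    u
  } else x
  cutoff <- 1 / max(p, q)                       # intermediate Nyquist units
  ntaps <- 2L * 10L * max(p, q)
  fir <- signal::fir1(ntaps, cutoff)
  y <- as.numeric(signal::filtfilt(fir, up))
  y <- y[seq(1L, length(y), by = q)]
  n_out <- round(length(x) * 100 / fs_in)
  if (length(y) >= n_out) y[seq_len(n_out)] else
    c(y, numeric(n_out - length(y)))
}

.simplify_ratio <- function(p, q) {
  # allow non-integer rates expressed to 1e-6 Hz
  s <- 1e6
  p <- round(p * s); q <- round(q * s)
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(p, q)
  c(p / d, q / d)
}

#' Cut a preprocessed recording into labeled 30 s epochs
#'
#' Walks the scored hypnogram intervals and emits one `sleep_epoch` per
#' half-open 30 s window `[t, t+30)`, aligned to the hypnogram onsets.
#' Epochs whose label maps to `NA` (unscored / movement) are dropped, and a
#' bad-segment rule rejects epochs where the recorder saturated (> 5% of
#' samples at the physical range limits) or the signal is constant for more
#' than 1 s (electrode fallen off).
#'
#' @param recording a `psg_recording`, already at 100 Hz and filtered
#' @param hypnogram data.frame from [read_hypnogram()] (raw labels) or with
#'   already-mapped stage names
#' @param eeg_channel,eog_channel channel names in `recording`
#' @param subject_id identifier stamped on each epoch
#' @param fs working sampling rate (100 Hz)
#' @return list of `sleep_epoch` objects (fields eeg, eog, label,
#'   subject_id, epoch_index)
#' @export
make_epochs <- function(recording, hypnogram, eeg_channel, eog_channel,
                        subject_id = "S1", fs = 100) {
  for (ch in c(eeg_channel, eog_channel))
    if (!ch %in% names(recording$channels))
      .err(paste0("channel absent from recording: ", ch),
           "sleepfusion_missing_channel")
  eeg <- recording$channels[[eeg_channel]]
  eog <- recording$channels[[eog_channel]]
  n <- length(eeg)
  hyp_end <- max(hypnogram$onset + hypnogram$duration)
  if (hyp_end > n / fs + 30)
    .err("hypnogram extends beyond the recording by more than one epoch",
         "sleepfusion_length_mismatch")
  mapped <- if (all(hypnogram$label %in% c(stage_levels(), NA)))
    hypnogram$label else map_stage_label(hypnogram$label)
  out <- list()
  k <- 0L
  for (i in seq_len(nrow(hypnogram))) {
    lab <- mapped[i]
    n_ep <- floor(hypnogram$duration[i] / 30)
    if (n_ep < 1L) next
    for (e in seq_len(n_ep)) {
      t0 <- hypnogram$onset[i] + (e - 1L) * 30
      i0 <- round(t0 * fs)
      if (i0 + 30L * fs > n) next          # partial tail window: skipped
      k <- k + 1L
      if (is.na(lab)) next                  # unscored: counted, not emitted
      seg_eeg <- eeg[(i0 + 1L):(i0 + 30L * fs)]
      seg_eog <- eog[(i0 + 1L):(i0 + 30L * fs)]
      if (.is_bad_segment(seg_eeg, recording$phys_range[[eeg_channel]], fs) ||
          .is_bad_segment(seg_eog, recording$phys_range[[eog_channel]], fs))
        next
      out[[length(out) + 1L]] <- structure(
        list(eeg = seg_eeg, eog = seg_eog, label = lab,
             subject_id = subject_id, epoch_index = k),
        class = "sleep_epoch")
    }
  }
  out
}

# Saturation / flatline rejection: > 5% of samples at the recorder's range
# limits, or any constant run longer than 1 s.
.is_bad_segment <- function(x, phys_range, fs) {
  if (!is.null(phys_range)) {
    tol <- 1e-6 * diff(range(phys_range))
    sat <- mean(x <= phys_range[1L] + tol | x >= phys_range[2L] - tol)
    if (sat > 0.05) return(TRUE)
  }
  r <- rle(diff(x) == 0)
  any(r$values & r$lengths >= fs)
}

#' @export
print.sleep_epoch <- function(x, ...) {
  cat("<sleep_epoch> ", x$subject_id, " #", x$epoch_index, " stage ",
      x$label, ", ", length(x$eeg), " samples/channel\n", sep = "")
  invisible(x)
}

#' Write/read an epoch store (one container per subject + label text file)
#'
#' The store is one serialized array container per subject
#' (`<subject>_epochs.rds`) holding the EEG/EOG sample matrices, plus a
#' plain-text label file (`<subject>_labels.txt`, one stage index per line
#' in the scoring-matrix order W=1, REM=2, N1=3, N2=4, N3=5).
#'
#' @param epochs list of `sleep_epoch`
#' @param dir output directory
#' @param subject_id store key (defaults to the first epoch's subject)
#' @return paths, invisibly
#' @export
write_epoch_store <- function(epochs, dir, subject_id = NULL) {
  stopifnot(length(epochs) > 0L)
  if (is.null(subject_id)) subject_id <- epochs[[1L]]$subject_id
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  eeg <- t(vapply(epochs, function(e) e$eeg, numeric(3000L)))
  eog <- t(vapply(epochs, function(e) e$eog, numeric(3000L)))
  labs <- vapply(epochs, function(e) e$label, "")
  p1 <- file.path(dir, paste0(subject_id, "_epochs.rds"))
  p2 <- file.path(dir, paste0(subject_id, "_labels.txt"))
  saveRDS(list(eeg = eeg, eog = eog, subject_id = subject_id,
               epoch_index = vapply(epochs, function(e) e$epoch_index, 0L)),
          p1)
  writeLines(as.character(stage_index(labs)), p2)
  invisible(c(p1, p2))
}

#' @rdname write_epoch_store
#' @export
read_epoch_store <- function(dir, subject_id) {
  d <- readRDS(file.path(dir, paste0(subject_id, "_epochs.rds")))
  labs <- stage_from_index(as.integer(readLines(
    file.path(dir, paste0(subject_id, "_labels.txt")))))
  lapply(seq_along(labs), function(i) structure(
    list(eeg = d$eeg[i, ], eog = d$eog[i, ], label = labs[i],
         subject_id = d$subject_id, epoch_index = d$epoch_index[i]),
    class = "sleep_epoch"))
}
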