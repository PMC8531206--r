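# Minimal EDF / EDF+ reader and writer (16-bit European Data Format).
# Covers what polysomnography work needs: multichannel signal records at
# per-channel rates, and EDF+ time-stamped annotation lists (TALs) for
# hypnograms. Values are scaled to physical units on read.

.err <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "sleepfusion_error")))
}

.pad <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) x <- substr(x, 1L, n)
  formatC(x, width = -n, flag = " ")
}

.num8 <- function(x) {
  d <- 8L
  repeat {
    s <- formatC(signif(x, d), format = "fg")
    if (nchar(s) <= 8L || d == 1L) break
    d <- d - 1L
  }
  .pad(s, 8L)
}

#' Write signals (and optional annotations) to an EDF/EDF+ file
#'
#' Each channel is scaled independently to the full 16-bit digital range.
#' Record duration is 1 s, so each channel must contain a whole number of
#' seconds at its sampling rate. When `annotations` is supplied the file is
#' written as EDF+C with an "EDF Annotations" channel carrying one
#' time-keeping TAL per record plus the events whose onset falls in it.
#'
#' @param path output file path
#' @param channels named list of numeric vectors (physical units, e.g. uV)
#' @param fs numeric vector of sampling rates (Hz), recycled to the number
#'   of channels; each must be a positive integer
#' @param start_date,start_time header fields, "dd.mm.yy" / "hh.mm.ss"
#' @param annotations optional data.frame with columns onset (s),
#'   duration (s), label
#' @param patient,recording free-text header fields
#' @return `path`, invisibly
#' @export
write_edf <- function(path, channels, fs, start_date = "01.01.01",
                      start_time = "00.00.00", annotations = NULL,
                      patient = "X X X X", recording = "Startdate X") {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)))
  fs <- rep_len(fs, length(channels))
  if (any(fs <= 0) || any(fs != round(fs)))
    .err("sampling rates must be positive integers", "sleepfusion_bad_header")
  durs <- mapply(function(x, f) length(x) / f, channels, fs)
  if (length(unique(durs)) != 1L)
    .err("all channels must cover identical duration",
         "sleepfusion_bad_header")
  n_rec <- durs[[1L]]
  if (n_rec != round(n_rec))
    .err("channels must contain a whole number of 1 s records",
         "sleepfusion_bad_header")
  n_rec <- as.integer(n_rec)

  scale <- lapply(channels, function(x) {
    pmin <- min(x); pmax <- max(x)
    if (pmax <= pmin) { pmin <- pmin - 1; pmax <- pmax + 1 }
    # pad by 0.2% so the 8-char header encoding still brackets the data,
    # then quantize against the encoded values, so reader and writer use
    # exactly the same scale
    pad <- 0.002 * (pmax - pmin)
    pmin <- as.numeric(trimws(.num8(pmin - pad)))
    pmax <- as.numeric(trimws(.num8(pmax + pad)))
    if (pmax <= pmin) pmax <- pmin + 1
    list(pmin = pmin, pmax = pmax, dmin = -32767L, dmax = 32767L)
  })
  dig <- mapply(function(x, s) {
    d <- as.integer(round((x - s$pmin) / (s$pmax - s$pmin) *
                            (s$dmax - s$dmin) + s$dmin))
    pmin(pmax(d, s$dmin), s$dmax)
  }, channels, scale, SIMPLIFY = FALSE)

  ann_recs <- NULL
  if (!is.null(annotations)) {
    tal_one <- function(on, du, lab) {
      d <- if (is.finite(du) && du > 0)
        paste0("\x15", formatC(du, format = "fg")) else ""
      paste0(ifelse(on >= 0, "+", ""), formatC(on, format = "fg"), d,
             "\x14", lab, "\x14")
    }
    ann_recs <- lapply(seq_len(n_rec) - 1L, function(r) {
      keep <- annotations$onset >= r & annotations$onset < r + 1
      ev <- if (any(keep))
        paste0(vapply(which(keep), function(i)
          tal_one(annotations$onset[i], annotations$duration[i],
                  annotations$label[i]), ""), collapse = "") else ""
      paste0("+", r, "\x14\x14", ev)      # NUL terminator comes from padding
    })
    # annotations after the last record are appended to the final record
    late <- annotations$onset >= n_rec
    if (any(late)) {
      extra <- paste0(vapply(which(late), function(i)
        tal_one(annotations$onset[i], annotations$duration[i],
                annotations$label[i]), ""), collapse = "")
      ann_recs[[n_rec]] <- paste0(ann_recs[[n_rec]], extra)
    }
  }
  ann_ns <- if (is.null(ann_recs)) 0L else
    as.integer(ceiling((max(nchar(ann_recs, type = "bytes")) + 1L) / 2))

  labels <- names(channels)
  ns <- length(channels) + (ann_ns > 0L)
  hdr_bytes <- 256L + 256L * ns

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  wr(.pad("0", 8L)); wr(.pad(patient, 80L)); wr(.pad(recording, 80L))
  wr(.pad(start_date, 8L)); wr(.pad(start_time, 8L))
  wr(.pad(hdr_bytes, 8L))
  wr(.pad(if (ann_ns > 0L) "EDF+C" else "", 44L))
  wr(.pad(n_rec, 8L)); wr(.pad(1, 8L)); wr(.pad(ns, 4L))

  all_lab <- c(labels, if (ann_ns > 0L) "EDF Annotations")
  for (l in all_lab) wr(.pad(l, 16L))
  for (i in seq_len(ns)) wr(.pad("", 80L))                 # transducer
  wr(paste(vapply(seq_len(ns), function(i)
    .pad(if (i <= length(labels)) "uV" else "", 8L), ""), collapse = ""))
  for (i in seq_len(ns))                                    # phys min
    wr(.num8(if (i <= length(labels)) scale[[i]]$pmin else -1))
  for (i in seq_len(ns))                                    # phys max
    wr(.num8(if (i <= length(labels)) scale[[i]]$pmax else 1))
  for (i in seq_len(ns))                                    # dig min
    wr(.pad(if (i <= length(labels)) -32767L else -32768L, 8L))
  for (i in seq_len(ns))                                    # dig max
    wr(.pad(32767L, 8L))
  for (i in seq_len(ns)) wr(.pad("", 80L))                  # prefiltering
  for (i in seq_len(ns))                                    # samples/record
    wr(.pad(if (i <= length(labels)) fs[i] else ann_ns, 8L))
  for (i in seq_len(ns)) wr(.pad("", 32L))

  for (r in seq_len(n_rec)) {
    for (i in seq_along(dig)) {
      s <- dig[[i]][((r - 1L) * fs[i] + 1L):(r * fs[i])]
      writeBin(s, con, size = 2L, endian = "little")
    }
    if (ann_ns > 0L) {
      bytes <- charToRaw(ann_recs[[r]])
      writeBin(c(bytes, raw(2L * ann_ns - length(bytes))), con)
    }
  }
  invisible(path)
}

.read_edf_header <- function(con, path) {
  rd <- function(n) {
    s <- readChar(con, n, useBytes = TRUE)
    if (length(s) == 0L)
      .err(paste0("corrupt EDF header in ", path), "sleepfusion_bad_header")
    trimws(s)
  }
  version <- rd(8L)
  patient <- rd(80L); recording <- rd(80L)
  start_date <- rd(8L); start_time <- rd(8L)
  hdr_bytes <- suppressWarnings(as.integer(rd(8L)))
  reserved <- rd(44L)
  n_rec <- suppressWarnings(as.integer(rd(8L)))
  rec_dur <- suppressWarnings(as.numeric(rd(8L)))
  ns <- suppressWarnings(as.integer(rd(4L)))
  if (anyNA(c(hdr_bytes, n_rec, rec_dur, ns)) || ns < 1L)
    .err(paste0("corrupt EDF header in ", path), "sleepfusion_bad_header")
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16L); fld(80L); phys_dim <- fld(8L)
  pmin <- as.numeric(fld(8L)); pmax <- as.numeric(fld(8L))
  dmin <- as.numeric(fld(8L)); dmax <- as.numeric(fld(8L))
  fld(80L)
  spr <- as.integer(fld(8L)); fld(32L)
  if (anyNA(c(pmin, pmax, dmin, dmax, spr)))
    .err(paste0("corrupt EDF signal headers in ", path),
         "sleepfusion_bad_header")
  list(version = version, patient = patient, recording = recording,
       start_date = start_date, start_time = start_time,
       hdr_bytes = hdr_bytes, reserved = reserved, n_rec = n_rec,
       rec_dur = rec_dur, ns = ns, labels = labels, phys_dim = phys_dim,
       pmin = pmin, pmax = pmax, dmin = dmin, dmax = dmax, spr = spr)
}

#' Read channels from an EDF/EDF+ file
#'
#' Returns the requested channels in physical units with native sampling
#' rates preserved. Missing files, absent channels and corrupt headers each
#' raise a distinct condition class (`sleepfusion_missing_file`,
#' `sleepfusion_missing_channel`, `sleepfusion_bad_header`).
#'
#' @param path EDF/EDF+ file
#' @param channel_names channels to extract; `NULL` reads every ordinary
#'   signal (annotation channels are never returned as signals)
#' @return object of class `psg_recording`: list with `channels` (named list
#'   of numeric vectors), `fs` (named Hz vector), `start_date`, `start_time`,
#'   `duration` (s), and `phys_range` (per-channel c(min, max), used by the
#'   saturation-based bad-epoch rule)
#' @export
read_edf <- function(path, channel_names = NULL) {
  if (!file.exists(path))
    .err(paste0("EDF file not found: ", path), "sleepfusion_missing_file")
  con <- file(path, "rb")
  on.exit(close(con))
  h <- .read_edf_header(con, path)
  is_ann <- h$labels == "EDF Annotations"
  want <- if (is.null(channel_names)) h$labels[!is_ann] else channel_names
  missing <- setdiff(want, h$labels[!is_ann])
  if (length(missing) > 0L)
    .err(paste0("channel(s) absent from ", path, ": ",
                paste(missing, collapse = ", ")),
         "sleepfusion_missing_channel")
  idx <- match(want, h$labels)
  raw_sig <- lapply(seq_len(h$ns), function(i)
    if (i %in% idx) integer(h$n_rec * h$spr[i]) else NULL)
  for (r in seq_len(h$n_rec)) {
    for (i in seq_len(h$ns)) {
      v <- readBin(con, "integer", n = h$spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      if (i %in% idx)
        raw_sig[[i]][((r - 1L) * h$spr[i] + 1L):(r * h$spr[i])] <- v
    }
  }
  gain <- (h$pmax - h$pmin) / (h$dmax - h$dmin)
  channels <- stats::setNames(lapply(idx, function(i)
    h$pmin[i] + (raw_sig[[i]] - h$dmin[i]) * gain[i]), want)
  structure(list(channels = channels,
                 fs = stats::setNames(h$spr[idx] / h$rec_dur, want),
                 start_date = h$start_date, start_time = h$start_time,
                 duration = h$n_rec * h$rec_dur,
                 phys_range = stats::setNames(lapply(idx, function(i)
                   c(h$pmin[i], h$pmax[i])), want)),
            class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat("<psg_recording> ", length(x$channels), " channel(s), ",
      x$duration, " s\n", sep = "")
  for (nm in names(x$channels))
    cat("  ", nm, ": ", x$fs[[nm]], " Hz, ", length(x$channels[[nm]]),
        " samples\n", sep = "")
  invisible(x)
}

# Parse all TALs from an EDF+ annotations channel.
.read_edf_annotations <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- .read_edf_header(con, path)
  ia <- which(h$labels == "EDF Annotations")
  if (length(ia) == 0L)
    .err(paste0("no EDF Annotations channel in ", path),
         "sleepfusion_bad_header")
  out <- list()
  for (r in seq_len(h$n_rec)) {
    for (i in seq_len(h$ns)) {
      nb <- 2L * h$spr[i]
      bytes <- readBin(con, "raw", n = nb)
      if (!(i %in% ia)) next
      txt <- rawToChar(bytes[bytes != as.raw(0L)], multiple = FALSE)
      # each TAL is onset[\x15dur]\x14label\x14 ; the stream is a
      # concatenation, so split on "+"/"-" onset starts after a \x14
      for (tal in strsplit(txt, "(?<=\x14)(?=[+-])", perl = TRUE)[[1L]]) {
        parts <- strsplit(tal, "\x14", fixed = TRUE)[[1L]]
        if (length(parts) == 0L) next
        head_part <- strsplit(parts[1L], "\x15", fixed = TRUE)[[1L]]
        onset <- suppressWarnings(as.numeric(head_part[1L]))
        if (is.na(onset)) next
        dur <- if (length(head_part) > 1L)
          suppressWarnings(as.numeric(head_part[2L])) else NA_real_
        labs <- parts[-1L]
        labs <- labs[nzchar(labs)]
        for (lb in labs)
          out[[length(out) + 1L]] <- list(onset = onset, duration = dur,
                                          label = lb)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(onset = numeric(0), duration = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  data.frame(onset = vapply(out, `[[`, 0, "onset"),
             duration = vapply(out, `[[`, 0, "duration"),
             label = vapply(out, `[[`, "", "label"),
             stringsAsFactors = FALSE)
}

#' Write a hypnogram as an EDF+ annotation-only file
#'
#' @param path output path
#' @param events data.frame with onset (s), duration (s), label columns
#' @param total_duration recording length in seconds (defaults to the end of
#'   the last event)
#' @return `path`, invisibly
#' @export
write_hypnogram_edf <- function(path, events, total_duration = NULL) {
  if (is.null(total_duration))
    total_duration <- max(events$onset + events$duration)
  # a single dummy signal is required to have a valid record structure; a
  # 1 Hz zero channel keeps files tiny
  write_edf(path,
            channels = list(`Hypnogram marker` = numeric(total_duration)),
            fs = 1L, annotations = events)
}
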