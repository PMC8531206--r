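# EDF I/O, stage-label mapping, filtering, resampling, epoching.

test_that("EDF round-trips channels, rates and physical units", {
  set.seed(1)
  ch <- list(`EEG Fpz-Cz` = rnorm(1000) * 50, `EOG horizontal` = rnorm(500) * 100)
  p <- tempfile(fileext = ".edf")
  write_edf(p, ch, fs = c(100L, 50L))
  r <- read_edf(p)
  expect_named(r$channels, names(ch))
  expect_equal(unname(r$fs), c(100, 50))
  expect_equal(r$duration, 10)
  expect_equal(lengths(r$channels), c(`EEG Fpz-Cz` = 1000L,
                                      `EOG horizontal` = 500L))
  # 16-bit quantization error is bounded by one digital step
  step <- diff(range(ch[[1]])) / 65534
  expect_lt(max(abs(r$channels[[1]] - ch[[1]])), step)
})

test_that("EDF reader agrees with an independent reader (mne)", {
  set.seed(2)
  x <- rnorm(300) * 20
  p <- tempfile(fileext = ".edf")
  write_edf(p, list(`EEG Fpz-Cz` = x), fs = 100L)
  out <- tempfile(fileext = ".csv")
  script <- sprintf(
    "import mne, numpy as np\nr = mne.io.read_raw_edf('%s', verbose='ERROR')\nnp.savetxt('%s', r.get_data()[0] * 1e6)", p, out)
  sf <- tempfile(fileext = ".py"); writeLines(script, sf)
  status <- system2("python", sf, stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0L)
  ref <- scan(out, quiet = TRUE)
  mine <- read_edf(p)$channels[[1]]
  expect_gt(stats::cor(ref, mine), 0.999999)
})

test_that("reader raises distinct named failures", {
  expect_error(read_edf(tempfile()), class = "sleepfusion_missing_file")
  set.seed(3)
  p <- tempfile(fileext = ".edf")
  write_edf(p, list(A = rnorm(100)), fs = 100L)
  expect_error(read_recording(p, c("A", "EMG")),
               class = "sleepfusion_missing_channel")
  expect_error(read_recording(p, "EMG"), "EMG")
  bad <- tempfile(fileext = ".edf")
  writeBin(charToRaw("not an edf"), bad)
  expect_error(read_edf(bad), class = "sleepfusion_bad_header")
})

test_that("native sampling rates pass through the header", {
  p <- tempfile(fileext = ".edf")
  write_edf(p, list(FAST = sin(seq_len(2000))), fs = 1000L)
  expect_equal(unname(read_edf(p)$fs), 1000)
})

test_that("hypnogram reading sorts, de-overlaps and round-trips", {
  ev <- data.frame(onset = c(1800, 0), duration = c(900, 1800),
                   label = c("Sleep stage 1", "Sleep stage W"))
  p <- tempfile(fileext = ".edf")
  write_hypnogram_edf(p, ev)
  h <- read_hypnogram(p)
  expect_equal(h$onset, c(0, 1800))            # sorted by onset
  expect_equal(h$label, c("Sleep stage W", "Sleep stage 1"))
  expect_equal(h$duration, c(1800, 900))

  # plain-text events table, out of order in the file
  tf <- tempfile(fileext = ".csv")
  utils::write.csv(ev, tf, row.names = FALSE)
  h2 <- read_hypnogram(tf)
  expect_equal(h2$onset, c(0, 1800))

  # overlapping intervals: warning + keep-first
  ov <- data.frame(onset = c(0, 900), duration = c(1800, 900),
                   label = c("Sleep stage W", "Sleep stage 2"))
  tf2 <- tempfile(fileext = ".csv")
  utils::write.csv(ov, tf2, row.names = FALSE)
  expect_warning(h3 <- read_hypnogram(tf2), "overlap")
  expect_equal(nrow(h3), 1L)
  expect_equal(h3$label, "Sleep stage W")
})

test_that("empty annotation file yields an empty event list", {
  p <- tempfile(fileext = ".edf")
  write_edf(p, list(M = numeric(10)), fs = 1L,
            annotations = data.frame(onset = numeric(0),
                                     duration = numeric(0),
                                     label = character(0)))
  expect_equal(nrow(read_hypnogram(p)), 0L)
})

test_that("stage mapping merges R&K stages 3/4 and drops unscorable epochs", {
  expect_equal(map_stage_label("Sleep stage 3"), "N3")
  expect_equal(map_stage_label("Sleep stage 4"), "N3")
  expect_equal(map_stage_label("Sleep stage W"), "W")
  expect_equal(map_stage_label("Sleep stage R"), "REM")
  expect_true(is.na(map_stage_label("Sleep stage ?")))
  expect_true(is.na(map_stage_label("Movement time")))
  # total over the Sleep-EDF vocabulary
  vocab <- c("Sleep stage W", "Sleep stage 1", "Sleep stage 2",
             "Sleep stage 3", "Sleep stage 4", "Sleep stage R",
             "Sleep stage ?", "Movement time")
  expect_silent(map_stage_label(vocab))
  expect_error(map_stage_label("Sleep stage X"), "Sleep stage X",
               class = "sleepfusion_bad_label")
})

test_that("stage indices follow the scoring order W=1 REM=2 N1=3 N2=4 N3=5", {
  expect_equal(stage_index(c("W", "REM", "N1", "N2", "N3")), 1:5)
  expect_equal(stage_from_index(1:5), c("W", "REM", "N1", "N2", "N3"))
})

test_that("bandpass has the order-3 Butterworth response, applied zero-phase", {
  fs <- 100
  x10 <- tone(10, dur = 30, fs = fs)
  y10 <- bandpass(x10, fs, 0.5, 32)
  mid <- 500:2500
  # in-band tone passes nearly unattenuated (zero-phase => amplitude^2 of
  # the one-pass response, still >= 0.95 for 10 Hz in 0.5-32)
  expect_gt(max(abs(y10[mid])) / max(abs(x10[mid])), 0.95)
  expect_gt(stats::cor(y10[mid], x10[mid]), 0.999)

  # one octave above the 32 Hz edge: at least 15 dB down (order-3 slope)
  x64 <- tone(32 * 2, dur = 30, fs = 200)
  y64 <- bandpass(x64, 200, 0.5, 32)
  atten <- 20 * log10(max(abs(y64[mid])) / max(abs(x64[mid])))
  expect_lt(atten, -15)

  expect_equal(bandpass(numeric(3000), fs, 0.5, 32), numeric(3000))
  expect_error(bandpass(x10, fs, 32, 0.5), class = "sleepfusion_bad_band")
  expect_error(bandpass(x10, fs, 0.5, 60), class = "sleepfusion_bad_band")
})

test_that("resampling to 100 Hz preserves length contract and waveforms", {
  x <- tone(5, dur = 30, fs = 1000)
  y <- resample_to_100hz(x, 1000)
  expect_length(y, 3000L)
  ref <- tone(5, dur = 30, fs = 100)
  mid <- 200:2800
  expect_gt(stats::cor(y[mid], ref[mid]), 0.999)
  expect_identical(resample_to_100hz(x, 100), x)
  expect_error(resample_to_100hz(x, 50), class = "sleepfusion_bad_rate")
  # rational (non-integer) ratio
  y2 <- resample_to_100hz(tone(5, dur = 10, fs = 250), 250)
  expect_length(y2, 1000L)
})

test_that("filtering and resampling are deterministic", {
  x <- pink_noise(3000, seed = 9)
  expect_identical(bandpass(x, 100, 0.5, 32), bandpass(x, 100, 0.5, 32))
  expect_identical(resample_to_100hz(x, 150), resample_to_100hz(x, 150))
})

test_that("epoching is exhaustive, non-overlapping and drops unscored epochs", {
  rec <- structure(list(
    channels = list(EEG = pink_noise(60000, 11), EOG = pink_noise(60000, 12)),
    fs = c(EEG = 100, EOG = 100), start_date = "x", start_time = "y",
    duration = 600, phys_range = list(EEG = NULL, EOG = NULL)),
    class = "psg_recording")
  hyp <- data.frame(onset = 0, duration = 600, label = "Sleep stage W")
  eps <- make_epochs(rec, hyp, "EEG", "EOG")
  expect_length(eps, 20L)
  expect_true(all(vapply(eps, `[[`, "", "label") == "W"))
  expect_true(all(vapply(eps, function(e) length(e$eeg), 0L) == 3000L))

  # last 30 s unscorable -> 19 epochs
  hyp2 <- data.frame(onset = c(0, 570), duration = c(570, 30),
                     label = c("Sleep stage W", "Sleep stage ?"))
  expect_length(make_epochs(rec, hyp2, "EEG", "EOG"), 19L)

  # non-overlap: each sample is claimed by exactly one epoch
  idx <- unlist(lapply(make_epochs(rec, hyp, "EEG", "EOG"),
                       function(e) e$epoch_index))
  expect_equal(anyDuplicated(idx), 0L)
  expect_lte(length(idx) * 3000L, 60000L)

  # hypnogram overrunning the recording by > 1 epoch is an error
  hyp3 <- data.frame(onset = 0, duration = 700, label = "Sleep stage W")
  expect_error(make_epochs(rec, hyp3, "EEG", "EOG"),
               class = "sleepfusion_length_mismatch")
})

test_that("saturated and flatlined epochs are rejected", {
  eeg <- pink_noise(60000, 13)
  eeg[30001:33000] <- 200                       # 30 s pinned at phys max
  rec <- structure(list(
    channels = list(EEG = eeg, EOG = pink_noise(60000, 14)),
    fs = c(EEG = 100, EOG = 100), start_date = "x", start_time = "y",
    duration = 600, phys_range = list(EEG = c(-200, 200), EOG = NULL)),
    class = "psg_recording")
  hyp <- data.frame(onset = 0, duration = 600, label = "Sleep stage W")
  eps <- make_epochs(rec, hyp, "EEG", "EOG")
  expect_length(eps, 19L)                       # the saturated epoch is gone
  expect_false(11L %in% vapply(eps, `[[`, 0L, "epoch_index"))
})

test_that("epoch store round-trips signals and the stage-index label file", {
  eps <- tiny_epochs(6)
  d <- tempfile()
  write_epoch_store(eps, d)
  labs <- readLines(file.path(d, "T1_labels.txt"))
  expect_equal(labs, as.character(stage_index(vapply(eps, `[[`, "", "label"))))
  back <- read_epoch_store(d, "T1")
  expect_equal(back[[3]]$eeg, eps[[3]]$eeg)
  expect_equal(vapply(back, `[[`, "", "label"),
               vapply(eps, `[[`, "", "label"))
})
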