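# Synthetic polysomnography with stage-dependent spectral structure and
# realistic stage-transition dynamics, so the full pipeline is testable
# without real recordings.
#
# The generator encodes the textbook stage signatures: wake alpha (8-12 Hz)
# with blinks on the EOG; N1 low-amplitude theta with slow rolling eye
# movements; N2 theta with sleep spindles (12-14 Hz bursts) and K-complexes;
# N3 high-amplitude delta with a quiet EOG (plus low-frequency crosstalk
# from the strong delta); REM with wake-like low-amplitude mixed-frequency
# EEG -- deliberately sharing the N1 EEG mixture, the classic source of
# N1/REM confusability -- and bursts of rapid eye-movement deflections on
# the EOG. Disambiguating REM from N1 therefore requires the EOG channel,
# and N2 from N3 the EEG channel: exactly the structure that makes
# multimodal fusion pay off.

#' Stage signal models for the synthetic generator
#'
#' @param preset "sleep-edf-like" (default difficulty: N1 spectrally between
#'   W and N2, REM EEG identical in distribution to N1) or "easy" (every
#'   stage separable from either channel; for smoke tests)
#' @return named list (W, REM, N1, N2, N3) of per-stage EEG/EOG models
#' @export
stage_models <- function(preset = c("sleep-edf-like", "easy")) {
  preset <- match.arg(preset)
  osc <- function(f, bw, amp) list(f = f, bw = bw, amp = amp)
  if (preset == "sleep-edf-like") {
    list(
      W = list(eeg = list(bg = 12, osc = list(osc(10, 1.5, 20),
                                              osc(20, 3, 8))),
               eog = list(bg = 10, defl = list(n = 6, dur = 0.30, amp = 120))),
      REM = list(eeg = list(bg = 12, osc = list(osc(5.5, 1.5, 18),
                                                osc(10, 1, 5))),
                 eog = list(bg = 8, defl = list(n = 8, dur = 0.25, amp = 130))),
      N1 = list(eeg = list(bg = 12, osc = list(osc(5.5, 1.5, 18),
                                               osc(10, 1, 5))),
                eog = list(bg = 8, slow = osc(0.4, 0.15, 40))),
      N2 = list(eeg = list(bg = 12, osc = list(osc(5.5, 1.5, 12)),
                           spindle = list(n = 2, amp = 30),
                           kcomplex = list(n = 1, amp = 80)),
                eog = list(bg = 8)),
      N3 = list(eeg = list(bg = 15, osc = list(osc(1.2, 0.8, 70),
                                               osc(2.5, 1, 25))),
                eog = list(bg = 8, slow = osc(1.2, 0.4, 15)))
    )
  } else {
    list(
      W = list(eeg = list(bg = 10, osc = list(osc(10, 1, 30))),
               eog = list(bg = 8, defl = list(n = 8, dur = 0.30, amp = 150))),
      REM = list(eeg = list(bg = 10, osc = list(osc(3, 0.8, 20))),
                 eog = list(bg = 8, defl = list(n = 10, dur = 0.25,
                                                amp = 150))),
      N1 = list(eeg = list(bg = 10, osc = list(osc(5.5, 1, 25))),
                eog = list(bg = 8, slow = osc(0.4, 0.1, 50))),
      N2 = list(eeg = list(bg = 10, osc = list(osc(6, 1, 10)),
                           spindle = list(n = 4, amp = 50),
                           kcomplex = list(n = 2, amp = 100)),
                eog = list(bg = 8)),
      N3 = list(eeg = list(bg = 12, osc = list(osc(1.2, 0.6, 90))),
                eog = list(bg = 8, slow = osc(1.2, 0.3, 12)))
    )
  }
}

#' Stage-transition model with the Sleep-EDF class balance
#'
#' First-order Markov model whose stationary distribution equals the target
#' stage proportions: each epoch either stays in the current stage (prob.
#' 1 - leave) or draws a fresh stage from the stationary mix. A common leave
#' rate across stages makes the stationary distribution exactly the target
#' (mean dwell ~3.3 min at the default 0.15, plausible for human sleep).
#'
#' @param preset "sleep-edf-like" uses the healthy-sleeper stage proportions
#'   W 30.6%, REM 14.5%, N1 8.7%, N2 38.1%, N3 8.0%; "easy" is uniform
#' @param leave per-epoch probability of redrawing the stage
#' @return list with `P` (5x5 transition matrix, scoring order
#'   W,REM,N1,N2,N3), `init` (initial distribution)
#' @export
hypnogram_model <- function(preset = c("sleep-edf-like", "easy"),
                            leave = 0.2) {
  preset <- match.arg(preset)
  pi0 <- if (preset == "sleep-edf-like")
    c(W = 15257, REM = 7234, N1 = 4339, N2 = 19014, N3 = 4009) / 49853
  else stats::setNames(rep(0.2, 5), stage_levels())
  P <- (1 - leave) * diag(5) + leave * matrix(pi0, 5, 5, byrow = TRUE)
  dimnames(P) <- list(stage_levels(), stage_levels())
  list(P = P, init = pi0)
}

#' Sample a hypnogram from a stage-transition model
#'
#' @param model list with `P` (rows sum to 1) and `init`, as from
#'   [hypnogram_model()]
#' @param n_epochs number of 30 s epochs (>= 1)
#' @param seed integer; the draw is deterministic per seed
#' @param require_all_stages redraw the night (up to 200 times) until every
#'   stage occurs at least once, mirroring the fact that whole-night
#'   recordings of healthy sleepers contain all five stages (and making
#'   even short synthetic corpora trainable). Defaults to TRUE for nights
#'   of 25 epochs or more.
#' @return character vector of stage labels
#' @export
sample_hypnogram <- function(model, n_epochs, seed = NULL,
                             require_all_stages = n_epochs >= 25L) {
  P <- model$P
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
    .err("transition rows must be nonnegative and sum to 1",
         "sleepfusion_bad_model")
  stopifnot(n_epochs >= 1L)
  with_seed(seed, {
    for (try in seq_len(if (require_all_stages) 200L else 1L)) {
      s <- integer(n_epochs)
      s[1L] <- sample.int(5L, 1L, prob = model$init)
      if (n_epochs > 1L)
        for (i in 2L:n_epochs)
          s[i] <- sample.int(5L, 1L, prob = P[s[i - 1L], ])
      if (!require_all_stages || length(unique(s)) == 5L) break
    }
    stage_levels()[s]
  })
}

# --- signal building blocks ------------------------------------------------

# 1/f^chi background noise via spectral shaping, unit scale ~ sd
.one_over_f <- function(n, scale, chi = 1) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1L))
  f <- pmin(f, n - f + 1)         # symmetric frequency index
  H <- 1 / f^(chi / 2)
  x <- Re(stats::fft(W * H, inverse = TRUE) / n)
  scale * x / stats::sd(x)
}

# amplitude-modulated band-limited oscillation
.osc_wave <- function(n, fs, f, bw, amp) {
  tt <- (seq_len(n) - 1L) / fs
  f0 <- stats::runif(1L, f - bw / 2, f + bw / 2)
  am <- 1 + 0.3 * sin(2 * pi * stats::runif(1L, 0.05, 0.12) * tt +
                        stats::runif(1L, 0, 2 * pi))
  amp / sqrt(2) * am * sin(2 * pi * f0 * tt + stats::runif(1L, 0, 2 * pi))
}

# Hann-windowed sinusoidal burst (sleep spindle, 12-14 Hz)
.spindle <- function(n, fs, amp) {
  len <- round(stats::runif(1L, 0.8, 1.2) * fs)
  at <- sample.int(n - len, 1L)
  f0 <- stats::runif(1L, 12, 14)
  tt <- (seq_len(len) - 1L) / fs
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(len) / (len + 1L))
  out <- numeric(n)
  out[at:(at + len - 1L)] <- amp * w * sin(2 * pi * f0 * tt)
  out
}

# biphasic transient: derivative-of-Gaussian pulse of width `dur` seconds
.biphasic <- function(n, fs, dur, amp, at = NULL) {
  len <- round(dur * fs)
  if (is.null(at)) at <- sample.int(n - len, 1L)
  u <- seq(-2.5, 2.5, length.out = len)
  pulse <- -u * exp(-u^2 / 2)
  pulse <- amp * pulse / max(abs(pulse))
  out <- numeric(n)
  out[at:(at + len - 1L)] <- pulse
  out
}

#' Synthesize one 30 s epoch of EEG and EOG for a stage
#'
#' EEG = 1/f background + stage oscillation mixture + stage transients
#' (spindles/K-complexes for N2). EOG = stage-specific eye-movement process
#' (blinks in W, slow rolling movements in N1, rapid deflections in REM,
#' low-frequency crosstalk in N3) over a 1/f background. Reproducible per
#' seed; a zero-amplitude model yields all-zero signals.
#'
#' @param stage one of "W","REM","N1","N2","N3"
#' @param model stage models from [stage_models()]
#' @param fs sampling rate (default 100 Hz)
#' @param seed optional integer for a deterministic draw
#' @return list with `eeg` and `eog`, each `30 * fs` samples (uV)
#' @export
synth_epoch <- function(stage, model = stage_models(), fs = 100,
                        seed = NULL) {
  stopifnot(stage %in% stage_levels())
  m <- model[[stage]]
  n <- 30L * fs
  with_seed(seed, {
    eeg <- if (m$eeg$bg > 0) .one_over_f(n, m$eeg$bg) else numeric(n)
    for (o in m$eeg$osc)
      if (o$amp > 0) eeg <- eeg + .osc_wave(n, fs, o$f, o$bw, o$amp)
    if (!is.null(m$eeg$spindle) && m$eeg$spindle$amp > 0)
      for (k in seq_len(m$eeg$spindle$n))
        eeg <- eeg + .spindle(n, fs, m$eeg$spindle$amp)
    if (!is.null(m$eeg$kcomplex) && m$eeg$kcomplex$amp > 0)
      for (k in seq_len(m$eeg$kcomplex$n))
        eeg <- eeg + .biphasic(n, fs, 0.8, m$eeg$kcomplex$amp)
    eog <- if (m$eog$bg > 0) .one_over_f(n, m$eog$bg) else numeric(n)
    if (!is.null(m$eog$slow) && m$eog$slow$amp > 0)
      eog <- eog + .osc_wave(n, fs, m$eog$slow$f, m$eog$slow$bw,
                             m$eog$slow$amp)
    if (!is.null(m$eog$defl) && m$eog$defl$amp > 0) {
      k <- stats::rpois(1L, m$eog$defl$n)
      k <- max(k, max(1L, m$eog$defl$n - 2L))   # keep the event train dense
      for (i in seq_len(k))
        eog <- eog + .biphasic(n, fs, m$eog$defl$dur, m$eog$defl$amp *
                                 stats::runif(1L, 0.8, 1.2))
    }
    list(eeg = eeg, eog = eog)
  })
}

#' Count rapid eye-movement deflections in an EOG epoch
#'
#' Detector used for generator diagnostics and tests: band-pass 1.5-10 Hz
#' (isolates fast deflections from slow rolling movements and drift), then
#' counts excursions above 3 robust standard deviations (1.4826 * MAD) with
#' at least 0.3 s separation.
#'
#' @param eog numeric EOG epoch
#' @param fs sampling rate (Hz)
#' @return integer count
#' @export
count_eog_deflections <- function(eog, fs = 100) {
  y <- bandpass(eog, fs, 1.5, 10)
  thr <- 3 * 1.4826 * stats::mad(y, center = 0)
  if (thr <= 0) return(0L)
  above <- abs(y) > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hits <- starts[r$values]
  if (length(hits) == 0L) return(0L)
  count <- 1L
  last <- hits[1L]
  for (h in hits[-1L]) {
    if (h - last > 0.3 * fs) { count <- count + 1L; last <- h }
  }
  count
}

#' Band-power summary of one epoch (naive staging features)
#'
#' Log power of the EEG in the delta (0.5-4), theta (4-8), alpha (8-12) and
#' sigma (12-16 Hz) bands, total EOG power, EOG power below 1 Hz, and the
#' rapid-deflection count. A linear classifier on these features is the
#' baseline that checks the generator carries recoverable stage signal.
#'
#' @param epoch a `sleep_epoch` or list with `eeg`, `eog`
#' @param fs sampling rate
#' @return named numeric vector of 7 features
#' @export
band_power_features <- function(epoch, fs = 100) {
  pw <- function(x, lo, hi) {
    n <- length(x)
    X <- Mod(stats::fft(x))^2 / n
    f <- (seq_len(n) - 1L) / n * fs
    sum(X[f >= lo & f < hi])
  }
  e <- epoch$eeg; o <- epoch$eog
  c(delta = log1p(pw(e, 0.5, 4)), theta = log1p(pw(e, 4, 8)),
    alpha = log1p(pw(e, 8, 12)), sigma = log1p(pw(e, 12, 16)),
    eog_total = log1p(pw(o, 0.5, 10)), eog_slow = log1p(pw(o, 0.1, 1)),
    eog_defl = count_eog_deflections(o, fs))
}

#' Generate a synthetic multi-subject PSG dataset
#'
#' Per subject: a Markov hypnogram, one synthetic epoch per scored interval,
#' and (optionally) an EDF signal file plus an EDF+ hypnogram file that
#' round-trip through the package's readers up to 16-bit quantization.
#'
#' @param n_subjects,epochs_per_subject dataset size (each >= 1)
#' @param preset generator preset, see [stage_models()]
#' @param seed master seed; subject and epoch seeds derive from it
#' @param dir if non-NULL, EDF + hypnogram files are written here
#' @return list with `subjects` (each: subject_id, labels, epochs, and when
#'   written, psg_path / hyp_path), `preset`, `seed`
#' @export
generate_dataset <- function(n_subjects, epochs_per_subject,
                             preset = "sleep-edf-like", seed = 1L,
                             dir = NULL) {
  stopifnot(n_subjects >= 1L, epochs_per_subject >= 1L)
  sm <- stage_models(preset)
  hm <- hypnogram_model(preset)
  subj_seeds <- with_seed(seed, sample.int(2^30, n_subjects * 2L))
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subjects <- lapply(seq_len(n_subjects), function(s) {
    sid <- sprintf("SYN%02d", s)
    labels <- sample_hypnogram(hm, epochs_per_subject, subj_seeds[2L * s - 1L])
    ep_seeds <- with_seed(subj_seeds[2L * s],
                          sample.int(2^30, epochs_per_subject))
    epochs <- lapply(seq_len(epochs_per_subject), function(i) {
      sig <- synth_epoch(labels[i], sm, seed = ep_seeds[i])
      structure(list(eeg = sig$eeg, eog = sig$eog, label = labels[i],
                     subject_id = sid, epoch_index = i),
                class = "sleep_epoch")
    })
    out <- list(subject_id = sid, labels = labels, epochs = epochs)
    if (!is.null(dir)) {
      eeg <- unlist(lapply(epochs, `[[`, "eeg"))
      eog <- unlist(lapply(epochs, `[[`, "eog"))
      psg <- file.path(dir, paste0(sid, "-PSG.edf"))
      hyp <- file.path(dir, paste0(sid, "-Hypnogram.edf"))
      write_edf(psg, list(`EEG Fpz-Cz` = eeg, `EOG horizontal` = eog),
                fs = 100L)
      raw_lab <- c("W" = "Sleep stage W", "REM" = "Sleep stage R",
                   "N1" = "Sleep stage 1", "N2" = "Sleep stage 2",
                   "N3" = "Sleep stage 3")[labels]
      r <- rle(unname(raw_lab))
      ends <- cumsum(r$lengths)
      write_hypnogram_edf(hyp, data.frame(
        onset = 30 * (ends - r$lengths), duration = 30 * r$lengths,
        label = r$values, stringsAsFactors = FALSE),
        total_duration = 30 * epochs_per_subject)
      out$psg_path <- psg
      out$hyp_path <- hyp
    }
    out
  })
  list(subjects = subjects, preset = preset, seed = seed)
}
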