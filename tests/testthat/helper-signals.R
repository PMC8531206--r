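# Shared fixtures: analytic test signals and the external reference EMD.

tone <- function(f, dur = 30, fs = 100, amp = 1, phase = 0) {
  amp * sin(2 * pi * f * (seq_len(dur * fs) - 1) / fs + phase)
}

cos_tone <- function(f, dur = 30, fs = 100, amp = 1) {
  amp * cos(2 * pi * f * (seq_len(dur * fs) - 1) / fs)
}

# linear chirp f0 -> f1 over dur seconds
chirp <- function(f0, f1, dur = 30, fs = 100) {
  tt <- (seq_len(dur * fs) - 1) / fs
  cos(2 * pi * (f0 * tt + (f1 - f0) / (2 * dur) * tt^2))
}

# 1/f noise without touching the global RNG state of the caller
pink_noise <- function(n, seed) {
  set.seed(seed)
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)
  x <- Re(stats::fft(W / sqrt(f), inverse = TRUE) / n)
  x / stats::sd(x)
}

# Reference EMD: the independent NumPy/SciPy implementation shipped under
# inst/oracle, run through the system python. Returns a matrix with one
# column per IMF (zero columns when none).
ref_emd <- function(x) {
  script <- system.file("oracle", "ref_emd.py", package = "sleepfusion")
  fin <- tempfile(fileext = ".csv")
  fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)))
  write(x, fin, ncolumns = 1)
  status <- system2("python", c(script, fin, fout), stdout = FALSE,
                    stderr = FALSE)
  stopifnot(status == 0)
  if (file.size(fout) == 0) return(matrix(0, length(x), 0))
  as.matrix(utils::read.csv(fout, header = FALSE))
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / max(sum(b^2), 1e-300))

# tiny deterministic epoch list for plumbing tests
tiny_epochs <- function(n = 10, seed = 42) {
  sm <- stage_models("easy")
  labels <- rep(stage_levels(), length.out = n)
  lapply(seq_len(n), function(i) {
    sig <- synth_epoch(labels[i], sm, seed = seed + i)
    structure(list(eeg = sig$eeg, eog = sig$eog, label = labels[i],
                   subject_id = "T1", epoch_index = i),
              class = "sleep_epoch")
  })
}
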