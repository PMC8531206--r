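# Adaptive time-frequency analysis: empirical mode decomposition (EMD),
# Hilbert spectral analysis, and assembly of the network input tensors.

#' One sifting step of empirical mode decomposition
#'
#' Subtracts the mean of the upper and lower cubic-spline envelopes (through
#' the local maxima / minima, with two extrema mirrored across each boundary)
#' from the signal. This is the elementary operation EMD iterates to isolate
#' an intrinsic mode function.
#'
#' @param signal numeric vector with at least 4 extrema
#' @return list with `candidate` (signal minus mean envelope) and
#'   `mean_envelope`, or `NULL` when the signal has fewer than 4 extrema,
#'   which signals termination of the decomposition (not an error).
#' @export
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' s <- sift_once(sin(2 * pi * 5 * t))
#' str(s)
sift_once <- function(signal) {
  x <- as.numeric(signal)
  em <- .env_mean_cpp(x)
  if (!em$ok) return(NULL)
  list(candidate = x - em$mean, mean_envelope = em$mean)
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by iterated
#' sifting. Each sift subtracts the mean spline envelope; sifting of one mode
#' stops once the Cauchy standard-deviation criterion
#' \eqn{\sum (h_{k-1}-h_k)^2 / \sum h_{k-1}^2} drops below `sd_threshold`
#' AND the candidate satisfies the defining IMF property (extrema and
#' zero-crossing counts within one of each other), or after `max_sift`
#' iterations. The whole decomposition stops at `max_imfs`, when the
#' residual has too few extrema to sift, or when the residual energy is
#' numerically negligible (relative 1e-12).
#'
#' The IMFs plus the residual reconstruct the input exactly by construction
#' (the residual is defined as input minus the accepted IMFs).
#'
#' @param signal finite numeric vector, length >= 64
#' @param max_imfs maximum number of IMFs to extract
#' @param sd_threshold Cauchy sifting-stop threshold (classical value 0.2)
#' @param max_sift cap on sifting iterations per IMF
#' @return object of class `imf_set`: list with `imfs` (list of numeric
#'   vectors), `residual`, and `n` (signal length)
#' @export
#' @examples
#' t <- seq(0, 2, by = 0.01)
#' dec <- emd(sin(2 * pi * 12 * t) + sin(2 * pi * 2 * t))
#' length(dec$imfs)
emd <- function(signal, max_imfs = 10L, sd_threshold = 0.2, max_sift = 50L) {
  x <- as.numeric(signal)
  if (length(x) < 64L) stop("emd: signal must have length >= 64")
  if (!all(is.finite(x))) stop("emd: signal contains NaN/Inf")
  e0 <- sum(x^2)
  res <- x
  imfs <- list()
  while (length(imfs) < max_imfs) {
    if (e0 > 0 && sum(res^2) < 1e-12 * e0) break   # residual numerically zero
    h <- res
    em <- .env_mean_cpp(h)
    if (!isTRUE(em$ok)) break
    for (it in seq_len(max_sift)) {
      h1 <- h - em$mean
      sdc <- sum(em$mean^2) / max(sum(h^2), .Machine$double.xmin)
      h <- h1
      em <- .env_mean_cpp(h)
      if (!isTRUE(em$ok)) break
      cz <- .extrema_zc_cpp(h)
      if (sdc < sd_threshold && abs(cz[1L] - cz[2L]) <= 1L) break
    }
    imfs[[length(imfs) + 1L]] <- h
    res <- res - h
  }
  structure(list(imfs = imfs, residual = res, n = length(x)),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat("<imf_set> ", length(x$imfs), " IMF(s), signal length ", x$n, "\n",
      sep = "")
  invisible(x)
}

#' Analytic signal: instantaneous amplitude and frequency of one IMF
#'
#' Computes the analytic extension by the FFT method (negative frequencies
#' zeroed, positive doubled). The instantaneous frequency is the centred
#' difference of the unwrapped phase, smoothed with a 5-point moving average,
#' scaled to Hz and clipped to \[0, fs/2\].
#'
#' @param imf zero-mean oscillatory numeric vector, length >= 8
#' @param fs sampling rate in Hz
#' @return list with `amplitude` and `inst_freq` (Hz), both the length of
#'   the input
#' @export
#' @examples
#' t <- seq(0, 1 - 0.01, by = 0.01)
#' a <- analytic_signal(cos(2 * pi * 10 * t), fs = 100)
#' stats::median(a$inst_freq)
analytic_signal <- function(imf, fs) {
  x <- as.numeric(imf)
  n <- length(x)
  if (n < 8L) stop("analytic_signal: input length must be >= 8")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1L) / 2L)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  amp <- Mod(z)
  ph <- Arg(z)
  # unwrap phase
  d <- diff(ph)
  d <- d - 2 * pi * round(d / (2 * pi))
  phu <- cumsum(c(ph[1L], d))
  # centred difference, one-sided at the ends
  dph <- c(phu[2L] - phu[1L],
           (phu[3:n] - phu[1:(n - 2L)]) / 2,
           phu[n] - phu[n - 1L])
  # 5-point moving average (shrinking window at the edges)
  k <- stats::filter(dph, rep(1 / 5, 5), sides = 2)
  k <- as.numeric(k)
  edge <- which(is.na(k))
  for (i in edge) {
    lo <- max(1L, i - 2L); hi <- min(n, i + 2L)
    k[i] <- mean(dph[lo:hi])
  }
  f <- k * fs / (2 * pi)
  f <- pmin(pmax(f, 0), fs / 2)
  list(amplitude = amp, inst_freq = f)
}

#' Hilbert spectrum: binned time-frequency energy of an IMF set
#'
#' Accumulates the squared instantaneous amplitude of every sample of every
#' IMF into the (frequency, time) bin containing it. Bin edges are linear on
#' \[f_min, f_max\] and \[0, duration\]; samples whose instantaneous frequency
#' falls outside the frequency range are dropped. Total grid energy therefore
#' equals the sum of squared amplitudes of all in-range samples exactly.
#'
#' @param imfset an `imf_set` from [emd()]
#' @param fs sampling rate (Hz)
#' @param n_freq_bins,n_time_bins grid size (each >= 1)
#' @param f_max upper frequency edge (<= fs/2)
#' @param f_min lower frequency edge (default 0)
#' @return object of class `hilbert_spectrum`: list with `energy`
#'   (n_freq_bins x n_time_bins, frequency rows ascending), `freq_edges`,
#'   `time_edges`
#' @export
hilbert_spectrum <- function(imfset, fs, n_freq_bins, n_time_bins, f_max,
                             f_min = 0) {
  stopifnot(inherits(imfset, "imf_set"), n_freq_bins >= 1L, n_time_bins >= 1L,
            f_max <= fs / 2, f_min < f_max)
  n <- imfset$n
  dur <- n / fs
  fe <- seq(f_min, f_max, length.out = n_freq_bins + 1L)
  te <- seq(0, dur, length.out = n_time_bins + 1L)
  energy <- matrix(0, n_freq_bins, n_time_bins)
  tt <- (seq_len(n) - 0.5) / fs
  ti <- findInterval(tt, te, rightmost.closed = TRUE)
  ti <- pmin(pmax(ti, 1L), n_time_bins)
  for (imf in imfset$imfs) {
    a <- analytic_signal(imf, fs)
    fi <- findInterval(a$inst_freq, fe, rightmost.closed = TRUE)
    keep <- fi >= 1L & fi <= n_freq_bins
    if (!any(keep)) next
    idx <- fi[keep] + (ti[keep] - 1L) * n_freq_bins
    add <- rowsum(a$amplitude[keep]^2, idx)
    energy[as.integer(rownames(add))] <- energy[as.integer(rownames(add))] +
      add[, 1L]
  }
  structure(list(energy = energy, freq_edges = fe, time_edges = te),
            class = "hilbert_spectrum")
}

#' @export
print.hilbert_spectrum <- function(x, ...) {
  cat("<hilbert_spectrum> ", nrow(x$energy), "x", ncol(x$energy),
      " bins, f in [", x$freq_edges[1L], ", ",
      x$freq_edges[length(x$freq_edges)], "] Hz, total energy ",
      format(sum(x$energy), digits = 4), "\n", sep = "")
  invisible(x)
}

# log(1+x) then min-max to [0,1] over the whole object; all-constant input
# maps to zeros.
.scale_feature <- function(x) {
  y <- log1p(x)
  r <- range(y)
  if (r[2L] > r[1L]) (y - r[1L]) / (r[2L] - r[1L]) else y * 0
}

#' EEG feature tensor: six 5 s Hilbert spectra of a 30 s epoch
#'
#' Splits a 3000-sample (30 s at 100 Hz) EEG epoch into six consecutive 5 s
#' sub-segments, runs EMD and Hilbert spectral analysis on each (30 frequency
#' bins over 0.5-32 Hz, the EEG preprocessing passband, and 30 time bins),
#' and stacks the six spectra in temporal order. With `normalize = "epoch"`
#' the stacked tensor is log(1+x) scaled then min-max normalised to \[0,1\]
#' over the whole epoch, so network inputs are bounded.
#'
#' @param eeg_epoch numeric vector of exactly 3000 samples
#' @param fs sampling rate, 100 Hz
#' @param normalize "epoch" (default) or "none"
#' @return 6 x 30 x 30 array (sub-segment x frequency x time)
#' @export
eeg_feature_tensor <- function(eeg_epoch, fs = 100, normalize = "epoch") {
  x <- as.numeric(eeg_epoch)
  if (length(x) != 3000L)
    stop("eeg_feature_tensor: epoch must have exactly 3000 samples")
  out <- array(0, c(6L, 30L, 30L))
  for (s in 1:6) {
    seg <- x[((s - 1L) * 500L + 1L):(s * 500L)]
    if (all(seg == 0)) next
    hs <- hilbert_spectrum(emd(seg), fs = fs, n_freq_bins = 30L,
                           n_time_bins = 30L, f_max = 32, f_min = 0.5)
    out[s, , ] <- hs$energy
  }
  if (identical(normalize, "epoch")) out <- .scale_feature(out)
  out
}

#' EOG feature matrix: whole-epoch Hilbert spectrum as a time sequence
#'
#' Transforms the full 30 s EOG epoch in one pass (EMD + Hilbert spectrum,
#' 30 frequency bins over 0.5-10 Hz, the EOG passband, and 30 one-second time
#' bins) and returns it time-major: rows are the 30 time steps the recurrent
#' subnetwork consumes, columns the 30 frequency bins.
#'
#' @inheritParams eeg_feature_tensor
#' @param eog_epoch numeric vector of exactly 3000 samples
#' @return 30 x 30 matrix (time step x frequency bin)
#' @export
eog_feature_matrix <- function(eog_epoch, fs = 100, normalize = "epoch") {
  x <- as.numeric(eog_epoch)
  if (length(x) != 3000L)
    stop("eog_feature_matrix: epoch must have exactly 3000 samples")
  if (all(x == 0)) return(matrix(0, 30L, 30L))
  hs <- hilbert_spectrum(emd(x), fs = fs, n_freq_bins = 30L,
                         n_time_bins = 30L, f_max = 10, f_min = 0.5)
  out <- t(hs$energy)
  if (identical(normalize, "epoch")) out <- .scale_feature(out)
  out
}

#' Paired network inputs for one epoch
#'
#' Builds the EEG tensor and EOG matrix for a single 30 s epoch, using either
#' the adaptive Hilbert-Huang features or the fixed-basis Morlet wavelet
#' baseline (same grid geometry, so the two are interchangeable network
#' inputs for feature-swap comparisons).
#'
#' @param epoch a `sleep_epoch` (list with `eeg` and `eog`) or a list with
#'   those two fields
#' @param method "hht" (default) or "cwt"
#' @param normalize "epoch" or "none"
#' @return object of class `feature_pair`: list with `eeg_tensor`
#'   (6 x 30 x 30) and `eog_matrix` (30 x 30)
#' @export
feature_pair <- function(epoch, method = c("hht", "cwt"),
                         normalize = "epoch") {
  method <- match.arg(method)
  if (method == "hht") {
    eegt <- eeg_feature_tensor(epoch$eeg, normalize = normalize)
    eogm <- eog_feature_matrix(epoch$eog, normalize = normalize)
  } else {
    eegt <- array(0, c(6L, 30L, 30L))
    for (s in 1:6) {
      seg <- epoch$eeg[((s - 1L) * 500L + 1L):(s * 500L)]
      eegt[s, , ] <- cwt_feature(seg, 30L, 30L, 0.5, 32, fs = 100)
    }
    eogm <- t(cwt_feature(epoch$eog, 30L, 30L, 0.5, 10, fs = 100))
    if (identical(normalize, "epoch")) {
      eegt <- .scale_feature(eegt)
      eogm <- .scale_feature(eogm)
    }
  }
  structure(list(eeg_tensor = eegt, eog_matrix = eogm),
            class = "feature_pair")
}

#' @export
print.feature_pair <- function(x, ...) {
  cat("<feature_pair> eeg 6x30x30, eog 30x30, ranges [",
      format(min(x$eeg_tensor), digits = 3), ", ",
      format(max(x$eeg_tensor), digits = 3), "] / [",
      format(min(x$eog_matrix), digits = 3), ", ",
      format(max(x$eog_matrix), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Morlet wavelet scalogram on the HHT grid geometry
#'
#' Continuous wavelet transform baseline: complex Morlet power (6 cycles) at
#' the centre frequency of each requested bin, averaged into the requested
#' time bins, so the output is directly interchangeable with a Hilbert
#' spectrum of the same geometry.
#'
#' @param epoch numeric signal (any length >= 8)
#' @param n_freq_bins,n_time_bins output grid size
#' @param f_lo,f_hi frequency band edges in Hz (0 < f_lo < f_hi <= fs/2)
#' @param fs sampling rate (Hz)
#' @param n_cycles Morlet width in cycles
#' @return n_freq_bins x n_time_bins matrix of nonnegative power
#' @export
cwt_feature <- function(epoch, n_freq_bins, n_time_bins, f_lo, f_hi,
                        fs = 100, n_cycles = 6) {
  x <- as.numeric(epoch)
  n <- length(x)
  if (n < 8L) stop("cwt_feature: signal too short")
  if (!(f_lo > 0 && f_lo < f_hi && f_hi <= fs / 2))
    stop("cwt_feature: invalid frequency band")
  fe <- seq(f_lo, f_hi, length.out = n_freq_bins + 1L)
  fc <- (fe[-1L] + fe[-length(fe)]) / 2
  te <- seq(0, n / fs, length.out = n_time_bins + 1L)
  ti <- findInterval((seq_len(n) - 0.5) / fs, te, rightmost.closed = TRUE)
  ti <- pmin(pmax(ti, 1L), n_time_bins)
  nfft <- 2L^ceiling(log2(2L * n))
  X <- stats::fft(c(x, numeric(nfft - n)))
  freqs <- (seq_len(nfft) - 1L) / nfft * fs
  out <- matrix(0, n_freq_bins, n_time_bins)
  cnt <- tabulate(ti, n_time_bins)
  for (k in seq_along(fc)) {
    sigma_t <- n_cycles / (2 * pi * fc[k])
    # frequency response of the (analytic) Morlet atom
    H <- 2 * exp(-2 * pi^2 * sigma_t^2 * (freqs - fc[k])^2)
    H[freqs > fs / 2] <- 0
    w <- stats::fft(X * H, inverse = TRUE)[seq_len(n)] / nfft
    p <- rowsum(Mod(w)^2, ti)
    out[k, as.integer(rownames(p))] <- p[, 1L] / pmax(cnt[as.integer(rownames(p))], 1L)
  }
  out
}
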