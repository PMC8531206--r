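# Empirical mode decomposition, Hilbert spectral analysis, feature tensors.

test_that("a pure tone is its own intrinsic mode", {
  x <- tone(5)
  s <- sift_once(x)
  expect_gt(stats::cor(s$candidate, x), 0.999)
  d <- emd(x)
  expect_gte(length(d$imfs), 1L)
  expect_lt(sum(d$residual^2) / sum(x^2), 0.01)
  expect_gt(abs(stats::cor(d$imfs[[1]], x)), 0.999)
})

test_that("sifting terminates on monotone input and emd handles degenerate cases", {
  expect_null(sift_once(seq_len(3000)))
  d <- emd(rep(1, 3000))
  expect_length(d$imfs, 0L)
  expect_equal(d$residual, rep(1, 3000))
  expect_error(emd(c(rep(0, 100), NaN)), "NaN")
  expect_error(emd(numeric(10)), "length")
})

test_that("one sift isolates the fast component of a two-tone mixture", {
  tt <- (seq_len(3000) - 1) / 100
  x <- sin(2 * pi * 2 * tt) + 0.5 * sin(2 * pi * 20 * tt)
  s <- sift_once(x)
  spec <- Mod(stats::fft(s$candidate))[1:1500]
  f <- (0:1499) / 30
  expect_equal(round(f[which.max(spec)]), 20)
})

test_that("emd separates well-spaced tones into leading IMFs", {
  tt <- (seq_len(3000) - 1) / 100
  x <- sin(2 * pi * 12 * tt) + sin(2 * pi * 2 * tt)
  d <- emd(x)
  expect_gte(length(d$imfs), 2L)
  expect_gt(abs(stats::cor(d$imfs[[1]], sin(2 * pi * 12 * tt))), 0.95)
  expect_gt(abs(stats::cor(d$imfs[[2]], sin(2 * pi * 2 * tt))), 0.95)
})

test_that("IMFs satisfy the extrema/zero-crossing defining property", {
  for (seed in 1:5) {
    x <- pink_noise(1000, seed)
    d <- emd(x)
    for (imf in d$imfs[seq_len(min(3, length(d$imfs)))]) {
      cz <- sleepfusion:::.extrema_zc_cpp(imf)
      expect_lte(abs(cz[1] - cz[2]), 1L + 2L)   # boundary tolerance 2
    }
  }
})

test_that("decomposition reconstructs the input to numerical precision", {
  for (seed in 1:20) {
    x <- pink_noise(500, seed)
    d <- emd(x)
    rec <- Reduce(`+`, d$imfs, d$residual)
    expect_lt(rel_l2(rec, x), 1e-9)
  }
})

test_that("decomposition agrees with the independent reference implementation", {
  set.seed(77)
  for (i in 1:5) {
    tt <- (seq_len(1000) - 1) / 100
    f1 <- stats::runif(1, 8, 15); f2 <- stats::runif(1, 1, 3)
    x <- stats::runif(1, .5, 2) * sin(2 * pi * f1 * tt + stats::runif(1, 0, 6)) +
      stats::runif(1, .5, 2) * sin(2 * pi * f2 * tt + stats::runif(1, 0, 6))
    ref <- ref_emd(x)
    mine <- emd(x)
    m <- min(ncol(ref), length(mine$imfs), 2L)
    expect_gte(m, 2L)
    for (k in seq_len(m))
      expect_gt(abs(stats::cor(mine$imfs[[k]], ref[, k])), 0.9)
  }
})

test_that("analytic signal recovers amplitude and instantaneous frequency", {
  x <- cos_tone(10)
  a <- analytic_signal(x, 100)
  inner <- 150:2850                      # away from boundary transients
  expect_lt(max(abs(a$amplitude[inner] - 1)), 0.02)
  expect_lt(abs(stats::median(a$inst_freq) - 10) / 10, 0.01)

  half <- analytic_signal(0.5 * cos_tone(3), 100)
  expect_lt(max(abs(half$amplitude[inner] - 0.5)), 0.01)

  expect_error(analytic_signal(numeric(4), 100), "length")
})

test_that("instantaneous frequency tracks a linear chirp", {
  x <- chirp(1, 15, dur = 30)
  a <- analytic_signal(x, 100)
  tt <- (seq_len(3000) - 1) / 100
  ctr <- round(0.1 * 3000):round(0.9 * 3000)
  fit <- stats::lm(a$inst_freq[ctr] ~ tt[ctr])
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("hilbert spectrum concentrates a tone and conserves energy", {
  d <- emd(tone(10))
  hs <- hilbert_spectrum(d, 100, 30, 30, f_max = 32)
  rowpow <- rowSums(hs$energy)
  peak_bin <- findInterval(10, hs$freq_edges)
  expect_gt(rowpow[peak_bin] / sum(rowpow), 0.90)
  # conservation against direct accumulation of in-range amplitude^2
  tot <- 0
  for (imf in d$imfs) {
    a <- analytic_signal(imf, 100)
    keep <- a$inst_freq >= 0 & a$inst_freq <= 32
    tot <- tot + sum(a$amplitude[keep]^2)
  }
  expect_lt(abs(sum(hs$energy) - tot) / tot, 1e-9)
})

test_that("an empty IMF set yields an all-zero grid", {
  d <- emd(rep(0.5, 3000))
  hs <- hilbert_spectrum(d, 100, 30, 30, f_max = 32)
  expect_equal(hs$energy, matrix(0, 30, 30))
})

test_that("EEG feature tensor has the 6x30x30 geometry the CNN expects", {
  ep <- tiny_epochs(1)[[1]]
  ft <- eeg_feature_tensor(ep$eeg)
  expect_equal(dim(ft), c(6L, 30L, 30L))
  expect_true(all(ft >= 0 & ft <= 1))
  expect_equal(eeg_feature_tensor(numeric(3000)), array(0, c(6, 30, 30)))
  expect_error(eeg_feature_tensor(numeric(2999)), "3000")
})

test_that("delta and alpha tones land in their frequency bins", {
  ft2 <- eeg_feature_tensor(tone(2), normalize = "none")
  ft10 <- eeg_feature_tensor(tone(10), normalize = "none")
  edges <- seq(0.5, 32, length.out = 31L)
  prof2 <- apply(ft2, 2, sum)
  prof10 <- apply(ft10, 2, sum)
  expect_equal(which.max(prof2), findInterval(2, edges))
  expect_equal(which.max(prof10), findInterval(10, edges))
  expect_true(which.max(prof2) != which.max(prof10))
})

test_that("EOG feature matrix is time-major with 30 one-second steps", {
  ep <- tiny_epochs(1)[[1]]
  fm <- eog_feature_matrix(ep$eog)
  expect_equal(dim(fm), c(30L, 30L))
  expect_equal(eog_feature_matrix(numeric(3000)), matrix(0, 30, 30))
  expect_error(eog_feature_matrix(numeric(100)), "3000")
  # slow REM-like deflection train concentrates energy in low-freq columns
  sm <- stage_models()
  rem <- synth_epoch("REM", sm, seed = 5)$eog
  frem <- eog_feature_matrix(rem, normalize = "none")
  colpow <- colSums(frem)
  expect_gt(sum(colpow[1:10]), sum(colpow[21:30]))
})

test_that("feature extraction is bit-identical across runs", {
  ep <- tiny_epochs(1)[[1]]
  p1 <- feature_pair(ep)
  p2 <- feature_pair(ep)
  expect_identical(p1$eeg_tensor, p2$eeg_tensor)
  expect_identical(p1$eog_matrix, p2$eog_matrix)
})

test_that("wavelet baseline peaks at the tone scale on the same grid", {
  g <- cwt_feature(tone(10), 30, 30, 0.5, 32, fs = 100)
  expect_equal(dim(g), c(30L, 30L))
  fc <- (seq(0.5, 32, length.out = 31)[-31] + seq(0.5, 32, length.out = 31)[-1]) / 2
  expect_equal(which.max(rowSums(g)), which.min(abs(fc - 10)))
  expect_equal(cwt_feature(numeric(3000), 30, 30, 0.5, 32),
               matrix(0, 30, 30))
  expect_error(cwt_feature(tone(10), 30, 30, 32, 0.5), "band")
  # interchangeable geometry with the adaptive features
  ep <- tiny_epochs(1)[[1]]
  fp <- feature_pair(ep, method = "cwt")
  expect_equal(dim(fp$eeg_tensor), c(6L, 30L, 30L))
  expect_equal(dim(fp$eog_matrix), c(30L, 30L))
})
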