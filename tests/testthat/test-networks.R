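# Subnetwork architecture conformance, focal loss, training behaviour.

table2_trace <- list(conv1 = c(6, 15, 15, 16), conv2 = c(6, 8, 8, 16),
                     pool1 = c(6, 4, 4, 16), conv3 = c(6, 2, 2, 16),
                     pool2 = c(6, 2, 2, 16), conv4 = c(6, 1, 1, 32),
                     pool3 = c(6, 1, 1, 32), conv5 = c(6, 1, 1, 64))

test_that("the EEG CNN reproduces the reference layer-by-layer shape chain", {
  p <- etn_init(1)
  tr <- etn_shape_trace(p)
  expect_equal(lapply(tr, as.numeric), lapply(table2_trace, as.numeric))
  fw <- etn_forward(array(stats::runif(5400), c(6, 30, 30)), p)
  expect_equal(nrow(fw$features), 384L)        # 6*1*1*64 flattened
  expect_equal(nrow(fw$features) + 200L, 584L) # first fusion layer width
  expect_equal(sum(fw$class_probs), 1, tolerance = 1e-9)
})

test_that("shape mismatches are reported with the offending layer", {
  p <- etn_init(1)
  expect_error(etn_forward(matrix(0, 100, 2), p), "conv1")
  expect_error(etn_forward(array(0, c(5, 30, 30)), p), "conv1")
})

test_that("zero input with zero biases and identity batch norm maps to zero", {
  p <- etn_init(2)
  fw <- etn_forward(matrix(0, 5400, 3), p)     # inference-mode batch norm
  expect_equal(max(abs(fw$features)), 0)
})

test_that("the EOG LSTM has a 200-unit state and is order sensitive", {
  p <- otn_init(1)
  X <- matrix(stats::runif(900), 30, 30)
  fw <- otn_forward(X, p)
  expect_equal(dim(fw$features), c(200L, 1L))
  perm <- otn_forward(X[sample(30), ], p)
  expect_gt(max(abs(perm$features - fw$features)), 1e-6)
  expect_error(otn_forward(matrix(0, 10, 30), p), "30")
})

test_that("a zero-initialized LSTM maps zero input to a zero state", {
  p <- otn_init(1)
  p$Wx[] <- 0; p$Wh[] <- 0; p$b[] <- 0
  fw <- otn_forward(matrix(0, 30, 30), p)
  expect_equal(max(abs(fw$features)), 0)
})

test_that("focal loss matches its closed forms and limit cases", {
  onehot <- c(1, 0, 0, 0, 0)
  expect_equal(focal_loss(onehot, "W", focal_params(gamma = 2)), 0)
  # gamma 0, alpha 1: categorical cross-entropy
  p <- c(.6, .1, .1, .1, .1)
  fp1 <- focal_params(alpha = rep(1, 5), gamma = 0)
  expect_equal(focal_loss(p, "W", fp1), -log(0.6), tolerance = 1e-12)
  # direct scalar evaluation: alpha .6, gamma 2, p_true .9
  p2 <- c(.9, .025, .025, .025, .025)
  expect_equal(focal_loss(p2, "W", focal_params(alpha = c(.6, .8, .9, .6, .9),
                                                gamma = 2)),
               0.6 * 0.01 * -log(0.9), tolerance = 1e-12)
  expect_equal(0.6 * 0.01 * -log(0.9), 6.32e-4, tolerance = 1e-2)
  # clamp with warning at zero true-class probability
  expect_warning(v <- focal_loss(c(0, .5, .5, 0, 0), "W", fp1), "clamp")
  expect_true(is.finite(v))
})

test_that("focal loss is nonnegative and strictly decreasing in p_true", {
  fp <- focal_params()
  ps <- seq(0.05, 0.95, by = 0.05)
  vals <- vapply(ps, function(pt) {
    rest <- (1 - pt) / 4
    focal_loss(c(pt, rest, rest, rest, rest), "W", fp)
  }, 0)
  expect_true(all(vals >= 0))
  expect_true(all(diff(vals) < 0))
})

test_that("focal gradient matches numerical differentiation", {
  set.seed(4)
  z <- matrix(stats::rnorm(10), 5, 2)
  y <- c(2L, 5L)
  al <- focal_params()$alpha
  lb <- sleepfusion:::.focal_batch(z, y, al, 2)
  for (k in sample(10, 4)) {
    zp <- z; zp[k] <- zp[k] + 1e-6
    zm <- z; zm[k] <- zm[k] - 1e-6
    ng <- (sleepfusion:::.focal_batch(zp, y, al, 2)$loss -
             sleepfusion:::.focal_batch(zm, y, al, 2)$loss) / 2e-6
    expect_equal(lb$dZ[k], ng, tolerance = 1e-5)
  }
})

test_that("subnetwork gradients match numerical differentiation", {
  set.seed(5)
  X <- matrix(stats::runif(5400 * 2), 5400, 2)
  y <- c(1L, 4L)
  al <- focal_params()$alpha
  p <- etn_init(3)
  fw <- etn_forward(X, p, train = TRUE)
  gr <- sleepfusion:::.etn_backward(
    p, fw, sleepfusion:::.focal_batch(fw$logits, y, al, 2)$dZ)
  fnum <- function(q) {
    f <- etn_forward(X, q, train = TRUE)
    sleepfusion:::.focal_batch(f$logits, y, al, 2)$loss
  }
  q1 <- p; q1$layers$conv2$W[7, 3] <- q1$layers$conv2$W[7, 3] + 1e-5
  q2 <- p; q2$layers$conv2$W[7, 3] <- q2$layers$conv2$W[7, 3] - 1e-5
  expect_equal(gr$layers$conv2$W[7, 3], (fnum(q1) - fnum(q2)) / 2e-5,
               tolerance = 1e-4)

  po <- otn_init(3)
  Xo <- array(stats::runif(1800), c(30, 30, 2))
  fo <- otn_forward(Xo, po)
  go <- sleepfusion:::.otn_backward(
    po, fo, sleepfusion:::.focal_batch(fo$logits, y, al, 2)$dZ)
  onum <- function(q) {
    f <- otn_forward(Xo, q)
    sleepfusion:::.focal_batch(f$logits, y, al, 2)$loss
  }
  q1 <- po; q1$Wh[20, 330] <- q1$Wh[20, 330] + 1e-5
  q2 <- po; q2$Wh[20, 330] <- q2$Wh[20, 330] - 1e-5
  expect_equal(go$Wh[20, 330], (onum(q1) - onum(q2)) / 2e-5,
               tolerance = 1e-4)
})

# small separable synthetic feature set: class k gets energy in its own
# frequency rows of both modalities
separable_pairs <- function(n, seed = 1) {
  set.seed(seed)
  labels <- rep(stage_levels(), length.out = n)
  pairs <- lapply(seq_len(n), function(i) {
    k <- stage_index(labels[i])
    eeg <- array(stats::runif(5400, 0, 0.05), c(6, 30, 30))
    eeg[, (k - 1) * 6 + 1:6, ] <- eeg[, (k - 1) * 6 + 1:6, ] + 0.8
    eog <- matrix(stats::runif(900, 0, 0.05), 30, 30)
    eog[, (k - 1) * 6 + 1:6] <- eog[, (k - 1) * 6 + 1:6] + 0.8
    structure(list(eeg_tensor = eeg, eog_matrix = eog),
              class = "feature_pair")
  })
  list(pairs = pairs, labels = labels)
}

test_that("both subnetworks fit linearly separable data to 100%", {
  d <- separable_pairs(50)
  cfg <- training_config(epochs = 30L, batch_size = 25L, seed = 1L)
  fe <- train_subnetwork(d$pairs, d$labels, "etn", cfg)
  expect_equal(tail(fe$history$accuracy, 1), 1)
  fo <- train_subnetwork(d$pairs, d$labels, "otn", cfg)
  expect_equal(tail(fo$history$accuracy, 1), 1)
  expect_equal(nrow(fe$history), 30L)
  # predictions follow the fitted classes
  pr <- predict_subnet(fe, d$pairs)
  expect_equal(pr$labels, d$labels)
})

test_that("training is deterministic under a fixed seed", {
  d <- separable_pairs(20)
  cfg <- training_config(epochs = 3L, batch_size = 10L, seed = 7L)
  h1 <- train_subnetwork(d$pairs, d$labels, "otn", cfg)$history
  h2 <- train_subnetwork(d$pairs, d$labels, "otn", cfg)$history
  expect_identical(h1, h2)
})

test_that("training refuses datasets with a missing class", {
  d <- separable_pairs(20)
  keep <- d$labels != "N3"
  expect_error(
    train_subnetwork(d$pairs[keep], d$labels[keep], "otn",
                     training_config(epochs = 1L)),
    "N3")
})
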