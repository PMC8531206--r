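# Gaussian-Bernoulli RBM correctness against brute-force enumeration,
# contrastive divergence behaviour, DBN pretraining and fine-tuning.

tiny_rbm <- function(nv = 3, nh = 2, type = "gaussian", seed = 10,
                     w_sd = 0.7) {
  r <- rbm_init(nv, nh, type, seed = seed, w_sd = w_sd)
  set.seed(seed + 1)
  r$a <- stats::rnorm(nv, sd = 0.5)
  r$b <- stats::rnorm(nh, sd = 0.5)
  if (type == "gaussian") r$sigma <- stats::runif(nv, 0.5, 1.5)
  r
}

all_hidden <- function(nh) {
  as.matrix(expand.grid(rep(list(c(0, 1)), nh)))
}

test_that("energy matches its closed forms", {
  r <- rbm_init(4, 3, "gaussian", seed = 1)
  r$W[] <- 0
  v <- c(0.3, -1, 2, 0.5)
  expect_equal(rbm_energy(v, c(0, 0, 0), r), sum(v^2) / 2)
  r2 <- tiny_rbm()
  expect_equal(rbm_energy(r2$a, rep(0, 2), r2), 0)
  expect_error(rbm_energy(c(1, 2), c(0, 0), r2), "shape")
})

test_that("hidden conditional equals the brute-force posterior over h", {
  r <- tiny_rbm(3, 2)
  v <- c(0.4, -0.8, 1.1)
  H <- all_hidden(2)
  en <- apply(H, 1, function(h) rbm_energy(v, h, r))
  pj <- exp(-en) / sum(exp(-en))               # p(h | v) by enumeration
  marg <- unname(colSums(H * pj))              # p(h_j = 1 | v)
  expect_equal(as.numeric(hidden_conditional(v, r)), marg,
               tolerance = 1e-9)
  # and the joint factorizes over hidden units given v
  ph <- as.numeric(hidden_conditional(v, r))
  prod_form <- apply(H, 1, function(h) prod(ph^h * (1 - ph)^(1 - h)))
  expect_equal(pj, prod_form, tolerance = 1e-9)
})

test_that("bernoulli RBM conditionals match enumeration in both directions", {
  r <- tiny_rbm(3, 2, type = "bernoulli")
  v <- c(1, 0, 1)
  H <- all_hidden(2)
  en <- apply(H, 1, function(h) rbm_energy(v, h, r))
  pj <- exp(-en) / sum(exp(-en))
  expect_equal(as.numeric(hidden_conditional(v, r)),
               unname(colSums(H * pj)), tolerance = 1e-9)
  h <- c(1, 0)
  V <- all_hidden(3)
  ev <- apply(V, 1, function(vv) rbm_energy(vv, h, r))
  pv <- exp(-ev) / sum(exp(-ev))
  expect_equal(as.numeric(visible_conditional(h, r)$mean),
               unname(colSums(V * pv)), tolerance = 1e-9)
})

test_that("gaussian visible conditional matches quadrature over a fine grid", {
  r <- tiny_rbm(2, 2)
  h <- c(1, 0)
  vc <- visible_conditional(h, r)
  # the energy is separable in v_i: integrate each coordinate on a grid
  for (i in 1:2) {
    g <- seq(vc$mean[i] - 8 * r$sigma[i], vc$mean[i] + 8 * r$sigma[i],
             length.out = 4001)
    en <- (g - r$a[i])^2 / (2 * r$sigma[i]^2) -
      g / r$sigma[i] * sum(r$W[i, ] * h)
    w <- exp(-(en - min(en)))
    expect_equal(sum(g * w) / sum(w), vc$mean[i], tolerance = 1e-3)
  }
  expect_equal(vc$sd, r$sigma)
  # W = 0 and h = 0 limits
  r0 <- r; r0$W[] <- 0
  expect_equal(as.numeric(visible_conditional(h, r0)$mean), r0$a)
  expect_equal(as.numeric(visible_conditional(c(0, 0), r)$mean), r$a)
})

test_that("zero learning rate leaves CD parameters unchanged", {
  r <- tiny_rbm(3, 2)
  set.seed(1)
  batch <- matrix(stats::rnorm(9), 3, 3)
  r2 <- cd_update(batch, r, k = 1, lr = 0)
  expect_identical(r2$W, r$W)
  expect_identical(r2$a, r$a)
  expect_identical(r2$b, r$b)
  expect_error(cd_update(matrix(c(1, NaN), 1), rbm_init(2, 2), 1, 0.1),
               "NaN")
})

test_that("CD training halves reconstruction error on stationary data", {
  # two correlated gaussian visibles: the hidden units must capture the
  # shared latent factor for the reconstruction to improve
  set.seed(21)
  n <- 200
  z <- stats::rnorm(n)
  data <- rbind(z + stats::rnorm(n, 0, 0.3), -z + stats::rnorm(n, 0, 0.3))
  data <- (data - rowMeans(data)) / apply(data, 1, stats::sd)
  r <- rbm_init(2, 4, "gaussian", seed = 3, w_sd = 0.1)
  recon_mse <- function(r) {
    ph <- hidden_conditional(data, r)
    vr <- visible_conditional(ph, r)$mean
    mean((vr - data)^2)
  }
  e0 <- recon_mse(r)
  set.seed(22)
  for (i in 1:500) r <- cd_update(data, r, k = 1, lr = 0.05)
  expect_lt(recon_mse(r), 0.5 * e0)
})

test_that("CD is deterministic given the RNG seed", {
  r <- tiny_rbm(3, 2)
  batch <- matrix(stats::rnorm(30), 3, 10)
  set.seed(5); r1 <- cd_update(batch, r, 1, 0.1)
  set.seed(5); r2 <- cd_update(batch, r, 1, 0.1)
  expect_identical(r1, r2)
})

test_that("greedy pretraining yields the prescribed stack widths", {
  set.seed(30)
  X <- matrix(stats::rnorm(20 * 584), 20, 584)
  dbn <- pretrain_dbn(X, epochs_per_layer = 1L, seed = 4)
  widths <- vapply(dbn$stack, function(r) dim(r$W), integer(2))
  expect_equal(widths, matrix(c(584, 300, 300, 200, 200, 100), 2))
  expect_equal(dim(dbn$head$W), c(100L, 5L))
  expect_equal(dbn$stack[[1]]$visible_type, "gaussian")
  expect_equal(dbn$stack[[2]]$visible_type, "bernoulli")
  expect_error(pretrain_dbn(X[, 1:100]), "584")
})

test_that("zero pretraining epochs returns a seed-reproducible random stack", {
  X <- matrix(0, 5, 584)
  d1 <- pretrain_dbn(X, epochs_per_layer = 0L, seed = 9)
  d2 <- pretrain_dbn(X, epochs_per_layer = 0L, seed = 9)
  d3 <- pretrain_dbn(X, epochs_per_layer = 0L, seed = 10)
  expect_identical(d1, d2)
  expect_gt(max(abs(d1$stack[[1]]$W - d3$stack[[1]]$W)), 0)
})

test_that("fine-tuning reaches 100% on separable 584-d features", {
  set.seed(40)
  n <- 100
  labels <- rep(stage_levels(), length.out = n)
  X <- matrix(stats::rnorm(n * 584, sd = 0.2), n, 584)
  for (i in seq_len(n))
    X[i, (stage_index(labels[i]) - 1) * 100 + 1:50] <- 2
  dbn <- pretrain_dbn(scale(X), epochs_per_layer = 2L, seed = 11)
  clf <- finetune(X, labels, dbn, fusion_config(epochs = 40L, seed = 12))
  expect_equal(tail(clf$history$accuracy, 1), 1)
  probs <- predict_stage(X, clf)
  expect_equal(colSums(probs), rep(1, n), tolerance = 1e-9)
  expect_equal(stage_from_index(apply(probs, 2, which.max)), labels)
  expect_identical(predict_stage(X, clf), probs)   # deterministic
  expect_error(predict_stage(X[, 1:10], clf), "width")
  expect_error(finetune(X[labels != "W", ], labels[labels != "W"], dbn),
               "W")
})

test_that("cross-entropy of a certain correct prediction is zero", {
  z <- matrix(c(50, 0, 0, 0, 0), 5, 1)        # softmax ~ one-hot
  lb <- sleepfusion:::.ce_batch(z, 1L)
  expect_equal(lb$loss, 0, tolerance = 1e-9)
})

test_that("pretraining helps over random initialization on structured data", {
  # label-poor, unlabeled-rich regime: features live near 5 class-specific
  # prototypes; the stack is pretrained on plentiful unlabeled data, then
  # fine-tuned on few labels. Unsupervised initialization should win the
  # paired comparison on most seeds.
  run_pair <- function(s) {
    set.seed(1000 + s)
    proto <- matrix(stats::rnorm(5 * 584), 5, 584)
    gen <- function(n, seed) {
      set.seed(seed)
      labels <- sample(stage_levels(), n, replace = TRUE)
      X <- proto[stage_index(labels), ] +
        matrix(stats::rnorm(n * 584), n, 584)
      list(X = X, labels = labels)
    }
    un <- gen(400, 2000 + s)
    lb <- gen(50, 3000 + s)
    te <- gen(200, 4000 + s)
    mu <- colMeans(un$X); sdv <- apply(un$X, 2, stats::sd)
    sc <- list(mean = mu, sd = sdv)
    Xs <- sweep(sweep(un$X, 2, mu), 2, sdv, "/")
    pre <- pretrain_dbn(Xs, epochs_per_layer = 10L, seed = s, lr = 1e-2)
    rnd <- pretrain_dbn(Xs, epochs_per_layer = 0L, seed = s)
    acc <- function(d0) {
      clf <- finetune(lb$X, lb$labels, d0,
                      fusion_config(epochs = 8L, seed = s),
                      standardize = sc)
      mean(stage_from_index(apply(predict_stage(te$X, clf), 2,
                                  which.max)) == te$labels)
    }
    acc(pre) > acc(rnd)
  }
  wins <- sum(vapply(1:10, run_pair, logical(1)))
  expect_gte(wins, 7L)
})
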