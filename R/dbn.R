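# Multimodal fusion head: a stack of restricted Boltzmann machines
# (584 -> 300 -> 200 -> 100), greedily pretrained with contrastive
# divergence, then fine-tuned end-to-end with a 5-way softmax and
# cross-entropy. The first RBM has Gaussian visible units (the concatenated
# real-valued subnetwork features, standardized per dimension, sigma fixed
# at 1); the deeper RBMs are Bernoulli-Bernoulli on the previous layer's
# hidden probabilities.
#
# Note on the conditionals: the method's original description writes the
# hidden conditional as a Gaussian, which is dimensionally inconsistent for binary hidden units; the
# standard logistic form p(h_j=1|v) = sigmoid(b_j + sum_i w_ij v_i / sigma_i)
# is used here, and the visible-bias symbol in the visible conditional is
# read as a_i. See the methods vignette.

#' Initialize a restricted Boltzmann machine
#'
#' @param n_visible,n_hidden layer widths
#' @param visible_type "gaussian" (real-valued visibles with per-unit scale
#'   sigma) or "bernoulli"
#' @param seed RNG seed for the weight draw
#' @param w_sd standard deviation of the initial weights
#' @return object of class `rbm_params`: list with `W` (visible x hidden),
#'   `a` (visible biases), `b` (hidden biases), `sigma`, `visible_type`
#' @export
rbm_init <- function(n_visible, n_hidden, visible_type = "gaussian",
                     seed = 1L, w_sd = 0.01) {
  stopifnot(visible_type %in% c("gaussian", "bernoulli"))
  with_seed(seed, structure(list(
    W = matrix(stats::rnorm(n_visible * n_hidden, sd = w_sd),
               n_visible, n_hidden),
    a = numeric(n_visible), b = numeric(n_hidden),
    sigma = rep(1, n_visible), visible_type = visible_type),
    class = "rbm_params"))
}

.check_rbm <- function(params, v = NULL, h = NULL) {
  if (!is.null(v) && length(v) != nrow(params$W))
    stop("shape mismatch: visible vector has length ", length(v),
         ", expected ", nrow(params$W))
  if (!is.null(h) && length(h) != ncol(params$W))
    stop("shape mismatch: hidden vector has length ", length(h),
         ", expected ", ncol(params$W))
  if (params$visible_type == "gaussian" && any(params$sigma <= 0))
    stop("gaussian visible scales must be positive")
}

#' Energy of a joint RBM configuration
#'
#' Gaussian-Bernoulli form:
#' \deqn{E(v,h) = \sum_i (v_i-a_i)^2 / 2\sigma_i^2 - \sum_j b_j h_j -
#'   \sum_{ij} (v_i/\sigma_i) h_j w_{ij}}
#' Bernoulli form replaces the quadratic term with \eqn{-\sum_i a_i v_i} and
#' drops the sigma scaling.
#'
#' @param v visible vector
#' @param h hidden (binary) vector
#' @param params an `rbm_params`
#' @return finite scalar energy
#' @export
rbm_energy <- function(v, h, params) {
  .check_rbm(params, v, h)
  if (params$visible_type == "gaussian") {
    sum((v - params$a)^2 / (2 * params$sigma^2)) - sum(params$b * h) -
      sum((v / params$sigma) * (params$W %*% h))
  } else {
    -sum(params$a * v) - sum(params$b * h) - sum(v * (params$W %*% h))
  }
}

#' Hidden conditional p(h_j = 1 | v)
#'
#' Logistic conditional of the (Gaussian-)Bernoulli RBM:
#' `sigmoid(b_j + sum_i w_ij v_i / sigma_i)` (sigma absent for Bernoulli
#' visibles). Accepts a matrix with samples in columns.
#'
#' @param v visible vector, or matrix (visible x N)
#' @param params an `rbm_params`
#' @return activation probabilities in (0,1), hidden x N
#' @export
hidden_conditional <- function(v, params) {
  v <- as.matrix(v)
  .check_rbm(params, v[, 1L])
  vs <- if (params$visible_type == "gaussian") v / params$sigma else v
  .sigmoid(crossprod(params$W, vs) + params$b)
}

#' Visible conditional given hidden states
#'
#' Gaussian visibles: mean `a_i + sigma_i * sum_j w_ij h_j`, variance
#' `sigma_i^2`. Bernoulli visibles: activation probability
#' `sigmoid(a_i + sum_j w_ij h_j)` (returned as `mean`, with `sd` 0).
#'
#' @param h hidden vector, or matrix (hidden x N)
#' @param params an `rbm_params`
#' @return list with `mean` (visible x N) and `sd` (per-visible scales)
#' @export
visible_conditional <- function(h, params) {
  h <- as.matrix(h)
  .check_rbm(params, h = h[, 1L])
  if (params$visible_type == "gaussian") {
    list(mean = params$a + params$sigma * (params$W %*% h),
         sd = params$sigma)
  } else {
    list(mean = .sigmoid(params$a + params$W %*% h),
         sd = rep(0, nrow(params$W)))
  }
}

#' One contrastive-divergence (CD-k) update
#'
#' Positive phase from the data batch, negative phase from k alternating
#' Gibbs steps (hidden states sampled; visibles reconstructed mean-field,
#' the usual choice for Gaussian visibles). Gradients are batch means; a
#' zero learning rate returns the parameters unchanged. The update is
#' stochastic: seed the RNG for determinism.
#'
#' @param batch matrix of visible vectors, samples in columns (visible x N)
#' @param params an `rbm_params`
#' @param k number of Gibbs steps (>= 1)
#' @param lr learning rate
#' @return updated `rbm_params`
#' @export
cd_update <- function(batch, params, k = 1L, lr = 1e-3) {
  stopifnot(k >= 1L)
  v0 <- as.matrix(batch)
  if (any(!is.finite(v0))) stop("NaN/Inf in batch")
  .check_rbm(params, v0[, 1L])
  N <- ncol(v0)
  ph0 <- hidden_conditional(v0, params)
  h <- (matrix(stats::runif(length(ph0)), nrow(ph0)) < ph0) * 1
  vk <- v0
  for (s in seq_len(k)) {
    vk <- visible_conditional(h, params)$mean
    phk <- hidden_conditional(vk, params)
    if (s < k) h <- (matrix(stats::runif(length(phk)), nrow(phk)) < phk) * 1
  }
  vs0 <- if (params$visible_type == "gaussian") v0 / params$sigma else v0
  vsk <- if (params$visible_type == "gaussian") vk / params$sigma else vk
  dW <- (vs0 %*% t(ph0) - vsk %*% t(phk)) / N
  da <- if (params$visible_type == "gaussian")
    rowMeans(v0 - vk) / params$sigma^2 else rowMeans(v0 - vk)
  db <- rowMeans(ph0 - phk)
  params$W <- params$W + lr * dW
  params$a <- params$a + lr * da
  params$b <- params$b + lr * db
  params
}

#' Greedy layer-wise pretraining of the fusion DBN
#'
#' Trains the RBM stack bottom-up with CD-1: the first RBM has Gaussian
#' visibles on the standardized 584-dimensional fused features, each further
#' RBM is Bernoulli-Bernoulli on the previous layer's hidden probabilities
#' (probabilities, not samples, are propagated -- the lower-variance common
#' practice). With `epochs_per_layer = 0` the randomly initialized stack is
#' returned, reproducibly per seed.
#'
#' @param features matrix, samples in rows (N x 584), already standardized
#'   per dimension
#' @param layer_sizes widths of the stack, default c(584, 300, 200, 100)
#' @param epochs_per_layer CD-1 epochs per RBM
#' @param seed RNG seed
#' @param lr CD learning rate
#' @param batch_size CD minibatch size
#' @return object of class `dbn_params`: list with `stack` (list of
#'   `rbm_params`) and `head` (100 -> 5 softmax layer)
#' @export
pretrain_dbn <- function(features, layer_sizes = c(584L, 300L, 200L, 100L),
                         epochs_per_layer = 10L, seed = 1L, lr = 1e-3,
                         batch_size = 32L) {
  X <- as.matrix(features)
  if (ncol(X) != layer_sizes[1L])
    stop("feature width ", ncol(X), " != expected ", layer_sizes[1L])
  n_layers <- length(layer_sizes) - 1L
  with_seed(seed, {
    stack <- vector("list", n_layers)
    V <- t(X)                                  # visible x N
    for (l in seq_len(n_layers)) {
      rbm <- rbm_init(layer_sizes[l], layer_sizes[l + 1L],
                      visible_type = if (l == 1L) "gaussian" else "bernoulli",
                      seed = NULL)             # draw from the current stream
      N <- ncol(V)
      if (epochs_per_layer > 0L) for (ep in seq_len(epochs_per_layer)) {
        ord <- sample.int(N)
        nb <- ceiling(N / batch_size)
        for (bi in seq_len(nb)) {
          take <- ord[((bi - 1L) * batch_size + 1L):min(bi * batch_size, N)]
          rbm <- cd_update(V[, take, drop = FALSE], rbm, k = 1L, lr = lr)
        }
      }
      stack[[l]] <- rbm
      V <- hidden_conditional(V, rbm)
    }
    head <- .dense_init(layer_sizes[n_layers + 1L], 5L)
    structure(list(stack = stack, head = head,
                   layer_sizes = layer_sizes), class = "dbn_params")
  })
}

# deterministic sigmoid forward pass through the stack
.dbn_forward <- function(dbn, X) {
  A <- list()
  V <- t(X)                                    # visible x N
  for (l in seq_along(dbn$stack)) {
    V <- hidden_conditional(V, dbn$stack[[l]])
    A[[l]] <- V
  }
  logits <- .dense_forward(V, dbn$head)
  list(acts = A, logits = logits, probs = .softmax(logits))
}

#' Fine-tune the DBN classifier with cross-entropy
#'
#' End-to-end backpropagation through the sigmoid stack and the softmax
#' head, minimizing categorical cross-entropy with Adam (learning rate
#' 1e-3, the reference fusion-stage rate). Standardization statistics are
#' estimated from the training features and stored with the classifier.
#'
#' @param features N x 584 matrix of fused subnetwork features (raw; the
#'   classifier standardizes internally)
#' @param labels character stage labels
#' @param dbn a `dbn_params` from [pretrain_dbn()] (pretrained or not)
#' @param config list with lr, epochs, batch_size, seed (see
#'   [fusion_config()])
#' @param standardize reuse these statistics instead of estimating
#'   (list with mean, sd), e.g. the ones pretraining used
#' @return object of class `dbn_classifier`: list with `dbn`, `scaler`,
#'   `history`
#' @export
finetune <- function(features, labels, dbn, config = fusion_config(),
                     standardize = NULL) {
  X <- as.matrix(features)
  y <- stage_index(labels)
  miss <- setdiff(stage_levels(), unique(labels))
  if (length(miss) > 0L)
    stop("class(es) absent from training data: ",
         paste(miss, collapse = ", "))
  scaler <- if (is.null(standardize)) {
    mu <- colMeans(X); s <- apply(X, 2L, stats::sd); s[s < 1e-8] <- 1
    list(mean = mu, sd = s)
  } else standardize
  Xs <- sweep(sweep(X, 2L, scaler$mean), 2L, scaler$sd, "/")
  N <- nrow(Xs)
  flat <- .dbn_flat(dbn)
  adam <- .adam_init(flat)
  set.seed(config$seed)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     accuracy = numeric(0))
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(N)
    nb <- ceiling(N / config$batch_size)
    ep_loss <- 0; ep_hit <- 0L
    for (bi in seq_len(nb)) {
      take <- ord[((bi - 1L) * config$batch_size + 1L):
                    min(bi * config$batch_size, N)]
      fw <- .dbn_forward(dbn, Xs[take, , drop = FALSE])
      lb <- .ce_batch(fw$logits, y[take])
      if (!is.finite(lb$loss)) stop("divergent loss (non-finite)")
      grads <- .dbn_backward(dbn, fw, lb$dZ, t(Xs[take, , drop = FALSE]))
      st <- .adam_step(flat, grads, adam, config$lr)
      flat <- st$params
      adam <- st$state
      dbn <- .dbn_unflat(dbn, flat)
      ep_loss <- ep_loss + lb$loss * length(take)
      ep_hit <- ep_hit + sum(apply(lb$probs, 2L, which.max) == y[take])
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / N,
                                   accuracy = ep_hit / N))
  }
  structure(list(dbn = dbn, scaler = scaler, history = hist,
                 config = config), class = "dbn_classifier")
}

#' Fusion-stage training configuration
#'
#' @param lr Adam learning rate (reference value 1e-3)
#' @param epochs fine-tuning epochs
#' @param batch_size minibatch size (32; the reference batch of 128 is tied
#'   to the subnetwork stage, see the vignette)
#' @param seed RNG seed
#' @return list
#' @export
fusion_config <- function(lr = 1e-3, epochs = 50L, batch_size = 32L,
                          seed = 1L) {
  list(lr = lr, epochs = as.integer(epochs),
       batch_size = as.integer(batch_size), seed = as.integer(seed))
}

.dbn_flat <- function(dbn) {
  out <- list()
  for (l in seq_along(dbn$stack)) {
    out[[paste0("W", l)]] <- dbn$stack[[l]]$W
    out[[paste0("b", l)]] <- dbn$stack[[l]]$b
  }
  out$head.W <- dbn$head$W
  out$head.b <- dbn$head$b
  out
}

.dbn_unflat <- function(dbn, flat) {
  for (l in seq_along(dbn$stack)) {
    dbn$stack[[l]]$W <- flat[[paste0("W", l)]]
    dbn$stack[[l]]$b <- flat[[paste0("b", l)]]
  }
  dbn$head$W <- flat$head.W
  dbn$head$b <- flat$head.b
  dbn
}

# backprop through sigmoid stack; V0 is visible x N (standardized).
# With want_input_grad the gradient wrt the (standardized) input is also
# returned, for joint fine-tuning into the subnetworks.
.dbn_backward <- function(dbn, fw, dLogits, V0, want_input_grad = FALSE) {
  grads <- list()
  hb <- .dense_backward(dLogits, fw$acts[[length(fw$acts)]], dbn$head)
  grads$head.W <- hb$grads$W
  grads$head.b <- hb$grads$b
  dA <- hb$dX
  for (l in rev(seq_along(dbn$stack))) {
    A <- fw$acts[[l]]
    dZ <- dA * A * (1 - A)
    Vin <- if (l == 1L) V0 else fw$acts[[l - 1L]]
    vs <- if (dbn$stack[[l]]$visible_type == "gaussian")
      Vin / dbn$stack[[l]]$sigma else Vin
    grads[[paste0("W", l)]] <- vs %*% t(dZ)
    grads[[paste0("b", l)]] <- rowSums(dZ)
    dA <- dbn$stack[[l]]$W %*% dZ
    if (dbn$stack[[l]]$visible_type == "gaussian")
      dA <- dA / dbn$stack[[l]]$sigma
  }
  out <- grads[names(.dbn_flat(dbn))]
  if (want_input_grad) list(grads = out, dV0 = dA) else out
}

#' Predict stage probabilities with the fused classifier
#'
#' @param features N x 584 matrix (raw fused subnetwork features) or a
#'   single 584-vector
#' @param classifier a `dbn_classifier`
#' @return 5 x N matrix of stage probabilities (columns sum to 1); the
#'   row order is the scoring order W, REM, N1, N2, N3
#' @export
predict_stage <- function(features, classifier) {
  X <- if (is.null(dim(features))) matrix(features, nrow = 1L) else
    as.matrix(features)
  if (ncol(X) != length(classifier$scaler$mean))
    stop("feature width ", ncol(X), " != expected ",
         length(classifier$scaler$mean))
  Xs <- sweep(sweep(X, 2L, classifier$scaler$mean), 2L,
              classifier$scaler$sd, "/")
  .dbn_forward(classifier$dbn, Xs)$probs
}
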