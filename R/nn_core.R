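# Minimal neural-network machinery for the two subnetworks: 3D "same"
# convolutions via precomputed im2col index maps, max pooling, batch
# normalisation, dense layers, softmax/focal losses, and Adam. Volumes are
# stored as vectors (position-major, channels slowest) with the batch as
# matrix columns, so every layer is one indexing pass plus one BLAS call.

# TensorFlow-convention "same" padding: output ceil(n/stride), total pad
# max((out-1)*stride + k - n, 0), split begin = floor(total/2).
.same_pad <- function(n, k, s) {
  out <- ceiling(n / s)
  tot <- max((out - 1L) * s + k - n, 0L)
  beg <- tot %/% 2L
  c(out = out, beg = beg, end = tot - beg)
}

# Index plan for a 3D convolution (or, with spatial_only channels, pooling).
.conv3d_plan <- function(in_dim, kernel, stride, filters = NULL,
                         pool = FALSE) {
  D <- in_dim[1L]; H <- in_dim[2L]; W <- in_dim[3L]; C <- in_dim[4L]
  kd <- kernel[1L]; kh <- kernel[2L]; kw <- kernel[3L]
  sd_ <- stride[1L]; sh <- stride[2L]; sw <- stride[3L]
  pd <- .same_pad(D, kd, sd_); ph <- .same_pad(H, kh, sh)
  pw <- .same_pad(W, kw, sw)
  Dp <- D + pd[["beg"]] + pd[["end"]]; Hp <- H + ph[["beg"]] + ph[["end"]]
  Wp <- W + pw[["beg"]] + pw[["end"]]
  od <- pd[["out"]]; oh <- ph[["out"]]; ow <- pw[["out"]]
  # linear indices (0-based) of original voxels inside one padded channel
  g <- expand.grid(d = seq_len(D) - 1L, h = seq_len(H) - 1L,
                   w = seq_len(W) - 1L)
  pos_pad <- (g$d + pd["beg"]) + (g$h + ph["beg"]) * Dp +
    (g$w + pw["beg"]) * Dp * Hp
  chan_off <- (seq_len(C) - 1L) * Dp * Hp * Wp
  pad_pos <- as.integer(outer(pos_pad, chan_off, "+")) + 1L
  # output-position window starts (0-based, one padded channel)
  go <- expand.grid(d = seq_len(od) - 1L, h = seq_len(oh) - 1L,
                    w = seq_len(ow) - 1L)
  starts <- go$d * sd_ + go$h * sh * Dp + go$w * sw * Dp * Hp
  # kernel offsets
  gk <- expand.grid(a = seq_len(kd) - 1L, b = seq_len(kh) - 1L,
                    cc = seq_len(kw) - 1L)
  offs <- gk$a + gk$b * Dp + gk$cc * Dp * Hp
  if (pool) {
    # per-channel windows: columns ordered position-fastest then channel
    starts_pc <- as.vector(outer(starts, chan_off, "+"))
    idx <- outer(offs, starts_pc, "+") + 1L
  } else {
    offs <- as.vector(outer(offs, chan_off, "+"))   # kernel x channel rows
    idx <- outer(offs, starts, "+") + 1L
  }
  storage.mode(idx) <- "integer"
  list(in_dim = in_dim, out_dim = c(od, oh, ow,
                                    if (pool) C else filters),
       n_in = D * H * W * C, n_pad = Dp * Hp * Wp * C,
       n_out_pos = od * oh * ow, ksize = nrow(idx),
       pad_pos = pad_pos, idx = idx, idx_vec = as.integer(idx),
       pool = pool)
}

.he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

# conv3d + batchnorm + ReLU block ------------------------------------------

.conv_block_init <- function(in_dim, kernel, stride, filters) {
  plan <- .conv3d_plan(in_dim, kernel, stride, filters)
  F_ <- filters
  list(plan = plan,
       W = .he_init(plan$ksize, F_, plan$ksize),
       b = numeric(F_),
       gamma = rep(1, F_), beta = numeric(F_),
       rmean = numeric(F_), rvar = rep(1, F_))
}

.conv_block_forward <- function(X, layer, train = FALSE, name = "conv") {
  plan <- layer$plan
  if (nrow(X) != plan$n_in)
    stop("shape mismatch at layer ", name, ": expected ", plan$n_in,
         " inputs, got ", nrow(X))
  N <- ncol(X)
  Xp <- matrix(0, plan$n_pad, N)
  Xp[plan$pad_pos, ] <- X
  Z0 <- .conv_fwd_cpp(Xp, plan$idx, layer$W, layer$b)
  eps <- 1e-5
  if (train) {
    mu <- rowMeans(Z0)
    v <- rowMeans((Z0 - mu)^2)
  } else {
    mu <- layer$rmean
    v <- layer$rvar
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (Z0 - mu) * invstd
  Z1 <- layer$gamma * xhat + layer$beta
  mask <- Z1 > 0
  Y <- Z1 * mask
  dim(Y) <- c(nrow(Y), plan$n_out_pos, N)
  Y <- aperm(Y, c(2L, 1L, 3L))
  dim(Y) <- c(plan$n_out_pos * dim(layer$W)[2L], N)
  list(out = Y,
       cache = list(Xp = Xp, xhat = xhat, invstd = invstd, mask = mask,
                    mu = mu, v = v, N = N))
}

.conv_block_backward <- function(dY, layer, cache) {
  plan <- layer$plan
  F_ <- ncol(layer$W)
  N <- cache$N
  dim(dY) <- c(plan$n_out_pos, F_, N)
  dY <- aperm(dY, c(2L, 1L, 3L))
  dim(dY) <- c(F_, plan$n_out_pos * N)
  dZ1 <- dY * cache$mask
  dgamma <- rowSums(dZ1 * cache$xhat)
  dbeta <- rowSums(dZ1)
  m <- ncol(dZ1)
  dxhat <- dZ1 * layer$gamma
  dZ0 <- (cache$invstd / m) *
    (m * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  bw <- .conv_bwd_cpp(cache$Xp, plan$idx, layer$W, dZ0)
  list(dX = bw$dXp[plan$pad_pos, , drop = FALSE],
       grads = list(W = bw$dW, b = as.numeric(bw$db), gamma = dgamma,
                    beta = dbeta))
}

# update running batch-norm statistics after a training step
.bn_update_running <- function(layer, cache, momentum = 0.9) {
  layer$rmean <- momentum * layer$rmean + (1 - momentum) * cache$mu
  layer$rvar <- momentum * layer$rvar + (1 - momentum) * cache$v
  layer
}

# max-pool block -------------------------------------------------------------

.pool_init <- function(in_dim, pool, stride) {
  list(plan = .conv3d_plan(in_dim, pool, stride, pool = TRUE))
}

.pool_forward <- function(X, layer, name = "pool") {
  plan <- layer$plan
  if (nrow(X) != plan$n_in)
    stop("shape mismatch at layer ", name, ": expected ", plan$n_in,
         " inputs, got ", nrow(X))
  N <- ncol(X)
  Xp <- matrix(-Inf, plan$n_pad, N)
  Xp[plan$pad_pos, ] <- X
  P <- Xp[plan$idx_vec, , drop = FALSE]
  ncols <- ncol(plan$idx)                      # n_out_pos * C
  dim(P) <- c(plan$ksize, ncols * N)
  best <- P[1L, ]
  arg <- rep(1L, length(best))
  if (plan$ksize > 1L) for (r in 2L:plan$ksize) {
    sel <- P[r, ] > best
    best[sel] <- P[r, sel]
    arg[sel] <- r
  }
  Y <- best
  dim(Y) <- c(ncols, N)
  list(out = Y, cache = list(arg = arg, N = N))
}

.pool_backward <- function(dY, layer, cache) {
  plan <- layer$plan
  N <- cache$N
  ncols <- ncol(plan$idx)
  u <- rep(seq_len(ncols), N)                   # output unit per element
  gidx <- plan$idx[(u - 1L) * plan$ksize + cache$arg]
  samp <- rep(seq_len(N) - 1L, each = ncols)
  lin <- gidx + samp * plan$n_pad
  acc <- rowsum(as.vector(dY), lin)
  dXp <- numeric(plan$n_pad * N)
  dXp[as.numeric(rownames(acc))] <- acc
  dim(dXp) <- c(plan$n_pad, N)
  dXp[plan$pad_pos, , drop = FALSE]
}

# dense layer ----------------------------------------------------------------

.dense_init <- function(n_in, n_out) {
  list(W = .he_init(n_in, n_out, n_in), b = numeric(n_out))
}

.dense_forward <- function(X, layer) crossprod(layer$W, X) + layer$b

.dense_backward <- function(dY, X, layer) {
  list(dX = layer$W %*% dY,
       grads = list(W = X %*% t(dY), b = rowSums(dY)))
}

# losses ---------------------------------------------------------------------

.softmax <- function(Z) {
  Z <- Z - matrix(apply(Z, 2L, max), nrow(Z), ncol(Z), byrow = TRUE)
  E <- exp(Z)
  E / matrix(colSums(E), nrow(Z), ncol(Z), byrow = TRUE)
}

#' Focal loss for one predicted distribution
#'
#' Class-balanced focal loss
#' \eqn{-\alpha_{label} (1 - p_{true})^{\gamma} \log p_{true}}, where
#' `p_true` is the predicted probability of the true class (the product of
#' the prediction vector with the one-hot label). With gamma = 0 and
#' alpha = 1 it reduces to the categorical cross-entropy of the true class;
#' a certain correct prediction has zero loss. A zero probability for the
#' true class is clamped at 1e-12 with a warning.
#'
#' @param pred_probs numeric 5-vector of class probabilities (scoring order
#'   W, REM, N1, N2, N3), summing to 1
#' @param label stage name or index of the true class
#' @param params list with `alpha` (5-vector of class weights in (0,1]) and
#'   `gamma` (>= 0); see [focal_params()]
#' @return nonnegative scalar loss
#' @export
#' @examples
#' focal_loss(c(.9, .025, .025, .025, .025), "W", focal_params())
focal_loss <- function(pred_probs, label, params = focal_params()) {
  stopifnot(length(pred_probs) == 5L, params$gamma >= 0,
            all(params$alpha > 0), all(params$alpha <= 1))
  idx <- if (is.character(label)) stage_index(label) else as.integer(label)
  pt <- pred_probs[idx]
  if (pt <= 0) {
    warning("true-class probability is zero; clamped at 1e-12")
    pt <- 1e-12
  }
  -params$alpha[idx] * (1 - pt)^params$gamma * log(pt)
}

#' Default focal-loss parameters
#'
#' The class-weight vector alpha assigns its largest weights (0.9) to the
#' minority stages N1 and N3 and is stated here in the scoring order
#' W, REM, N1, N2, N3: (0.6, 0.8, 0.9, 0.6, 0.9). The default focusing
#' exponent is gamma = 2.
#'
#' @param alpha 5-vector of class weights in (0,1], scoring order
#' @param gamma focusing exponent, >= 0
#' @return list with `alpha`, `gamma`
#' @export
focal_params <- function(alpha = c(W = 0.6, REM = 0.8, N1 = 0.9,
                                   N2 = 0.6, N3 = 0.9),
                         gamma = 2) {
  stopifnot(length(alpha) == 5L, all(alpha > 0), all(alpha <= 1), gamma >= 0)
  list(alpha = unname(alpha), gamma = gamma)
}

# batched focal loss + gradient wrt logits; labels are integer indices
.focal_batch <- function(logits, labels, alpha, gamma) {
  N <- ncol(logits)
  P <- .softmax(logits)
  sel <- cbind(labels, seq_len(N))
  pt <- pmax(P[sel], 1e-12)
  al <- alpha[labels]
  loss <- mean(-al * (1 - pt)^gamma * log(pt))
  # dL/dp_t, then chain through softmax: dz_j = dLdp * p_t (1[j=t] - p_j)
  dLdp <- if (gamma == 0) -al / pt else
    al * gamma * (1 - pt)^(gamma - 1) * log(pt) - al * (1 - pt)^gamma / pt
  coef <- dLdp * pt / N
  dZ <- -P * matrix(coef, nrow(P), N, byrow = TRUE)
  dZ[sel] <- dZ[sel] + coef
  list(loss = loss, dZ = dZ, probs = P)
}

# cross-entropy + gradient wrt logits
.ce_batch <- function(logits, labels) {
  N <- ncol(logits)
  P <- .softmax(logits)
  sel <- cbind(labels, seq_len(N))
  loss <- mean(-log(pmax(P[sel], 1e-12)))
  dZ <- P / N
  dZ[sel] <- dZ[sel] - 1 / N
  list(loss = loss, dZ = dZ, probs = P)
}

# Adam -----------------------------------------------------------------------

.adam_init <- function(params) {
  zero <- function(x) {
    if (is.list(x)) lapply(x, zero) else x * 0
  }
  list(m = zero(params), v = zero(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in names(g)) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      return(out)
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
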