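# EOG Tensor Network: a single-layer LSTM that consumes the 30 x 30 EOG
# Hilbert spectrum time-major -- 30 time steps of 30 frequency-bin values --
# and characterises the progressive frequency evolution of eye movements.
# The final hidden state (200 units) is the fusion feature; an auxiliary
# softmax head is used only for subnetwork training.

#' Initialize the EOG LSTM subnetwork
#'
#' Single-layer LSTM, input width 30, 30 time steps, 200 hidden units.
#' Input weights are He-normal, recurrent weights small-normal, forget-gate
#' bias 1 (standard recipe for stable early training).
#'
#' @param seed integer RNG seed
#' @param n_hidden hidden state width (200)
#' @param n_input per-step input width (30)
#' @return object of class `otn_params`
#' @export
otn_init <- function(seed = 1L, n_hidden = 200L, n_input = 30L) {
  with_seed(seed, {
    nh <- n_hidden
    b <- numeric(4L * nh)
    b[(nh + 1L):(2L * nh)] <- 1                 # forget gate bias
    structure(list(
      Wx = .he_init(n_input, 4L * nh, n_input),
      Wh = matrix(stats::rnorm(nh * 4L * nh, sd = 1 / sqrt(nh)), nh, 4L * nh),
      b = b,
      head = .dense_init(nh, 5L),
      n_hidden = nh, n_input = n_input), class = "otn_params")
  })
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Forward pass of the EOG subnetwork
#'
#' @param eog_matrix one 30 x 30 matrix (time step x frequency bin), or a
#'   30 x 30 x N array with the batch in the third dimension
#' @param params an `otn_params`
#' @return list with `features` (final hidden state, 200 x N),
#'   `class_probs` (5 x N auxiliary softmax), `logits`, `cache`
#' @export
otn_forward <- function(eog_matrix, params) {
  X <- eog_matrix
  if (is.matrix(X)) {
    if (!all(dim(X) == c(30L, params$n_input)))
      stop("shape mismatch: EOG input must be 30 x ", params$n_input)
    dim(X) <- c(30L, params$n_input, 1L)
  }
  stopifnot(dim(X)[1L] == 30L, dim(X)[2L] == params$n_input)
  N <- dim(X)[3L]
  nh <- params$n_hidden
  h <- matrix(0, nh, N)
  cc <- matrix(0, nh, N)
  steps <- vector("list", 30L)
  ii <- seq_len(nh); ff <- nh + ii; gg <- 2L * nh + ii; oo <- 3L * nh + ii
  for (t in 1:30) {
    xt <- matrix(X[t, , ], nrow = params$n_input, ncol = N)
    Z <- crossprod(params$Wx, xt) + crossprod(params$Wh, h) + params$b
    i_g <- .sigmoid(Z[ii, , drop = FALSE])
    f_g <- .sigmoid(Z[ff, , drop = FALSE])
    g_g <- tanh(Z[gg, , drop = FALSE])
    o_g <- .sigmoid(Z[oo, , drop = FALSE])
    c_new <- f_g * cc + i_g * g_g
    h_new <- o_g * tanh(c_new)
    steps[[t]] <- list(xt = xt, h_prev = h, c_prev = cc, i = i_g, f = f_g,
                       g = g_g, o = o_g, c = c_new)
    h <- h_new
    cc <- c_new
  }
  logits <- .dense_forward(h, params$head)
  list(features = h, logits = logits, class_probs = .softmax(logits),
       cache = steps)
}

# truncated-nowhere BPTT over the full 30 steps
.otn_backward <- function(params, fw, dLogits, dFeatures = NULL) {
  hb <- .dense_backward(dLogits, fw$features, params$head)
  nh <- params$n_hidden
  dh <- hb$dX
  if (!is.null(dFeatures)) dh <- dh + dFeatures
  dc <- dh * 0
  dWx <- params$Wx * 0; dWh <- params$Wh * 0; db <- params$b * 0
  ii <- seq_len(nh); ff <- nh + ii; gg <- 2L * nh + ii; oo <- 3L * nh + ii
  for (t in 30:1) {
    s <- fw$cache[[t]]
    tc <- tanh(s$c)
    do <- dh * tc
    dc <- dc + dh * s$o * (1 - tc^2)
    di <- dc * s$g
    dg <- dc * s$i
    df <- dc * s$c_prev
    dc_prev <- dc * s$f
    dZ <- rbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                dg * (1 - s$g^2),
                do * s$o * (1 - s$o))
    dWx <- dWx + s$xt %*% t(dZ)
    dWh <- dWh + s$h_prev %*% t(dZ)
    db <- db + rowSums(dZ)
    dh <- params$Wh %*% dZ
    dc <- dc_prev
  }
  list(Wx = dWx, Wh = dWh, b = db, head = hb$grads)
}
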