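# EEG Tensor Network: a 3D CNN over the 6 x 30 x 30 stack of 5 s Hilbert
# spectra. Five convolutional layers (ReLU, batch norm before activation)
# interleaved with three max-pooling layers, "same" padding throughout, which
# is the only padding scheme that reproduces the reference output-shape
# chain:
#   conv1 (2,5,5)/(1,2,2)x16 -> 6x15x15x16   conv2 (2,5,5)/(1,2,2)x16 -> 6x8x8x16
#   pool1 (1,2,2)/(1,2,2)    -> 6x4x4x16     conv3 (2,3,3)/(1,2,2)x16 -> 6x2x2x16
#   pool2 (1,2,2)/(1,1,1)    -> 6x2x2x16     conv4 (2,3,3)/(1,2,2)x32 -> 6x1x1x32
#   pool3 (2,1,1)/(1,1,1)    -> 6x1x1x32     conv5 (2,1,1)/(1,1,1)x64 -> 6x1x1x64
# The flattened 6*1*1*64 = 384 map is the fusion feature; an auxiliary
# softmax head is used only to train the subnetwork with focal loss.

#' Initialize the EEG 3D convolutional subnetwork
#'
#' He-normal weights, zero biases, identity batch norm. The architecture is
#' fixed (see the layer trace in [etn_shape_trace()]).
#'
#' @param seed integer RNG seed for the weight draw
#' @return object of class `etn_params`
#' @export
etn_init <- function(seed = 1L) {
  with_seed(seed, {
    layers <- list(
      conv1 = .conv_block_init(c(6L, 30L, 30L, 1L), c(2L, 5L, 5L),
                               c(1L, 2L, 2L), 16L),
      conv2 = .conv_block_init(c(6L, 15L, 15L, 16L), c(2L, 5L, 5L),
                               c(1L, 2L, 2L), 16L),
      pool1 = .pool_init(c(6L, 8L, 8L, 16L), c(1L, 2L, 2L), c(1L, 2L, 2L)),
      conv3 = .conv_block_init(c(6L, 4L, 4L, 16L), c(2L, 3L, 3L),
                               c(1L, 2L, 2L), 16L),
      pool2 = .pool_init(c(6L, 2L, 2L, 16L), c(1L, 2L, 2L), c(1L, 1L, 1L)),
      conv4 = .conv_block_init(c(6L, 2L, 2L, 16L), c(2L, 3L, 3L),
                               c(1L, 2L, 2L), 32L),
      pool3 = .pool_init(c(6L, 1L, 1L, 32L), c(2L, 1L, 1L), c(1L, 1L, 1L)),
      conv5 = .conv_block_init(c(6L, 1L, 1L, 32L), c(2L, 1L, 1L),
                               c(1L, 1L, 1L), 64L)
    )
    head <- .dense_init(384L, 5L)
    structure(list(layers = layers, head = head), class = "etn_params")
  })
}

#' Layer-by-layer output shapes of the EEG subnetwork
#'
#' @param params an `etn_params`
#' @return named list of c(depth, height, width, channels) per layer
#' @export
etn_shape_trace <- function(params) {
  lapply(params$layers, function(l) unname(l$plan$out_dim))
}

#' Forward pass of the EEG subnetwork
#'
#' @param eeg_tensor one 6 x 30 x 30 array, or a 5400 x N matrix of
#'   flattened tensors (batch in columns)
#' @param params an `etn_params`
#' @param train use batch statistics (TRUE) or running statistics (FALSE)
#' @return list with `features` (384 x N fusion features), `class_probs`
#'   (5 x N auxiliary softmax), `logits`, and `cache` (for backprop)
#' @export
etn_forward <- function(eeg_tensor, params, train = FALSE) {
  X <- eeg_tensor
  if (is.array(X) && length(dim(X)) == 3L) {
    if (!all(dim(X) == c(6L, 30L, 30L)))
      stop("shape mismatch at layer conv1: input must be 6 x 30 x 30")
    X <- matrix(as.vector(X), ncol = 1L)
  }
  if (nrow(X) != 5400L)
    stop("shape mismatch at layer conv1: expected 5400 inputs, got ",
         nrow(X))
  caches <- list()
  for (nm in names(params$layers)) {
    l <- params$layers[[nm]]
    if (is.null(l$W)) {
      r <- .pool_forward(X, l, name = nm)
    } else {
      r <- .conv_block_forward(X, l, train = train, name = nm)
    }
    caches[[nm]] <- c(r$cache, list(X_in = X))
    X <- r$out
  }
  feats <- X                                   # 384 x N
  logits <- .dense_forward(feats, params$head)
  list(features = feats, logits = logits, class_probs = .softmax(logits),
       cache = caches)
}

# backward pass: dLogits from the loss, plus optional gradient on the
# features themselves (for fused fine-tuning). Returns grads mirroring params.
.etn_backward <- function(params, fw, dLogits, dFeatures = NULL) {
  hb <- .dense_backward(dLogits, fw$features, params$head)
  dX <- hb$dX
  if (!is.null(dFeatures)) dX <- dX + dFeatures
  grads <- list(layers = list(), head = hb$grads)
  for (nm in rev(names(params$layers))) {
    l <- params$layers[[nm]]
    cache <- fw$cache[[nm]]
    if (is.null(l$W)) {
      dX <- .pool_backward(dX, l, cache)
      grads$layers[[nm]] <- list()
    } else {
      r <- .conv_block_backward(dX, l, cache)
      dX <- r$dX
      grads$layers[[nm]] <- r$grads
    }
  }
  grads$layers <- grads$layers[names(params$layers)]
  grads
}
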