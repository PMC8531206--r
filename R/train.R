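# Training loop shared by the two subnetworks: focal loss, Adam, L2 weight
# penalty, minibatches, deterministic under a fixed seed.

#' Training configuration for the subnetworks
#'
#' Defaults follow the reference training protocol: Adam with learning rate 1e-3,
#' minibatch 128, up to 50 epochs, focal loss with gamma 2 and the
#' class-balanced alpha vector of [focal_params()], L2 penalty 1e-4 on all
#' convolutional/dense/recurrent weight matrices (not biases or batch-norm
#' parameters).
#'
#' @param lr Adam learning rate
#' @param batch_size minibatch size
#' @param epochs number of passes over the training set
#' @param alpha,gamma focal-loss parameters (scoring order W,REM,N1,N2,N3)
#' @param l2 weight-decay coefficient
#' @param seed RNG seed controlling initialization and batch order
#' @param val_fraction optional fraction of samples held out to monitor
#'   validation accuracy and keep the best epoch (0 disables)
#' @return list of class `training_config`
#' @export
training_config <- function(lr = 1e-3, batch_size = 128L, epochs = 50L,
                            alpha = focal_params()$alpha, gamma = 2,
                            l2 = 1e-4, seed = 1L, val_fraction = 0) {
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), alpha = alpha, gamma = gamma,
                 l2 = l2, seed = as.integer(seed),
                 val_fraction = val_fraction),
            class = "training_config")
}

#' Stack feature pairs into network-ready arrays
#'
#' @param pairs list of `feature_pair`
#' @return list with `eeg` (5400 x N matrix of flattened 6x30x30 tensors)
#'   and `eog` (30 x 30 x N array)
#' @export
stack_feature_pairs <- function(pairs) {
  N <- length(pairs)
  eeg <- vapply(pairs, function(p) as.vector(p$eeg_tensor), numeric(5400L))
  eog <- array(0, c(30L, 30L, N))
  for (i in seq_len(N)) eog[, , i] <- pairs[[i]]$eog_matrix
  list(eeg = matrix(eeg, nrow = 5400L), eog = eog)
}

# flat trainable-parameter views -------------------------------------------

.etn_flat <- function(p) {
  out <- list()
  for (nm in names(p$layers)) {
    l <- p$layers[[nm]]
    if (!is.null(l$W))
      for (f in c("W", "b", "gamma", "beta"))
        out[[paste0(nm, ".", f)]] <- l[[f]]
  }
  out[["head.W"]] <- p$head$W
  out[["head.b"]] <- p$head$b
  out
}

.etn_unflat <- function(p, flat) {
  for (nm in names(p$layers)) {
    if (!is.null(p$layers[[nm]]$W))
      for (f in c("W", "b", "gamma", "beta"))
        p$layers[[nm]][[f]] <- flat[[paste0(nm, ".", f)]]
  }
  p$head$W <- flat[["head.W"]]
  p$head$b <- flat[["head.b"]]
  p
}

.etn_flat_grads <- function(g) {
  out <- list()
  for (nm in names(g$layers)) {
    if (length(g$layers[[nm]]) > 0L)
      for (f in c("W", "b", "gamma", "beta"))
        out[[paste0(nm, ".", f)]] <- g$layers[[nm]][[f]]
  }
  out[["head.W"]] <- g$head$W
  out[["head.b"]] <- g$head$b
  out
}

.otn_flat <- function(p)
  list(Wx = p$Wx, Wh = p$Wh, b = p$b, head.W = p$head$W, head.b = p$head$b)

.otn_unflat <- function(p, flat) {
  p$Wx <- flat$Wx; p$Wh <- flat$Wh; p$b <- flat$b
  p$head$W <- flat$head.W; p$head$b <- flat$head.b
  p
}

.otn_flat_grads <- function(g)
  list(Wx = g$Wx, Wh = g$Wh, b = g$b, head.W = g$head$W, head.b = g$head$b)

# names of flat entries that receive the L2 penalty (weight matrices only)
.l2_names <- function(flat)
  names(flat)[grepl("(\\.W$|^Wx$|^Wh$)", names(flat))]

#' Train one heterogeneous subnetwork with focal loss
#'
#' Trains the EEG 3D CNN (`which = "etn"`) or the EOG LSTM
#' (`which = "otn"`) on feature pairs with the class-balanced focal loss,
#' Adam, and L2 weight decay. All five stages must be present in the
#' training labels; a divergent (non-finite) loss aborts. Deterministic for
#' a fixed `config$seed`.
#'
#' @param pairs list of `feature_pair`, or the result of
#'   [stack_feature_pairs()]
#' @param labels character stage labels, one per pair
#' @param which "etn" or "otn"
#' @param config a [training_config()]
#' @return object of class `subnet_fit`: list with `params`, `history`
#'   (data.frame epoch/loss/accuracy), `which`, `config`
#' @export
train_subnetwork <- function(pairs, labels, which = c("etn", "otn"),
                             config = training_config()) {
  which <- match.arg(which)
  stacked <- if (is.list(pairs) && !is.null(pairs$eeg)) pairs
             else stack_feature_pairs(pairs)
  y <- stage_index(labels)
  N <- length(y)
  stopifnot(N >= 1L)
  miss <- setdiff(stage_levels(), unique(labels))
  if (length(miss) > 0L)
    stop("class(es) absent from training data: ",
         paste(miss, collapse = ", "))
  params <- if (which == "etn") etn_init(config$seed) else
    otn_init(config$seed)
  flat <- if (which == "etn") .etn_flat(params) else .otn_flat(params)
  adam <- .adam_init(flat)
  l2n <- .l2_names(flat)

  set.seed(config$seed)
  val_idx <- integer(0)
  if (config$val_fraction > 0) {
    val_idx <- sample.int(N, max(1L, round(config$val_fraction * N)))
  }
  tr_idx <- setdiff(seq_len(N), val_idx)
  best <- list(acc = -Inf, params = params)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     accuracy = numeric(0), val_accuracy = numeric(0))
  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    nb <- ceiling(length(ord) / config$batch_size)
    ep_loss <- 0; ep_hit <- 0L
    for (bi in seq_len(nb)) {
      take <- ord[((bi - 1L) * config$batch_size + 1L):
                    min(bi * config$batch_size, length(ord))]
      yb <- y[take]
      if (which == "etn") {
        fw <- etn_forward(stacked$eeg[, take, drop = FALSE], params,
                          train = TRUE)
      } else {
        fw <- otn_forward(stacked$eog[, , take, drop = FALSE], params)
      }
      lb <- .focal_batch(fw$logits, yb, config$alpha, config$gamma)
      if (!is.finite(lb$loss)) stop("divergent loss (non-finite)")
      grads <- if (which == "etn") .etn_backward(params, fw, lb$dZ) else
        .otn_backward(params, fw, lb$dZ)
      gflat <- if (which == "etn") .etn_flat_grads(grads) else
        .otn_flat_grads(grads)
      for (nm in l2n) gflat[[nm]] <- gflat[[nm]] + config$l2 * flat[[nm]]
      st <- .adam_step(flat, gflat, adam, config$lr)
      flat <- st$params
      adam <- st$state
      params <- if (which == "etn") .etn_unflat(params, flat) else
        .otn_unflat(params, flat)
      if (which == "etn") {
        for (nm in names(params$layers))
          if (!is.null(params$layers[[nm]]$W))
            params$layers[[nm]] <- .bn_update_running(params$layers[[nm]],
                                                      fw$cache[[nm]])
      }
      ep_loss <- ep_loss + lb$loss * length(take)
      ep_hit <- ep_hit + sum(apply(lb$probs, 2L, which.max) == yb)
    }
    val_acc <- NA_real_
    if (length(val_idx) > 0L) {
      pv <- .subnet_probs(params, which, stacked, val_idx)
      val_acc <- mean(apply(pv, 2L, which.max) == y[val_idx])
      if (val_acc >= best$acc) best <- list(acc = val_acc, params = params)
    }
    hist <- rbind(hist, data.frame(epoch = ep,
                                   loss = ep_loss / length(tr_idx),
                                   accuracy = ep_hit / length(tr_idx),
                                   val_accuracy = val_acc))
  }
  if (length(val_idx) > 0L && is.finite(best$acc)) params <- best$params
  structure(list(params = params, history = hist, which = which,
                 config = config), class = "subnet_fit")
}

.subnet_probs <- function(params, which, stacked, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(
    if (which == "etn") ncol(stacked$eeg) else dim(stacked$eog)[3L])
  if (which == "etn")
    etn_forward(stacked$eeg[, idx, drop = FALSE], params)$class_probs
  else
    otn_forward(stacked$eog[, , idx, drop = FALSE], params)$class_probs
}

#' @export
print.subnet_fit <- function(x, ...) {
  h <- x$history
  cat("<subnet_fit> ", toupper(x$which), ", ", nrow(h), " epoch(s), final ",
      "loss ", format(h$loss[nrow(h)], digits = 4), ", train acc ",
      format(h$accuracy[nrow(h)], digits = 3), "\n", sep = "")
  invisible(x)
}

#' Predict stage probabilities with a trained subnetwork
#'
#' @param fit a `subnet_fit`
#' @param pairs list of `feature_pair` or stacked arrays
#' @return list with `probs` (5 x N), `features` (fusion features),
#'   `labels` (predicted stage names)
#' @export
predict_subnet <- function(fit, pairs) {
  stacked <- if (is.list(pairs) && !is.null(pairs$eeg)) pairs
             else stack_feature_pairs(pairs)
  fw <- if (fit$which == "etn")
    etn_forward(stacked$eeg, fit$params) else
    otn_forward(stacked$eog, fit$params)
  list(probs = fw$class_probs, features = fw$features,
       labels = stage_from_index(apply(fw$class_probs, 2L, which.max)))
}
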