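# End-to-end orchestration: feature extraction over epoch lists, subnetwork
# training, DBN fusion, prediction, and the scaled experiment harness.

#' Pipeline configuration
#'
#' One declarative object covering every stage. Defaults are the reference
#' training protocol (Adam 1e-3, minibatch 128, 50 epochs, focal alpha/gamma,
#' CD-1 pretraining); scale `subnet_epochs` / `fusion_epochs` down for
#' small corpora.
#'
#' @param feature_method "hht" (adaptive) or "cwt" (wavelet baseline)
#' @param normalize feature scaling, "epoch" or "none"
#' @param subnet_epochs training epochs for each subnetwork
#' @param fusion_epochs fine-tuning epochs for the DBN head
#' @param pretrain_epochs CD-1 epochs per RBM layer
#' @param lr learning rate (all stages)
#' @param batch_size subnetwork minibatch
#' @param fusion_batch_size fusion-stage minibatch
#' @param alpha,gamma focal-loss parameters
#' @param l2 weight decay for the subnetworks
#' @param seed master seed; every stage derives its stream from it
#' @param unfreeze_subnets if TRUE, a joint fine-tuning pass backpropagates
#'   the fusion loss into the subnetworks (default: frozen extractors)
#' @param val_fraction passed to [training_config()]
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(feature_method = "hht", normalize = "epoch",
                            subnet_epochs = 50L, fusion_epochs = 50L,
                            pretrain_epochs = 10L, lr = 1e-3,
                            batch_size = 128L, fusion_batch_size = 32L,
                            alpha = focal_params()$alpha, gamma = 2,
                            l2 = 1e-4, seed = 1L,
                            unfreeze_subnets = FALSE, val_fraction = 0) {
  structure(list(feature_method = feature_method, normalize = normalize,
                 subnet_epochs = as.integer(subnet_epochs),
                 fusion_epochs = as.integer(fusion_epochs),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 lr = lr, batch_size = as.integer(batch_size),
                 fusion_batch_size = as.integer(fusion_batch_size),
                 alpha = alpha, gamma = gamma, l2 = l2,
                 seed = as.integer(seed),
                 unfreeze_subnets = isTRUE(unfreeze_subnets),
                 val_fraction = val_fraction),
            class = "pipeline_config")
}

#' Extract feature pairs for a list of epochs
#'
#' @param epochs list of `sleep_epoch`
#' @param method "hht" or "cwt"
#' @param normalize "epoch" or "none"
#' @return list of `feature_pair`
#' @export
extract_features <- function(epochs, method = "hht", normalize = "epoch") {
  lapply(epochs, feature_pair, method = method, normalize = normalize)
}

# concatenated subnetwork features, samples in rows: 384 (EEG) + 200 (EOG)
.fuse_features <- function(etn_feats, otn_feats) {
  cbind(t(etn_feats), t(otn_feats))
}

#' Train the full fusion pipeline on a set of subjects
#'
#' Extracts features, trains the EEG and EOG subnetworks with focal loss,
#' concatenates their 384- and 200-dimensional feature vectors into the
#' 584-dimensional fusion input, pretrains the DBN stack greedily with CD-1
#' on the standardized features, and fine-tunes with cross-entropy. With
#' `config$unfreeze_subnets` an additional joint pass backpropagates the
#' fusion loss into the subnetworks.
#'
#' @param subjects list of subjects (each: `subject_id`, `epochs`)
#' @param config a [pipeline_config()]
#' @return object of class `pipeline_fit`
#' @export
train_pipeline <- function(subjects, config = pipeline_config()) {
  epochs <- unlist(lapply(subjects, `[[`, "epochs"), recursive = FALSE)
  labels <- vapply(epochs, `[[`, "", "label")
  pairs <- extract_features(epochs, config$feature_method, config$normalize)
  stacked <- stack_feature_pairs(pairs)
  etn_fit <- train_subnetwork(
    stacked, labels, "etn",
    training_config(lr = config$lr, batch_size = config$batch_size,
                    epochs = config$subnet_epochs, alpha = config$alpha,
                    gamma = config$gamma, l2 = config$l2,
                    seed = config$seed, val_fraction = config$val_fraction))
  otn_fit <- train_subnetwork(
    stacked, labels, "otn",
    training_config(lr = config$lr, batch_size = config$batch_size,
                    epochs = config$subnet_epochs, alpha = config$alpha,
                    gamma = config$gamma, l2 = config$l2,
                    seed = config$seed + 1L,
                    val_fraction = config$val_fraction))
  fe <- predict_subnet(etn_fit, stacked)
  fo <- predict_subnet(otn_fit, stacked)
  FF <- .fuse_features(fe$features, fo$features)
  mu <- colMeans(FF)
  s <- apply(FF, 2L, stats::sd); s[s < 1e-8] <- 1
  scaler <- list(mean = mu, sd = s)
  Fs <- sweep(sweep(FF, 2L, mu), 2L, s, "/")
  dbn <- pretrain_dbn(Fs, epochs_per_layer = config$pretrain_epochs,
                      seed = config$seed + 2L, lr = config$lr,
                      batch_size = config$fusion_batch_size)
  clf <- finetune(FF, labels, dbn,
                  fusion_config(lr = config$lr,
                                epochs = config$fusion_epochs,
                                batch_size = config$fusion_batch_size,
                                seed = config$seed + 3L),
                  standardize = scaler)
  fit <- structure(list(etn = etn_fit, otn = otn_fit, classifier = clf,
                        config = config), class = "pipeline_fit")
  if (config$unfreeze_subnets)
    fit <- .joint_finetune(fit, stacked, labels)
  fit
}

# joint fine-tuning: backpropagate the fusion cross-entropy through the DBN
# into both subnetworks (one extra pass at the fusion learning rate).
.joint_finetune <- function(fit, stacked, labels) {
  config <- fit$config
  y <- stage_index(labels)
  N <- length(y)
  etn_p <- fit$etn$params; otn_p <- fit$otn$params
  clf <- fit$classifier
  flat <- c(.etn_flat(etn_p), .otn_flat(otn_p), .dbn_flat(clf$dbn))
  names(flat) <- make.unique(names(flat))
  adam <- .adam_init(flat)
  set.seed(config$seed + 4L)
  ne <- length(.etn_flat(etn_p)); no <- length(.otn_flat(otn_p))
  for (ep in seq_len(max(1L, config$fusion_epochs %/% 2L))) {
    ord <- sample.int(N)
    nb <- ceiling(N / config$fusion_batch_size)
    for (bi in seq_len(nb)) {
      take <- ord[((bi - 1L) * config$fusion_batch_size + 1L):
                    min(bi * config$fusion_batch_size, N)]
      fe <- etn_forward(stacked$eeg[, take, drop = FALSE], etn_p,
                        train = TRUE)
      fo <- otn_forward(stacked$eog[, , take, drop = FALSE], otn_p)
      FF <- .fuse_features(fe$features, fo$features)
      Xs <- sweep(sweep(FF, 2L, clf$scaler$mean), 2L, clf$scaler$sd, "/")
      fw <- .dbn_forward(clf$dbn, Xs)
      lb <- .ce_batch(fw$logits, y[take])
      if (!is.finite(lb$loss)) stop("divergent loss (non-finite)")
      gd <- .dbn_backward(clf$dbn, fw, lb$dZ, t(Xs), want_input_grad = TRUE)
      dFF <- t(gd$dV0) / matrix(clf$scaler$sd, nrow(FF), ncol(FF),
                                byrow = TRUE)
      dEt <- t(dFF[, 1:384, drop = FALSE])
      dOt <- t(dFF[, 385:584, drop = FALSE])
      ge <- .etn_backward(etn_p, fe, lb$dZ * 0, dFeatures = dEt)
      go <- .otn_backward(otn_p, fo, lb$dZ * 0, dFeatures = dOt)
      gflat <- c(.etn_flat_grads(ge), .otn_flat_grads(go), gd$grads)
      names(gflat) <- names(flat)
      st <- .adam_step(flat, gflat, adam, config$lr)
      flat <- st$params
      adam <- st$state
      etn_p <- .etn_unflat(etn_p, flat[seq_len(ne)])
      otn_p <- .otn_unflat(otn_p, stats::setNames(
        flat[ne + seq_len(no)], names(.otn_flat(otn_p))))
      clf$dbn <- .dbn_unflat(clf$dbn, stats::setNames(
        flat[(ne + no + 1L):length(flat)], names(.dbn_flat(clf$dbn))))
      for (nm in names(etn_p$layers))
        if (!is.null(etn_p$layers[[nm]]$W))
          etn_p$layers[[nm]] <- .bn_update_running(etn_p$layers[[nm]],
                                                   fe$cache[[nm]])
    }
  }
  fit$etn$params <- etn_p
  fit$otn$params <- otn_p
  fit$classifier <- clf
  fit
}

#' Predict stages for a list of epochs with a trained pipeline
#'
#' @param fit a `pipeline_fit`
#' @param epochs list of `sleep_epoch`
#' @param pairs optional precomputed feature pairs (skips extraction)
#' @return list with `labels` (fused prediction), `probs` (5 x N),
#'   `labels_etn`, `labels_otn` (single-modality predictions)
#' @export
predict_pipeline <- function(fit, epochs, pairs = NULL) {
  if (is.null(pairs))
    pairs <- extract_features(epochs, fit$config$feature_method,
                              fit$config$normalize)
  stacked <- stack_feature_pairs(pairs)
  pe <- predict_subnet(fit$etn, stacked)
  po <- predict_subnet(fit$otn, stacked)
  FF <- .fuse_features(pe$features, po$features)
  probs <- predict_stage(FF, fit$classifier)
  list(labels = stage_from_index(apply(probs, 2L, which.max)),
       probs = probs, labels_etn = pe$labels, labels_otn = po$labels)
}

#' @export
print.pipeline_fit <- function(x, ...) {
  cat("<pipeline_fit> features:", x$config$feature_method,
      "| subnet epochs:", x$config$subnet_epochs,
      "| fusion epochs:", x$config$fusion_epochs, "\n")
  invisible(x)
}

#' Run one scaled synthetic fusion experiment
#'
#' Generates a synthetic multi-subject dataset, holds out one subject,
#' trains the full pipeline on the rest, and scores the fused model and
#' both single-modality subnetworks on the held-out subject. This is the
#' package's standard end-to-end check that multimodal fusion beats either
#' modality alone.
#'
#' @param n_subjects,epochs_per_subject dataset size
#' @param preset generator preset
#' @param seed master seed (dataset and training)
#' @param config a [pipeline_config()]; its seed is overridden by `seed`
#' @param test_subject index of the held-out subject (default: rotates
#'   with the seed)
#' @return list with `accuracy_fused`, `accuracy_etn`, `accuracy_otn`
#'   (percent), `kappa`, `macro_f1`, `cm`, `truth`, `pred`, `fit`
#' @export
run_experiment <- function(n_subjects = 5L, epochs_per_subject = 200L,
                           preset = "sleep-edf-like", seed = 1L,
                           config = pipeline_config(subnet_epochs = 10L,
                                                    fusion_epochs = 5L),
                           test_subject = NULL) {
  config$seed <- as.integer(seed)
  ds <- generate_dataset(n_subjects, epochs_per_subject, preset = preset,
                         seed = seed)
  if (is.null(test_subject))
    test_subject <- (seed %% n_subjects) + 1L
  train_subj <- ds$subjects[-test_subject]
  test_ep <- ds$subjects[[test_subject]]$epochs
  fit <- train_pipeline(train_subj, config)
  pr <- predict_pipeline(fit, test_ep)
  truth <- vapply(test_ep, `[[`, "", "label")
  cm <- confusion_matrix(truth, pr$labels)
  list(accuracy_fused = 100 * mean(pr$labels == truth),
       accuracy_etn = 100 * mean(pr$labels_etn == truth),
       accuracy_otn = 100 * mean(pr$labels_otn == truth),
       kappa = kappa_statistic(cm),
       macro_f1 = suppressWarnings(per_class_f1(cm))$macro,
       cm = cm, truth = truth, pred = pr$labels,
       test_subject = test_subject, fit = fit)
}

#' Multi-seed fusion benchmark on one synthetic dataset
#'
#' Generates the synthetic corpus once (fixed `data_seed`), extracts features
#' once, then repeats training across `train_seeds`, each time holding out a
#' different subject (subject-wise fold). Reports, per seed, the held-out
#' accuracy of the fused model and of each single-modality subnetwork on the
#' same fold -- the package's standard check that multimodal fusion beats
#' either modality alone.
#'
#' @param n_subjects,epochs_per_subject,preset dataset specification
#' @param data_seed seed for the synthetic corpus
#' @param train_seeds integer vector of training seeds (one run per seed)
#' @param config a [pipeline_config()] template (its seed is overridden)
#' @return data.frame with one row per seed: accuracy_fused, accuracy_etn,
#'   accuracy_otn (percent), kappa, macro_f1, test_subject
#' @export
run_fusion_benchmark <- function(n_subjects = 5L, epochs_per_subject = 200L,
                                 preset = "sleep-edf-like", data_seed = 1L,
                                 train_seeds = 1:5,
                                 config = pipeline_config(
                                   subnet_epochs = 10L, fusion_epochs = 5L)) {
  ds <- generate_dataset(n_subjects, epochs_per_subject, preset = preset,
                         seed = data_seed)
  feats <- lapply(ds$subjects, function(s)
    extract_features(s$epochs, config$feature_method, config$normalize))
  labels <- lapply(ds$subjects, `[[`, "labels")
  rows <- list()
  for (k in seq_along(train_seeds)) {
    seed <- train_seeds[k]
    test_subject <- ((seed - 1L) %% n_subjects) + 1L
    cfg <- config
    cfg$seed <- as.integer(seed)
    tr_pairs <- unlist(feats[-test_subject], recursive = FALSE)
    tr_labels <- unlist(labels[-test_subject])
    fit <- .train_pipeline_on_features(tr_pairs, tr_labels, cfg)
    pr <- predict_pipeline(fit, epochs = NULL, pairs = feats[[test_subject]])
    truth <- labels[[test_subject]]
    cm <- confusion_matrix(truth, pr$labels)
    rows[[k]] <- data.frame(
      seed = seed, test_subject = test_subject,
      accuracy_fused = 100 * mean(pr$labels == truth),
      accuracy_etn = 100 * mean(pr$labels_etn == truth),
      accuracy_otn = 100 * mean(pr$labels_otn == truth),
      kappa = kappa_statistic(cm),
      macro_f1 = suppressWarnings(per_class_f1(cm))$macro)
  }
  do.call(rbind, rows)
}

# core of train_pipeline, starting from precomputed feature pairs
.train_pipeline_on_features <- function(pairs, labels, config) {
  stacked <- stack_feature_pairs(pairs)
  etn_fit <- train_subnetwork(
    stacked, labels, "etn",
    training_config(lr = config$lr, batch_size = config$batch_size,
                    epochs = config$subnet_epochs, alpha = config$alpha,
                    gamma = config$gamma, l2 = config$l2,
                    seed = config$seed, val_fraction = config$val_fraction))
  otn_fit <- train_subnetwork(
    stacked, labels, "otn",
    training_config(lr = config$lr, batch_size = config$batch_size,
                    epochs = config$subnet_epochs, alpha = config$alpha,
                    gamma = config$gamma, l2 = config$l2,
                    seed = config$seed + 1L,
                    val_fraction = config$val_fraction))
  fe <- predict_subnet(etn_fit, stacked)
  fo <- predict_subnet(otn_fit, stacked)
  FF <- .fuse_features(fe$features, fo$features)
  mu <- colMeans(FF)
  s <- apply(FF, 2L, stats::sd); s[s < 1e-8] <- 1
  scaler <- list(mean = mu, sd = s)
  Fs <- sweep(sweep(FF, 2L, mu), 2L, s, "/")
  dbn <- pretrain_dbn(Fs, epochs_per_layer = config$pretrain_epochs,
                      seed = config$seed + 2L, lr = config$lr,
                      batch_size = config$fusion_batch_size)
  clf <- finetune(FF, labels, dbn,
                  fusion_config(lr = config$lr,
                                epochs = config$fusion_epochs,
                                batch_size = config$fusion_batch_size,
                                seed = config$seed + 3L),
                  standardize = scaler)
  fit <- structure(list(etn = etn_fit, otn = otn_fit, classifier = clf,
                        config = config), class = "pipeline_fit")
  if (config$unfreeze_subnets)
    fit <- .joint_finetune(fit, stacked, labels)
  fit
}

#' Save / load a trained pipeline checkpoint
#'
#' The checkpoint is a single serialized archive holding all weights, the
#' full configuration, and the training seed, sufficient to reproduce
#' predictions exactly.
#'
#' @param fit a `pipeline_fit`
#' @param path file path (.rds)
#' @return `path` / the restored `pipeline_fit`
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(list(format = "sleepfusion-checkpoint-v1", fit = fit), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "sleepfusion-checkpoint-v1"))
    stop("not a sleepfusion checkpoint: ", path)
  x$fit
}
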