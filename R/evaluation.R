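# Scoring: confusion matrix in the scoring order W, REM, N1, N2, N3,
# Cohen's kappa, overall accuracy, per-class F1, and the subject-wise
# cross-validation harness.

#' Confusion matrix of sleep-stage predictions
#'
#' Entry S_ij counts epochs whose true stage is i and predicted stage is j,
#' with classes ordered W, REM, N1, N2, N3 (the scoring-matrix convention
#' used throughout).
#'
#' @param truth,pred character stage labels (equal length, >= 1)
#' @return 5 x 5 integer matrix of class `stage_confusion`
#' @export
confusion_matrix <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("truth and pred must have equal length")
  if (length(truth) < 1L) stop("empty label lists")
  lev <- stage_levels()
  S <- table(factor(truth, levels = lev), factor(pred, levels = lev))
  S <- matrix(as.integer(S), 5L, 5L, dimnames = list(truth = lev, pred = lev))
  structure(S, class = c("stage_confusion", "matrix"))
}

#' @export
print.stage_confusion <- function(x, ...) {
  cat("Stage confusion matrix (rows = truth, cols = predicted)\n")
  print(unclass(x))
  cat(sprintf("accuracy %.2f%%, kappa %.3f\n",
              overall_accuracy(x), kappa_statistic(x)))
  invisible(x)
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement (P0 - Pe) / (1 - Pe), with P0 the observed
#' agreement (trace / total) and Pe the expected agreement under
#' independent marginals (sum of row-sum x column-sum products / total^2).
#'
#' @param cm confusion matrix (counts)
#' @return scalar kappa (<= 1); errors when Pe = 1 (all mass in one
#'   agreeing cell), where kappa is undefined
#' @export
kappa_statistic <- function(cm) {
  S <- unclass(cm)
  n <- sum(S)
  stopifnot(n > 0)
  p0 <- sum(diag(S)) / n
  pe <- sum(rowSums(S) * colSums(S)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4)
    stop("kappa undefined: expected agreement Pe = 1")
  (p0 - pe) / (1 - pe)
}

#' Overall accuracy (percent) from a confusion matrix
#'
#' @param cm confusion matrix (counts)
#' @return percentage in 0..100: 100 * trace / total
#' @export
overall_accuracy <- function(cm) {
  S <- unclass(cm)
  n <- sum(S)
  stopifnot(n > 0)
  100 * sum(diag(S)) / n
}

#' Per-class F1 scores and macro mean
#'
#' Precision from columns, recall from rows, F1 = 2PR/(P+R). A class with
#' zero support in both truth and predictions gets F1 = 0 with a warning.
#'
#' @param cm confusion matrix (counts)
#' @return list with `f1` (named 5-vector) and `macro` (mean)
#' @export
per_class_f1 <- function(cm) {
  S <- unclass(cm)
  stopifnot(sum(S) > 0)
  tp <- diag(S)
  prec <- ifelse(colSums(S) > 0, tp / colSums(S), 0)
  rec <- ifelse(rowSums(S) > 0, tp / rowSums(S), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  empty <- rowSums(S) == 0 & colSums(S) == 0
  if (any(empty))
    warning("class(es) with zero support: ",
            paste(rownames(S)[empty], collapse = ", "), "; F1 set to 0")
  names(f1) <- rownames(S)
  list(f1 = f1, macro = mean(f1))
}

#' Subject-wise leave-one-out cross-validation
#'
#' Splits epochs by subject (no subject ever appears in both the training
#' and test side of a fold), trains the full pipeline on each training
#' side, and scores the held-out subject. Optionally only a random subset
#' of folds is evaluated and reported (the protocol of scoring a random
#' selection of held-out subjects).
#'
#' @param dataset list with `subjects`, each a list with `subject_id`,
#'   `epochs` (list of `sleep_epoch`); e.g. from [generate_dataset()]
#' @param config pipeline configuration from [pipeline_config()]
#' @param n_report number of folds to evaluate (default: all); selected at
#'   random under `config$seed` when fewer than the subject count
#' @return object of class `cv_result`: list with `folds` (per-fold metric
#'   data.frame), `pooled_cm` (sum of fold confusion matrices), `pooled`
#'   metrics list, `fold_cms`
#' @export
cross_validate <- function(dataset, config = pipeline_config(),
                           n_report = NULL) {
  subjects <- dataset$subjects
  ns <- length(subjects)
  if (ns < 2L) stop("cross-validation needs at least 2 subjects")
  folds <- seq_len(ns)
  if (!is.null(n_report) && n_report < ns)
    folds <- sort(with_seed(config$seed, sample.int(ns, n_report)))
  fold_rows <- list()
  fold_cms <- list()
  for (k in folds) {
    fit <- train_pipeline(subjects[-k], config)
    pr <- predict_pipeline(fit, subjects[[k]]$epochs)
    truth <- vapply(subjects[[k]]$epochs, `[[`, "", "label")
    cm <- confusion_matrix(truth, pr$labels)
    fold_cms[[length(fold_cms) + 1L]] <- cm
    f1 <- suppressWarnings(per_class_f1(cm))
    fold_rows[[length(fold_rows) + 1L]] <- data.frame(
      fold = k, subject = subjects[[k]]$subject_id,
      n_test = length(truth),
      accuracy = overall_accuracy(cm),
      kappa = kappa_statistic(cm),
      macro_f1 = f1$macro,
      accuracy_etn = 100 * mean(pr$labels_etn == truth),
      accuracy_otn = 100 * mean(pr$labels_otn == truth))
  }
  folds_df <- do.call(rbind, fold_rows)
  pooled_cm <- Reduce(`+`, lapply(fold_cms, unclass))
  pooled_cm <- structure(pooled_cm, class = c("stage_confusion", "matrix"))
  pooled <- list(accuracy = overall_accuracy(pooled_cm),
                 kappa = kappa_statistic(pooled_cm),
                 macro_f1 = suppressWarnings(per_class_f1(pooled_cm))$macro)
  structure(list(folds = folds_df, fold_cms = fold_cms,
                 pooled_cm = pooled_cm, pooled = pooled),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", nrow(x$folds), " fold(s)\n", sep = "")
  print(x$folds, row.names = FALSE)
  cat(sprintf("pooled: accuracy %.2f%%, kappa %.3f, macro F1 %.3f\n",
              x$pooled$accuracy, x$pooled$kappa, x$pooled$macro_f1))
  invisible(x)
}
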