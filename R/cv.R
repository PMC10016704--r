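#' Confusion matrix with fixed class order
#'
#' @param true,pred Character vectors of true and predicted labels.
#' @param classes Class order for rows (true) and columns (predicted).
#' @return C x C integer matrix.
#' @export
confusion_matrix <- function(true, pred, classes = cytomil_classes()) {
  tab <- table(factor(true, levels = classes),
               factor(pred, levels = classes))
  m <- matrix(as.integer(tab), length(classes), length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

#' Per-class F1 scores from a confusion matrix
#'
#' `F1_i = 2 TP / (2 TP + FP + FN)`; defined as `NA` when a class has no
#' true or predicted members at all.
#'
#' @param cm Confusion matrix (rows = true, columns = predicted).
#' @return Named numeric vector of per-class F1 scores.
#' @export
f1_scores <- function(cm) {
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  denom <- 2 * tp + fp + fn
  f1 <- ifelse(denom == 0, NA_real_, 2 * tp / denom)
  stats::setNames(f1, rownames(cm))
}

# Area under the precision-recall curve by the step-wise (average
# precision) rule: AP = sum over positives of precision at each recall
# increment.
pr_auc <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  sum(precision[y == 1]) / sum(y)
}

# One-vs-rest ROC-AUC (via pROC) and PR-AUC for each class from a pooled
# probability matrix.
ovr_aucs <- function(true, prob, classes) {
  res <- lapply(classes, function(cl) {
    y <- as.integer(true == cl)
    if (length(unique(y)) < 2L) return(c(roc_auc = NA_real_, pr_auc = NA_real_))
    roc <- pROC::roc(y, prob[, cl], quiet = TRUE,
                     direction = "<", levels = c(0, 1))
    c(roc_auc = as.numeric(pROC::auc(roc)), pr_auc = pr_auc(y, prob[, cl]))
  })
  m <- do.call(rbind, res)
  rownames(m) <- classes
  m
}

#' Cross-validated training and pooled evaluation
#'
#' Trains one MIL model per fold on that fold's train/validation patients
#' and predicts its held-out test patients; because the folds' test sets
#' partition the cohort, pooling the test predictions counts every patient
#' exactly once. Reports the pooled confusion matrix, per-class F1 both
#' pooled and as mean +/- s.d. over folds, and pooled one-vs-rest ROC-AUC
#' and precision-recall AUC per class.
#'
#' @param bags List of [new_bag()] objects.
#' @param manifest `data.frame` with `patient_id` and `label` (one row per
#'   bag); defaults to a minimal manifest derived from the bags.
#' @param cfg A [mil_config()].
#' @param k Number of folds.
#' @param seed Seed for the fold split (model training uses `cfg$seed`
#'   offset per fold).
#' @param verbose Print per-fold progress.
#' @return List of class `cytomil_cv` with elements `confusion`,
#'   `f1_pooled`, `macro_f1`, `f1_by_fold` (k x C matrix), `f1_mean`,
#'   `f1_sd`, `aucs` (per-class ROC/PR AUC), `predictions` (data.frame of
#'   pooled test predictions with probability columns), `folds`,
#'   `models` (per-fold `mil_params`), and `config`.
#' @export
cross_validate <- function(bags, manifest = NULL, cfg = mil_config(),
                           k = 5L, seed = 1L, verbose = FALSE) {
  ids <- vapply(bags, function(b) b$patient_id, character(1))
  if (is.null(manifest)) {
    manifest <- data.frame(patient_id = ids,
                           label = vapply(bags, function(b) b$label,
                                          character(1)),
                           stringsAsFactors = FALSE)
  }
  folds <- make_folds(manifest, k = k, seed = seed)
  classes <- cfg$classes
  models <- vector("list", k)
  pred_rows <- vector("list", k)
  f1_by_fold <- matrix(NA_real_, k, length(classes),
                       dimnames = list(NULL, classes))

  for (f in seq_len(k)) {
    fold_cfg <- cfg
    fold_cfg$seed <- child_seed(cfg$seed, paste0("fold", f))
    fit <- train_mil(bags, folds[[f]], fold_cfg)
    models[[f]] <- fit$params
    test_bags <- bags[ids %in% folds[[f]]$test]
    preds <- lapply(test_bags, mil_forward, params = fit$params)
    prob <- do.call(rbind, lapply(preds, function(p) p$p))
    df <- data.frame(
      patient_id = vapply(test_bags, function(b) b$patient_id, character(1)),
      true = vapply(test_bags, function(b) b$label, character(1)),
      pred = vapply(preds, function(p) p$label, character(1)),
      fold = f, stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(prob))
    pred_rows[[f]] <- df
    f1_by_fold[f, ] <- f1_scores(confusion_matrix(df$true, df$pred, classes))
    if (verbose) {
      message(sprintf("fold %d: best epoch %d, test accuracy %.3f",
                      f, fit$best_epoch, mean(df$true == df$pred)))
    }
  }

  predictions <- do.call(rbind, pred_rows)
  cm <- confusion_matrix(predictions$true, predictions$pred, classes)
  f1p <- f1_scores(cm)
  aucs <- ovr_aucs(predictions$true,
                   as.matrix(predictions[, classes, drop = FALSE]), classes)
  structure(list(
    confusion = cm,
    f1_pooled = f1p,
    macro_f1 = mean(f1p, na.rm = TRUE),
    f1_by_fold = f1_by_fold,
    f1_mean = colMeans(f1_by_fold, na.rm = TRUE),
    f1_sd = apply(f1_by_fold, 2L, stats::sd, na.rm = TRUE),
    aucs = aucs,
    predictions = predictions,
    folds = folds,
    models = models,
    config = cfg
  ), class = "cytomil_cv")
}

#' @export
print.cytomil_cv <- function(x, ...) {
  cat("<cytomil_cv> pooled confusion matrix:\n")
  print(x$confusion)
  cat(sprintf("macro F1 (pooled): %.3f\n", x$macro_f1))
  f1 <- sprintf("%s %.2f+/-%.2f", names(x$f1_mean), x$f1_mean, x$f1_sd)
  cat("per-class F1 over folds:", paste(f1, collapse = ", "), "\n")
  invisible(x)
}

#' Binary AML-versus-control accuracy
#'
#' Collapses multi-class predictions to "AML" (any non-control class)
#' versus "control" and returns the accuracy of that binary decision.
#'
#' @param predictions `data.frame` with `true` and `pred` columns (e.g.
#'   `cross_validate(...)$predictions`).
#' @param control_label Label of the control class.
#' @return Single numeric accuracy in `[0, 1]`.
#' @export
aml_vs_control_accuracy <- function(predictions, control_label = "control") {
  mean((predictions$true == control_label) ==
         (predictions$pred == control_label))
}
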