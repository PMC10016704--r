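#' Per-patient cellular composition report
#'
#' Builds the data behind the per-patient composition bar plots: for every
#' patient, cells ordered by the attention they received for the bag's
#' predicted class (low to high), each with its individual predicted
#' class; patients ordered by the bag-level output activation of their
#' predicted class, strongest first, with the bag prediction and a
#' correctness flag attached.
#'
#' @param bag_preds List of `bag_prediction`s from [mil_forward()] (with
#'   `patient_id`, `cell_ids`, `true_label`).
#' @param instance_preds `data.frame` of pooled [predict_instances()]
#'   rows covering the same cells.
#' @return List with `patients` (data.frame: patient_id, pred, true,
#'   correct, activation -- ordered by decreasing activation) and `cells`
#'   (data.frame: patient_id, order, cell_id, attention, cell_pred).
#' @export
composition_report <- function(bag_preds, instance_preds) {
  pat <- do.call(rbind, lapply(bag_preds, function(bp) {
    data.frame(patient_id = bp$patient_id, pred = bp$label,
               true = bp$true_label %||% NA_character_,
               correct = identical(bp$label, bp$true_label),
               activation = unname(bp$p[bp$label_index]),
               stringsAsFactors = FALSE)
  }))
  pat <- pat[order(-pat$activation), ]
  cells <- do.call(rbind, lapply(bag_preds, function(bp) {
    rk <- rank_by_attention(bp)
    m <- match(rk$cell_id, instance_preds$cell_id)
    data.frame(patient_id = bp$patient_id, order = rk$rank,
               cell_id = rk$cell_id, attention = rk$attention,
               cell_pred = instance_preds$pred[m],
               stringsAsFactors = FALSE)
  }))
  list(patients = pat, cells = cells)
}

#' Serialize cross-validation metrics
#'
#' Writes a deterministic JSON bundle of the cross-validation results --
#' per-class F1 mean and standard deviation over folds, pooled F1 and
#' macro F1, the pooled confusion matrix, pooled one-vs-rest ROC and
#' precision-recall AUCs, and optionally the consort (QC accounting)
#' report -- plus the confusion matrix as CSV.
#'
#' @param cv A `cytomil_cv` from [cross_validate()].
#' @param out_dir Output directory.
#' @param consort Optional `consort_report` to echo into the bundle.
#' @return Named list of written file paths, invisibly.
#' @export
report_metrics <- function(cv, out_dir, consort = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list(
    classes = cv$config$classes,
    f1_mean = as.list(cv$f1_mean),
    f1_sd = as.list(cv$f1_sd),
    f1_pooled = as.list(cv$f1_pooled),
    macro_f1 = cv$macro_f1,
    roc_auc = as.list(stats::setNames(cv$aucs[, "roc_auc"],
                                      rownames(cv$aucs))),
    pr_auc = as.list(stats::setNames(cv$aucs[, "pr_auc"],
                                     rownames(cv$aucs))),
    aml_vs_control_accuracy = aml_vs_control_accuracy(cv$predictions),
    confusion = lapply(seq_len(nrow(cv$confusion)),
                       function(i) as.list(cv$confusion[i, ]))
  )
  if (!is.null(consort)) bundle$consort <- list(stages = consort$stages)
  json_path <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(bundle[order(names(bundle))], json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  csv_path <- file.path(out_dir, "confusion.csv")
  utils::write.csv(cv$confusion, csv_path)
  invisible(list(metrics = json_path, confusion = csv_path))
}
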