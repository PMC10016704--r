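#' Instance-level deconvolution of a bag
#'
#' Passes every cell of a bag through the trained model individually, as a
#' bag of size one. The resulting per-cell class probabilities describe
#' the smear's cellular composition in terms of the bag-level classes,
#' without any cell-level annotation. For a size-one bag the attention is
#' trivially 1, so the instance prediction is exactly the bag prediction
#' restricted to that cell.
#'
#' @param params Trained [mil_init()] parameters.
#' @param bag A [new_bag()] object.
#' @return `data.frame` with one row per cell: `cell_id`, `patient_id`,
#'   `pred`, `pred_prob`, plus one probability column per class, in bag
#'   order.
#' @export
predict_instances <- function(params, bag) {
  # a size-1 bag's forward pass reduces to: h = f_emb(x); z_i = h;
  # s_i = u(_i)' h + b_i -- so instance probabilities come straight from
  # the embedded feature, one softmax per cell
  H <- embed_instances(bag, params)
  S <- if (ncol(params$head_W) == 1L) {
    outer(params$head_b, drop(H %*% params$head_W), "+")         # C x N
  } else {
    sweep(t(params$head_W) %*% t(H), 1L, params$head_b, "+")
  }
  P <- t(apply(S, 2L, softmax))                                  # N x C
  colnames(P) <- params$classes
  k <- apply(P, 1L, which.max)
  out <- data.frame(cell_id = bag$cell_ids,
                    patient_id = bag$patient_id,
                    pred = params$classes[k],
                    pred_prob = P[cbind(seq_len(nrow(P)), k)],
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(P))
}

#' Order a bag's cells by attention
#'
#' Sorts cells ascending by the attention they received for the bag's
#' predicted class (low-attention cells first, as in the standard
#' composition bar plots). The sort is stable: ties keep bag order.
#'
#' @param prediction A `bag_prediction` from [mil_forward()] (must carry
#'   the attention row and cell ids).
#' @return `data.frame` with `rank`, `cell_id`, `bag_index`, `attention`.
#' @export
rank_by_attention <- function(prediction) {
  if (is.null(prediction$attention)) {
    stop_field("prediction", "carries no attention row")
  }
  a <- as.numeric(prediction$attention)
  ord <- order(a)  # radix sort on doubles: stable
  data.frame(rank = seq_along(a),
             cell_id = prediction$cell_ids[ord],
             bag_index = ord,
             attention = a[ord],
             stringsAsFactors = FALSE)
}

#' Attention-quartile versus annotation concordance
#'
#' Splits a bag's cells into four rank-based attention quartiles (sizes
#' differing by at most one, lowest attention = quartile 1) and summarizes
#' the annotated relevance-group composition of each quartile. If
#' `relevant_groups` is given, the aggregate "diagnostically relevant"
#' fraction per quartile is reported as well. Cells without an annotation
#' are counted separately and excluded from the fractions.
#'
#' @param ranked `data.frame` from [rank_by_attention()].
#' @param annotations `data.frame` with `cell_id` and `relevance_group`
#'   columns (open vocabulary); at most one row per cell.
#' @param relevant_groups Optional character vector naming the relevance
#'   groups that count as diagnostically relevant.
#' @return List of class `quartile_summary`: `counts` (cells per
#'   quartile), `composition` (4 x groups fraction matrix, rows sum to 1),
#'   `relevant_fraction` (length-4 vector or NULL), `boundaries`
#'   (attention values at quartile edges), `n_unannotated`.
#' @export
quartile_concordance <- function(ranked, annotations,
                                 relevant_groups = NULL) {
  if (anyDuplicated(annotations$cell_id)) {
    dup <- annotations$cell_id[duplicated(annotations$cell_id)][1L]
    stop(sprintf("ambiguous duplicate annotation for cell '%s'", dup),
         call. = FALSE)
  }
  m <- match(ranked$cell_id, annotations$cell_id)
  grp <- annotations$relevance_group[m]
  n <- nrow(ranked)
  # rank-based quartiles with sizes differing by <= 1
  q <- as.integer(ceiling(seq_len(n) / n * 4))
  keep <- !is.na(grp)
  groups <- sort(unique(grp[keep]))
  comp <- matrix(0, 4L, length(groups),
                 dimnames = list(paste0("Q", 1:4), groups))
  for (qq in 1:4) {
    sel <- keep & q == qq
    if (any(sel)) comp[qq, ] <- as.numeric(table(factor(grp[sel],
                                                        levels = groups)) /
                                             sum(sel))
  }
  rel <- NULL
  if (!is.null(relevant_groups)) {
    rel <- vapply(1:4, function(qq) {
      sel <- keep & q == qq
      if (!any(sel)) return(NA_real_)
      mean(grp[sel] %in% relevant_groups)
    }, numeric(1))
    names(rel) <- paste0("Q", 1:4)
  }
  structure(list(
    counts = as.integer(table(factor(q, levels = 1:4))),
    composition = comp,
    relevant_fraction = rel,
    boundaries = stats::quantile(ranked$attention, c(0.25, 0.5, 0.75)),
    n_unannotated = sum(!keep)
  ), class = "quartile_summary")
}

#' @export
print.quartile_summary <- function(x, ...) {
  cat("<quartile_summary> cells per quartile:",
      paste(x$counts, collapse = ", "), "\n")
  print(round(x$composition, 3))
  if (!is.null(x$relevant_fraction)) {
    cat("diagnostically relevant fraction:",
        paste(sprintf("%s=%.2f", names(x$relevant_fraction),
                      x$relevant_fraction), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Representative cells per class across folds
#'
#' For each class and each cross-validation fold, selects the `k_per_fold`
#' test-set cells with the highest instance-level output activation for
#' that class (ties broken deterministically by patient id then cell id)
#' and concatenates them across folds -- with 5 folds and the default
#' `k_per_fold = 2` this yields the "top 10 cells per class" gallery.
#'
#' @param instance_preds `data.frame` of instance predictions pooled over
#'   folds, with a `fold` column and one probability column per class
#'   (e.g. rbind of [predict_instances()] outputs plus `fold`).
#' @param classes Class labels to report.
#' @param k_per_fold Cells per class per fold.
#' @return `data.frame` with `class`, `fold`, `cell_id`, `patient_id`,
#'   `activation`, ordered by class then descending activation.
#' @export
representative_cells <- function(instance_preds,
                                 classes = cytomil_classes(),
                                 k_per_fold = 2L) {
  k_per_fold <- check_count(k_per_fold, "k_per_fold")
  out <- list()
  for (cl in classes) {
    for (f in sort(unique(instance_preds$fold))) {
      sub <- instance_preds[instance_preds$fold == f, ]
      if (nrow(sub) < k_per_fold) {
        warning(sprintf("fold %s has only %d candidate cells for class %s",
                        f, nrow(sub), cl))
      }
      ord <- order(-sub[[cl]], sub$patient_id, sub$cell_id)
      take <- utils::head(ord, k_per_fold)
      out[[length(out) + 1L]] <- data.frame(
        class = cl, fold = f,
        cell_id = sub$cell_id[take],
        patient_id = sub$patient_id[take],
        activation = sub[[cl]][take],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(match(res$class, classes), res$fold, -res$activation), ]
}

#' Classification robustness to subsampled bags
#'
#' Evaluates how bag classification degrades when only `s` of a patient's
#' cells are available: for every patient and every size `s` in `sizes`
#' (clipped to the bag size; the full size is always included), draws
#' `reps` random subsets without replacement, classifies each subset, and
#' reports the mean accuracy over patients per size plus the per-patient
#' mean true-class output activation. At `s = N` the subsample is the full
#' bag, so accuracy and activation reproduce the full-bag results exactly.
#' A "random cells from dataset" baseline draws cells across all patients,
#' ignoring patient ground truth.
#'
#' @param params Trained [mil_init()] parameters.
#' @param bags List of bags to evaluate (typically one fold's test set).
#' @param sizes Subsample-size ladder; sizes above a patient's bag size
#'   are skipped for that patient (the full bag size is always evaluated).
#' @param reps Random subsets per size and patient.
#' @param seed Integer seed for all subsampling.
#' @param baseline Also compute the cross-patient random-cell baseline.
#' @return List of class `subsample_robustness`: `by_size` (data.frame
#'   size, mean_accuracy, n_patients), `by_patient` (data.frame patient,
#'   size, accuracy, mean_true_activation), `baseline` (data.frame or
#'   NULL), `full_bag_accuracy`.
#' @export
subsample_robustness <- function(params, bags,
                                 sizes = c(1L, 2L, 5L, 10L, 20L, 50L,
                                           100L, 200L, 500L),
                                 reps = 100L, seed = 1L, baseline = TRUE) {
  reps <- check_count(reps, "reps")
  set.seed(child_seed(seed, "subsample"))
  classes <- params$classes
  rows <- list()
  full_correct <- logical(length(bags))

  for (bi in seq_along(bags)) {
    bag <- bags[[bi]]
    n <- bag_size(bag)
    H <- embed_instances(bag, params)      # embed once, reuse per subset
    y_idx <- match(bag$label, classes)
    ss <- sort(unique(c(sizes[sizes <= n], n)))
    for (s in ss) {
      if (s == n) {
        pred <- forward_from_H(H, params)
        acc <- as.numeric(pred$label_index == y_idx)
        act <- pred$p[y_idx]
        if (s == n) full_correct[bi] <- acc == 1
      } else {
        correct <- numeric(reps)
        act_r <- numeric(reps)
        for (r in seq_len(reps)) {
          idx <- sample.int(n, s)
          pred <- forward_from_H(H[idx, , drop = FALSE], params)
          correct[r] <- pred$label_index == y_idx
          act_r[r] <- pred$p[y_idx]
        }
        acc <- mean(correct)
        act <- mean(act_r)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = bag$patient_id, label = bag$label, size = s,
        accuracy = acc, mean_true_activation = act,
        full_size = n, stringsAsFactors = FALSE)
    }
  }
  by_patient <- do.call(rbind, rows)

  # mean accuracy over patients per nominal ladder size; a patient is
  # skipped at sizes exceeding its bag (reflected in n_patients)
  ladder <- sort(unique(sizes))
  by_size <- do.call(rbind, lapply(ladder, function(s) {
    sub <- by_patient[by_patient$size == s, ]
    data.frame(size = s,
               mean_accuracy = if (nrow(sub)) mean(sub$accuracy) else
                 NA_real_,
               n_patients = nrow(sub))
  }))

  base <- NULL
  if (baseline) {
    pool <- do.call(rbind, lapply(bags, function(b) b$features))
    base <- do.call(rbind, lapply(ladder[ladder <= nrow(pool)], function(s) {
      labs <- vapply(seq_len(reps), function(r) {
        idx <- sample.int(nrow(pool), s)
        Hs <- embed_instances(pool[idx, , drop = FALSE], params)
        forward_from_H(Hs, params)$label
      }, character(1))
      data.frame(size = s, prediction_table = I(list(table(labs))))
    }))
  }

  structure(list(by_size = by_size, by_patient = by_patient,
                 baseline = base,
                 full_bag_accuracy = mean(full_correct)),
            class = "subsample_robustness")
}

# Forward pass from pre-embedded instances (skips f_emb).
forward_from_H <- function(H, params) {
  af <- attention_forward(H, params)
  Z <- t(H) %*% af$alpha
  s <- head_logits(Z, params)
  p <- softmax(s)
  names(p) <- params$classes
  k <- which.max(p)
  list(p = p, label = params$classes[k], label_index = k)
}

#' AUROC of attention for planted versus background cells
#'
#' On synthetic bags with known planted flags, measures how well the
#' predicted class's attention row separates planted (diagnostic) cells
#' from background cells: the area under the ROC curve of attention as a
#' score for the planted flag, computed per bag and averaged.
#'
#' @param params Trained [mil_init()] parameters.
#' @param bags List of synthetic bags carrying `planted` flags.
#' @param correctly_classified_only Restrict to bags the model classifies
#'   correctly.
#' @return List: `mean_auroc`, `per_bag` (data.frame patient_id, auroc,
#'   correct, top_quartile_planted_fraction, base_rate), `n_used`.
#' @export
attention_planted_auroc <- function(params, bags,
                                    correctly_classified_only = TRUE) {
  rows <- list()
  for (bag in bags) {
    if (is.null(bag$planted) || !any(bag$planted) || all(bag$planted)) next
    pred <- mil_forward(bag, params)
    correct <- pred$label == bag$label
    if (correctly_classified_only && !correct) next
    a <- as.numeric(pred$attention)
    roc <- pROC::roc(bag$planted, a, quiet = TRUE,
                     direction = "<", levels = c(FALSE, TRUE))
    n <- length(a)
    top_q <- order(a, decreasing = TRUE)[seq_len(ceiling(n / 4))]
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = bag$patient_id,
      auroc = as.numeric(pROC::auc(roc)),
      correct = correct,
      top_quartile_planted_fraction = mean(bag$planted[top_q]),
      base_rate = mean(bag$planted),
      stringsAsFactors = FALSE)
  }
  per_bag <- do.call(rbind, rows)
  list(mean_auroc = if (is.null(per_bag)) NA_real_ else mean(per_bag$auroc),
       per_bag = per_bag,
       n_used = if (is.null(per_bag)) 0L else nrow(per_bag))
}
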