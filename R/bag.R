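#' Construct a patient bag
#'
#' A bag is the unit of supervision in multiple instance learning: one
#' patient's ordered set of single-cell feature vectors together with the
#' patient-level label. Instance order is meaningful only as a stable join
#' key back to the source images; the model itself is permutation invariant.
#'
#' @param features Numeric matrix, one row per cell (instance), `d` columns.
#' @param patient_id Single string identifying the patient.
#' @param label Class label; must be one of `classes`.
#' @param classes Character vector of allowed labels (fixed class order).
#' @param cell_ids Optional character vector of per-row cell identifiers;
#'   defaults to `"<patient_id>_cell0001"` style names.
#' @param planted Optional logical vector flagging synthetic diagnostic
#'   instances (used by the synthetic-cohort generator and ignored by the
#'   model).
#'
#' @return An object of class `cytomil_bag`.
#' @export
new_bag <- function(features, patient_id, label,
                    classes = cytomil_classes(),
                    cell_ids = NULL, planted = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features) || nrow(features) < 1L) {
    stop_field("features", "must be a numeric matrix with at least one row")
  }
  if (anyNA(features) || any(!is.finite(features))) {
    stop_field("features", "must be finite")
  }
  if (!is.character(patient_id) || length(patient_id) != 1L) {
    stop_field("patient_id", "must be a single string")
  }
  if (!label %in% classes) {
    stop_field("label", sprintf("'%s' not in allowed labels: %s",
                                label, paste(classes, collapse = ", ")))
  }
  n <- nrow(features)
  if (is.null(cell_ids)) {
    cell_ids <- sprintf("%s_cell%04d", patient_id, seq_len(n))
  }
  if (length(cell_ids) != n) stop_field("cell_ids", "length must match rows")
  if (!is.null(planted) && length(planted) != n) {
    stop_field("planted", "length must match rows")
  }
  structure(
    list(features = features, patient_id = patient_id, label = label,
         classes = classes, cell_ids = as.character(cell_ids),
         planted = planted),
    class = "cytomil_bag"
  )
}

#' @export
print.cytomil_bag <- function(x, ...) {
  cat(sprintf("<cytomil_bag> patient %s | label %s | %d cells x %d features\n",
              x$patient_id, x$label, nrow(x$features), ncol(x$features)))
  invisible(x)
}

#' Number of instances in a bag
#' @param bag A `cytomil_bag`.
#' @return Integer instance count.
#' @export
bag_size <- function(bag) nrow(bag$features)

# Reorder instances of a bag (used for in-training permutation; keeps
# cell ids and planted flags aligned with their feature rows).
permute_bag <- function(bag, perm) {
  bag$features <- bag$features[perm, , drop = FALSE]
  bag$cell_ids <- bag$cell_ids[perm]
  if (!is.null(bag$planted)) bag$planted <- bag$planted[perm]
  bag
}
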