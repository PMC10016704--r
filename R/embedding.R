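#' Fit a 2-D UMAP embedding on one fold's cell features
#'
#' Fits a nonlinear 2-D embedding (UMAP) on the single-cell features of
#' one fold; cells from other folds are later mapped into the same space
#' with [map_into_embedding()] without refitting. Neighborhood parameters
#' follow the library defaults; the seed is fixed and single-threaded
#' optimization is used so coordinates are reproducible.
#'
#' @param features N x d numeric matrix (N >= 10).
#' @param n_neighbors UMAP neighborhood size.
#' @param min_dist UMAP minimum embedding distance.
#' @param seed Integer seed.
#' @return A fitted embedder (class `cytomil_embedder`) with `$coords`
#'   (N x 2 matrix of the training coordinates).
#' @export
fit_embedding <- function(features, n_neighbors = 15L, min_dist = 0.1,
                          seed = 1L) {
  features <- as.matrix(features)
  if (nrow(features) < 10L) {
    stop_field("features", "need at least 10 feature vectors")
  }
  if (all(apply(features, 2L, stats::var) < 1e-12)) {
    stop_field("features", "degenerate input: all vectors identical")
  }
  set.seed(child_seed(seed, "umap"))
  model <- uwot::umap(features, n_components = 2L,
                      n_neighbors = min(n_neighbors, nrow(features) - 1L),
                      min_dist = min_dist, ret_model = TRUE,
                      n_threads = 1L, n_sgd_threads = 0L)
  structure(list(model = model, coords = model$embedding, seed = seed),
            class = "cytomil_embedder")
}

#' Map new cells into a fitted embedding
#'
#' Transforms new feature vectors into the fitted 2-D space without
#' refitting and attaches instance predictions as color/intensity fields
#' when provided.
#'
#' @param embedder A [fit_embedding()] result.
#' @param features M x d matrix of new cell features (may have 0 rows).
#' @param instance_preds Optional `data.frame` from [predict_instances()]
#'   (row-aligned with `features`) supplying `pred` and `pred_prob`.
#' @return `data.frame` with `x`, `y` and, if predictions were given,
#'   `cell_id`, `pred_class`, `probability`.
#' @export
map_into_embedding <- function(embedder, features, instance_preds = NULL) {
  stopifnot(inherits(embedder, "cytomil_embedder"))
  features <- as.matrix(features)
  if (nrow(features) == 0L) {
    return(data.frame(x = numeric(), y = numeric()))
  }
  expected <- embedder$model$norig_col
  if (!is.null(expected) && ncol(features) != expected) {
    stop_field("features",
               sprintf("dimension %d does not match the fitted embedder (%d)",
                       ncol(features), expected))
  }
  set.seed(child_seed(embedder$seed, "umap-transform"))
  xy <- uwot::umap_transform(features, embedder$model, n_threads = 1L)
  out <- data.frame(x = xy[, 1L], y = xy[, 2L])
  if (!is.null(instance_preds)) {
    stopifnot(nrow(instance_preds) == nrow(out))
    out$cell_id <- instance_preds$cell_id
    out$pred_class <- instance_preds$pred
    out$probability <- instance_preds$pred_prob
  }
  out
}
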