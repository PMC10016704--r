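#' Patient-level stratified cross-validation folds
#'
#' Builds `k` train/validation/test splits at the patient level,
#' stratified by class. Within each class the (shuffled) patients are cut
#' into `k` chunks whose sizes differ by at most one (largest-remainder
#' rounding); fold `f` uses chunk `f` as its test set and the next chunk
#' (cyclically) as its validation set, so every patient appears in exactly
#' one test set across folds and the train/validation/test proportions
#' approximate 60/20/20 for `k = 5`.
#'
#' @param manifest `data.frame` with `patient_id` and `label` columns.
#' @param k Number of folds.
#' @param seed Integer seed for the within-class shuffle.
#' @return List of `k` fold splits, each a list with `fold`, `train`,
#'   `val`, `test` (character vectors of patient ids).
#' @export
make_folds <- function(manifest, k = 5L, seed = 1L) {
  k <- check_count(k, "k", min = 2L)
  stopifnot(all(c("patient_id", "label") %in% names(manifest)))
  if (anyDuplicated(manifest$patient_id)) {
    stop_field("manifest", "duplicate patient ids")
  }
  tab <- table(manifest$label)
  small <- names(tab)[tab < k]
  if (length(small) > 0L) {
    stop(sprintf("class '%s' has fewer than k=%d patients", small[1L], k),
         call. = FALSE)
  }
  set.seed(child_seed(seed, "folds"))
  # chunk assignment per class: sizes floor(n/k) with the first n %% k
  # chunks enlarged by one (largest-remainder)
  chunk_of <- integer(nrow(manifest))
  for (cl in names(tab)) {
    idx <- which(manifest$label == cl)
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
    chunk_of[idx] <- rep(seq_len(k), times = sizes)
  }
  lapply(seq_len(k), function(f) {
    val_chunk <- f %% k + 1L
    list(fold = f,
         train = manifest$patient_id[!chunk_of %in% c(f, val_chunk)],
         val = manifest$patient_id[chunk_of == val_chunk],
         test = manifest$patient_id[chunk_of == f])
  })
}
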