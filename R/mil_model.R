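#' MIL model configuration
#'
#' Hyperparameters of the attention-based multiple-instance-learning model.
#' Defaults follow the published recipe for bags of deep single-cell
#' features: a 500-unit instance embedding, 128-unit attention space,
#' learning rate 5e-5, early stopping after 20 epochs without validation
#' improvement, and at most 150 epochs.
#'
#' @param embed_dim Width of the instance embedding produced by `f_emb`.
#' @param attention_dim Width of the attention hidden space.
#' @param lr Learning rate for the Adam optimizer.
#' @param patience Epochs without validation-loss improvement before
#'   training stops.
#' @param max_epochs Hard cap on training epochs.
#' @param optimizer Optimizer name; only `"adam"` is implemented.
#' @param head Classification-head layout. `"per_class"` (default) gives
#'   each class its own weight vector applied to its own pooled feature
#'   (`s_i = u_i'z_i + b_i`), which keeps single-cell deconvolution
#'   class-specific. `"shared"` ties one weight vector across classes;
#'   note that a shared head makes all size-one bags predict the same
#'   class, so it is unsuitable when instance-level deconvolution is
#'   needed.
#' @param nonneg_head Constrain the head weight vectors (not the biases)
#'   to be non-negative during training (projected gradient step). With
#'   free weights the class softmax admits degenerate optima in which one
#'   class is recognized "by elimination" and its attention row inverts
#'   (low attention on its evidence cells); non-negative evidence weights
#'   remove those optima because a class's logit can only rise by
#'   attending to cells with class evidence (see the package vignette).
#' @param subsample_min If set, every training step draws a fresh random
#'   sub-bag whose size is uniform between this value and the full bag
#'   size (evaluation always uses full bags). This in-bag subsampling
#'   augmentation multiplies the diversity of training bags and prevents
#'   the decision boundary from keying on bag-size artifacts such as the
#'   extreme order statistics of large background-only bags. `NULL`
#'   (default) trains on full bags with only the in-bag order
#'   permutation.
#' @param attention_decay L2 penalty coefficient on the attention
#'   parameters (V_i, W_i). Because raw attention scores are bounded by
#'   the norm of W_i, decay soft-caps how sharp the per-class softmax can
#'   get: a handful of extreme background cells cannot monopolize the
#'   pooled bag feature, while a genuine evidence population still
#'   dominates. 0 (default) disables it.
#' @param seed Master seed; initialization and per-epoch shuffles derive
#'   independent streams from it.
#' @param classes Class labels in fixed index order.
#'
#' @return A list of class `mil_config`.
#' @export
mil_config <- function(embed_dim = 500L, attention_dim = 128L,
                       lr = 5e-5, patience = 20L, max_epochs = 150L,
                       optimizer = "adam", head = c("per_class", "shared"),
                       nonneg_head = TRUE, subsample_min = NULL,
                       attention_decay = 0,
                       seed = 1L, classes = cytomil_classes()) {
  embed_dim <- check_count(embed_dim, "embed_dim")
  attention_dim <- check_count(attention_dim, "attention_dim")
  check_number(lr, "lr", min = 0, strict_min = TRUE)
  patience <- check_count(patience, "patience")
  max_epochs <- check_count(max_epochs, "max_epochs")
  if (patience > max_epochs) stop_field("patience", "must be <= max_epochs")
  optimizer <- match.arg(optimizer, "adam")
  head <- match.arg(head)
  check_flag(nonneg_head, "nonneg_head")
  if (!is.null(subsample_min)) {
    subsample_min <- check_count(subsample_min, "subsample_min")
  }
  check_number(attention_decay, "attention_decay", min = 0)
  if (length(classes) < 2L) stop_field("classes", "need at least 2 classes")
  structure(
    list(embed_dim = embed_dim, attention_dim = attention_dim, lr = lr,
         patience = patience, max_epochs = max_epochs, optimizer = optimizer,
         head = head, nonneg_head = nonneg_head,
         subsample_min = subsample_min, attention_decay = attention_decay,
         seed = as.integer(seed), classes = classes),
    class = "mil_config"
  )
}

#' Initialize MIL model parameters
#'
#' Parameters comprise the instance embedder `f_emb` (single hidden layer,
#' rectifier activation), one attention weight pair (V_i, W_i) per class,
#' and one linear classification head per class applied to that class's
#' own pooled bag feature. The per-class structure keeps attention rows
#' decoupled: no parameter is shared between the attention score of one
#' class and another.
#'
#' @param d Input feature dimension.
#' @param cfg A [mil_config()].
#'
#' @return An object of class `mil_params`. Attention weights for class
#'   `i` live in rows `((i-1)*L_att+1):(i*L_att)` of `$att_V` and column
#'   `i` of `$att_W`.
#' @export
mil_init <- function(d, cfg = mil_config()) {
  d <- check_count(d, "d")
  C <- length(cfg$classes)
  L <- cfg$embed_dim
  La <- cfg$attention_dim
  head_cols <- if (cfg$head == "shared") 1L else C
  set.seed(child_seed(cfg$seed, "init"))
  head_W <- matrix(stats::rnorm(L * head_cols, sd = sqrt(1 / L)),
                   L, head_cols)
  if (isTRUE(cfg$nonneg_head)) head_W <- abs(head_W)
  params <- structure(list(
    emb_W = matrix(stats::rnorm(d * L, sd = sqrt(2 / d)), d, L),
    emb_b = numeric(L),
    att_V = matrix(stats::rnorm(C * La * L, sd = sqrt(1 / L)), C * La, L),
    att_W = matrix(stats::rnorm(La * C, sd = sqrt(1 / La)), La, C),
    head_W = head_W,
    head_b = numeric(C),
    d = d, embed_dim = L, attention_dim = La,
    head = cfg$head,
    classes = cfg$classes
  ), class = "mil_params")
  params
}

#' @export
print.mil_params <- function(x, ...) {
  cat(sprintf(
    "<mil_params> d=%d -> embed %d -> attention %d | %d classes: %s\n",
    x$d, x$embed_dim, x$attention_dim, length(x$classes),
    paste(x$classes, collapse = ", ")))
  invisible(x)
}

# Row block of the stacked attention matrix V belonging to class i.
att_rows <- function(params, i) {
  La <- params$attention_dim
  ((i - 1L) * La + 1L):(i * La)
}

#' Embed bag instances
#'
#' Applies the instance embedder `f_emb` row-wise:
#' `h_k = relu(W'x_k + b)`. The output row order equals the bag order.
#'
#' @param bag A [new_bag()] object (or a plain numeric matrix of features).
#' @param params A [mil_init()] parameter set.
#' @return Numeric matrix `H` of size N x embed_dim.
#' @export
embed_instances <- function(bag, params) {
  X <- if (inherits(bag, "cytomil_bag")) bag$features else as.matrix(bag)
  if (ncol(X) != params$d) {
    stop_field("bag", sprintf("feature dimension %d does not match model d=%d",
                              ncol(X), params$d))
  }
  H <- X %*% params$emb_W
  H <- sweep(H, 2L, params$emb_b, "+")
  relu(H)
}

# Internal fused attention pass. Returns the N x C alpha matrix plus the
# intermediates needed for backpropagation.
attention_forward <- function(H, params) {
  C <- length(params$classes)
  La <- params$attention_dim
  N <- nrow(H)
  Tpre <- H %*% t(params$att_V)            # N x (C*La)
  Tt <- tanh(Tpre)
  e <- matrix(0, N, C)
  for (i in seq_len(C)) {
    e[, i] <- Tt[, att_rows(params, i), drop = FALSE] %*% params$att_W[, i]
  }
  # per-class softmax over instances (columns of e), max-subtracted
  emax <- apply(e, 2L, max)
  ex <- exp(sweep(e, 2L, emax, "-"))
  alpha <- sweep(ex, 2L, colSums(ex), "/")  # N x C
  list(alpha = alpha, e = e, Tt = Tt)
}

#' Class-wise attention matrix
#'
#' Computes the raw attention scores `e[i,k] = W_i' tanh(V_i h_k)` and the
#' per-class softmax over instances
#' `alpha[i,k] = exp(e[i,k]) / sum_j exp(e[i,j])`, so each class row of the
#' attention matrix is a probability distribution over the bag's cells.
#' Class rows are computed from disjoint parameters, eliminating
#' inter-class competition for attention.
#'
#' @param H Embedded instances (N x embed_dim), as from [embed_instances()].
#' @param params A [mil_init()] parameter set.
#' @return List with `A` (C x N attention matrix, rows sum to 1) and
#'   `scores` (C x N raw scores).
#' @export
classwise_attention <- function(H, params) {
  H <- as.matrix(H)
  if (anyNA(H) || any(!is.finite(H))) stop_field("H", "must be finite")
  af <- attention_forward(H, params)
  A <- t(af$alpha)
  rownames(A) <- params$classes
  list(A = A, scores = structure(t(af$e), dimnames = list(params$classes, NULL)))
}

#' Attention pooling
#'
#' Pools embedded instances into one bag feature per class:
#' `z_i = sum_k alpha[i,k] * h_k`.
#'
#' @param H Embedded instances (N x embed_dim).
#' @param A Attention matrix (C x N), rows summing to 1.
#' @return Matrix `Z` of size embed_dim x C; column `i` is `z_i`.
#' @export
attention_pool <- function(H, A) {
  H <- as.matrix(H)
  A <- as.matrix(A)
  if (ncol(A) != nrow(H)) {
    stop_field("A", sprintf("has %d columns but H has %d rows", ncol(A), nrow(H)))
  }
  Z <- t(H) %*% t(A)
  colnames(Z) <- rownames(A)
  Z
}

# Logits from the pooled bag features: shared head applies the same
# weight vector to every class's pooled feature, per-class head applies
# column i to z_i.
head_logits <- function(Z, params) {
  if (ncol(params$head_W) == 1L) {
    drop(crossprod(Z, params$head_W)) + params$head_b
  } else {
    colSums(Z * params$head_W) + params$head_b
  }
}

#' Bag classification head
#'
#' Applies a linear head to each class's own pooled feature
#' (`s_i = u'z_i + b_i` with a shared weight vector `u` by default, or
#' `s_i = u_i'z_i + b_i` with per-class weights; see [mil_config()]),
#' converts logits to probabilities with a softmax, and predicts the
#' argmax class (ties broken toward the lowest class index). The
#' predicted class's attention row is attached.
#'
#' @param Z Pooled bag features (embed_dim x C), as from [attention_pool()].
#' @param params A [mil_init()] parameter set.
#' @param A Optional C x N attention matrix to attach to the prediction.
#' @return A `bag_prediction`: list with `p` (named probability vector),
#'   `label`, `label_index`, `logits`, `attention` (predicted class's row
#'   of `A`, or NULL), `A`, and `Z`.
#' @export
classify_bag <- function(Z, params, A = NULL) {
  C <- length(params$classes)
  Z <- as.matrix(Z)
  if (!all(dim(Z) == c(params$embed_dim, C))) {
    stop_field("Z", sprintf("must be %d x %d", params$embed_dim, C))
  }
  s <- head_logits(Z, params)
  p <- softmax(s)
  names(p) <- params$classes
  k <- unname(which.max(p))  # first (lowest-index) maximum breaks ties
  structure(list(
    p = p,
    label = params$classes[k],
    label_index = k,
    logits = stats::setNames(s, params$classes),
    attention = if (!is.null(A)) A[k, ] else NULL,
    A = A,
    Z = Z
  ), class = "bag_prediction")
}

#' @export
print.bag_prediction <- function(x, ...) {
  cat(sprintf("<bag_prediction> %s (p=%.3f)\n", x$label, x$p[x$label_index]))
  print(round(x$p, 4))
  invisible(x)
}

#' Full MIL forward pass
#'
#' Embeds instances, computes the class-wise attention matrix, pools, and
#' classifies: `(y, alpha) = f(B)`. The composition is permutation
#' invariant -- reordering the bag's cells permutes attention columns but
#' leaves the probability vector unchanged (up to floating-point error).
#'
#' @param bag A [new_bag()] object.
#' @param params A [mil_init()] parameter set.
#' @return A `bag_prediction` (see [classify_bag()]) with `cell_ids` and
#'   `patient_id` attached.
#' @export
mil_forward <- function(bag, params) {
  H <- embed_instances(bag, params)
  att <- classwise_attention(H, params)
  Z <- attention_pool(H, att$A)
  pred <- classify_bag(Z, params, A = att$A)
  if (inherits(bag, "cytomil_bag")) {
    pred$patient_id <- bag$patient_id
    pred$cell_ids <- bag$cell_ids
    pred$true_label <- bag$label
  }
  pred
}
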