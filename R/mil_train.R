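# Fused forward + backward pass for one bag. Returns the loss and the
# gradient list (same shapes as the trainable entries of `params`).
# Gradients are derived analytically for the composition
#   H = relu(X W_e + b_e); T = tanh(H V'); e_i = T_i W_i;
#   alpha_i = softmax(e_i); z_i = H' alpha_i; s_i = u_i' z_i + c_i;
#   loss = -log softmax(s)[y].
mil_grad <- function(X, y_index, params) {
  C <- length(params$classes)
  La <- params$attention_dim

  Hpre <- sweep(X %*% params$emb_W, 2L, params$emb_b, "+")
  H <- relu(Hpre)
  af <- attention_forward(H, params)
  alpha <- af$alpha                       # N x C
  Tt <- af$Tt                             # N x (C*La)
  Z <- t(H) %*% alpha                     # L x C
  s <- head_logits(Z, params)
  p <- softmax(s)
  loss <- -log(max(p[y_index], 1e-12))

  ds <- p
  ds[y_index] <- ds[y_index] - 1
  if (ncol(params$head_W) == 1L) {
    d_head_W <- Z %*% ds                  # shared weight vector
    dZ <- params$head_W %*% t(ds)         # dZ[, i] = ds_i * u
  } else {
    d_head_W <- sweep(Z, 2L, ds, "*")
    dZ <- sweep(params$head_W, 2L, ds, "*")
  }
  d_head_b <- ds
  dalpha <- H %*% dZ                      # N x C
  dH <- alpha %*% t(dZ)                   # pooling path into H

  # softmax backward per class column
  de <- alpha * sweep(dalpha, 2L, colSums(alpha * dalpha), "-")

  dT <- matrix(0, nrow(X), C * La)
  d_att_W <- matrix(0, La, C)
  for (i in seq_len(C)) {
    rows <- att_rows(params, i)
    dT[, rows] <- de[, i] %o% params$att_W[, i]
    d_att_W[, i] <- crossprod(Tt[, rows, drop = FALSE], de[, i])
  }
  dTpre <- dT * (1 - Tt * Tt)
  d_att_V <- crossprod(dTpre, H)          # (C*La) x L
  dH <- dH + dTpre %*% params$att_V       # attention path into H

  dHpre <- dH * (H > 0)
  d_emb_W <- crossprod(X, dHpre)
  d_emb_b <- colSums(dHpre)

  list(loss = loss, p = p,
       grads = list(emb_W = d_emb_W, emb_b = d_emb_b,
                    att_V = d_att_V, att_W = d_att_W,
                    head_W = d_head_W, head_b = d_head_b))
}

# Mean bag-level cross-entropy over a list of bags.
mil_loss <- function(bags, params) {
  cls <- params$classes
  mean(vapply(bags, function(b) {
    p <- mil_forward(b, params)$p
    -log(max(p[match(b$label, cls)], 1e-12))
  }, numeric(1)))
}

adam_new <- function(params, names) {
  st <- list(t = 0L, m = list(), v = list())
  for (nm in names) {
    st$m[[nm]] <- params[[nm]] * 0
    st$v[[nm]] <- params[[nm]] * 0
  }
  st
}

adam_step <- function(params, grads, st, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = st)
}

#' Train the attention-MIL model
#'
#' Minimizes the bag-level categorical cross-entropy with Adam, taking one
#' optimizer step per bag. Each epoch shuffles the bag order and permutes
#' the instance order within every bag; with `cfg$subsample_min` set, the
#' permutation becomes a fresh random sub-bag per step (see
#' [mil_config()]). Optional L2 decay on the attention parameters and the
#' non-negativity projection of the head weights are applied per step.
#' After each epoch the mean validation loss is evaluated; training stops
#' once `cfg$patience` consecutive epochs bring no improvement (any
#' decrease counts; the earliest best epoch is kept) or at
#' `cfg$max_epochs`. The returned parameters are those of the best
#' validation epoch.
#'
#' @param bags List of [new_bag()] objects (all classes share `cfg$classes`).
#' @param split List with `train` and `val` character vectors of patient
#'   ids (e.g. one element of [make_folds()]); bags not listed are ignored.
#' @param cfg A [mil_config()].
#' @param verbose Print per-epoch losses.
#'
#' @return List with `params` (best-epoch `mil_params`), `log` (data.frame
#'   of epoch, train_loss, val_loss), `best_epoch`, and `config`.
#' @export
train_mil <- function(bags, split, cfg = mil_config(), verbose = FALSE) {
  ids <- vapply(bags, function(b) b$patient_id, character(1))
  train_bags <- bags[ids %in% split$train]
  val_bags <- bags[ids %in% split$val]
  if (length(train_bags) == 0L) stop_field("split", "train set is empty")
  if (length(val_bags) == 0L) stop_field("split", "validation set is empty")
  labs <- vapply(train_bags, function(b) b$label, character(1))
  if (length(unique(labs)) < 2L) {
    stop_field("bags", "training set must contain at least 2 classes")
  }

  d <- ncol(train_bags[[1L]]$features)
  params <- mil_init(d, cfg)
  trainable <- c("emb_W", "emb_b", "att_V", "att_W", "head_W", "head_b")
  st <- adam_new(params, trainable)
  y_idx <- match(labs, cfg$classes)

  set.seed(child_seed(cfg$seed, "shuffle"))
  best <- list(loss = Inf, epoch = 0L, params = params)
  log_rows <- vector("list", cfg$max_epochs)

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(length(train_bags))
    tl <- 0
    for (j in ord) {
      X <- train_bags[[j]]$features
      n <- nrow(X)
      # in-bag permutation; with subsample_min set this becomes a fresh
      # random sub-bag of uniform size each step
      take <- if (is.null(cfg$subsample_min) || n <= cfg$subsample_min) n
        else sample(cfg$subsample_min:n, 1L)
      X <- X[sample.int(n, take), , drop = FALSE]
      g <- mil_grad(X, y_idx[j], params)
      if (!is.finite(g$loss)) {
        stop("non-finite training loss at epoch ", epoch,
             "; aborting with last finite parameters", call. = FALSE)
      }
      if (cfg$attention_decay > 0) {
        g$grads$att_W <- g$grads$att_W + cfg$attention_decay * params$att_W
        g$grads$att_V <- g$grads$att_V + cfg$attention_decay * params$att_V
      }
      upd <- adam_step(params, g$grads, st, cfg$lr)
      params <- upd$params
      st <- upd$state
      if (isTRUE(cfg$nonneg_head)) {
        params$head_W[params$head_W < 0] <- 0  # projected gradient step
      }
      tl <- tl + g$loss
    }
    vl <- mil_loss(val_bags, params)
    log_rows[[epoch]] <- data.frame(epoch = epoch,
                                    train_loss = tl / length(train_bags),
                                    val_loss = vl)
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      tl / length(train_bags), vl))
    }
    if (vl < best$loss) {
      best <- list(loss = vl, epoch = epoch, params = params)
    }
    if (epoch - best$epoch >= cfg$patience) break
  }

  list(params = best$params,
       log = do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1))]),
       best_epoch = best$epoch,
       config = cfg)
}
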