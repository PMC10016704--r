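# Minimal CPU convolutional network used as the desk-scale feature
# extractor. Convolutions are evaluated as matrix products via
# precomputed im2col index tables: images are stored as flattened
# (H, W, C) column-major arrays, each conv layer holds an index matrix
# mapping output positions to input patch elements, and both the forward
# pass and all gradients reduce to BLAS calls plus indexed scatters.

# im2col index table for a valid (unpadded) convolution / pooling window.
# Rows: output positions (row index fastest, matching column-major
# flattening); columns: patch elements ordered (dy, dx, channel).
im2col_index <- function(H, W, C, k, s) {
  oh <- conv_out_size(H, k, s)
  ow <- conv_out_size(W, k, s)
  oy <- rep(seq_len(oh), times = ow)
  ox <- rep(seq_len(ow), each = oh)
  y0 <- (oy - 1L) * s
  x0 <- (ox - 1L) * s
  idx <- matrix(0L, oh * ow, k * k * C)
  j <- 0L
  for (cc in seq_len(C)) {
    off_c <- (cc - 1L) * H * W
    for (dx in seq_len(k)) {
      for (dy in seq_len(k)) {
        j <- j + 1L
        idx[, j] <- y0 + dy + (x0 + dx - 1L) * H + off_c
      }
    }
  }
  attr(idx, "out_shape") <- c(oh, ow, C)
  idx
}

# Build the runtime plan (index tables + parameter shapes) for a backbone
# whose layers are all valid convs and 2x2-style max pools (the tiny_cnn
# family). Padded architectures (resnet34) are shape-only configuration.
cnn_plan <- function(backbone) {
  stopifnot(inherits(backbone, "cytomil_backbone"))
  if (any(vapply(backbone$layers, function(l) l$p, 0L) != 0L)) {
    stop(sprintf(
      "backbone '%s' is available as configuration only; no trainable %s",
      backbone$backbone, "implementation ships for padded architectures"),
      call. = FALSE)
  }
  H <- backbone$input_size; W <- backbone$input_size
  C <- backbone$in_channels
  plan <- list()
  for (ly in backbone$layers) {
    if (ly$type == "conv") {
      idx <- im2col_index(H, W, C, ly$k, ly$s)
      plan[[length(plan) + 1L]] <- list(
        type = "conv", idx = idx, k_in = ly$k * ly$k * C, out = ly$out,
        in_len = H * W * C)
      os <- attr(idx, "out_shape")
      H <- os[1L]; W <- os[2L]; C <- ly$out
    } else {
      # pooling is per-channel: positions ordered (oy, ox, channel)
      idx1 <- im2col_index(H, W, 1L, ly$k, ly$s)
      os <- attr(idx1, "out_shape")
      P1 <- os[1L] * os[2L]
      idx <- do.call(rbind, lapply(seq_len(C) - 1L,
                                   function(cc) idx1 + cc * H * W))
      plan[[length(plan) + 1L]] <- list(
        type = "maxpool", idx = idx, in_len = H * W * C, P1 = P1)
      H <- os[1L]; W <- os[2L]
    }
  }
  plan
}

cnn_init_params <- function(backbone, num_classes, seed = 1L) {
  plan <- cnn_plan(backbone)
  set.seed(child_seed(seed, "cnn-init"))
  params <- list(conv = list(), fc = NULL)
  for (ly in plan) {
    if (ly$type == "conv") {
      params$conv[[length(params$conv) + 1L]] <- list(
        W = matrix(stats::rnorm(ly$k_in * ly$out,
                                sd = sqrt(2 / ly$k_in)), ly$k_in, ly$out),
        b = numeric(ly$out))
    }
  }
  d <- backbone$feature_dim
  params$fc <- list(W = matrix(stats::rnorm(d * num_classes,
                                            sd = sqrt(1 / d)),
                               d, num_classes),
                    b = numeric(num_classes))
  params
}

# Forward pass; returns class probabilities, the pre-head feature vector,
# and (optionally) the caches needed for backprop.
cnn_forward <- function(xflat, plan, params, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(plan)) else NULL
  ci <- 0L
  for (li in seq_along(plan)) {
    ly <- plan[[li]]
    if (ly$type == "conv") {
      ci <- ci + 1L
      Xcol <- matrix(xflat[ly$idx], nrow(ly$idx), ncol(ly$idx))
      Y <- Xcol %*% params$conv[[ci]]$W
      Y <- sweep(Y, 2L, params$conv[[ci]]$b, "+")
      mask <- Y > 0
      Y[!mask] <- 0
      if (keep_cache) caches[[li]] <- list(Xcol = Xcol, mask = mask)
      xflat <- as.vector(Y)
    } else {
      Vals <- matrix(xflat[ly$idx], nrow(ly$idx), ncol(ly$idx))
      amax <- max.col(Vals, ties.method = "first")
      if (keep_cache) caches[[li]] <- list(amax = amax)
      xflat <- Vals[cbind(seq_len(nrow(Vals)), amax)]
    }
  }
  feat <- xflat
  s <- drop(crossprod(params$fc$W, feat)) + params$fc$b
  p <- softmax(s)
  list(p = p, features = feat, caches = caches)
}

# Backward pass for one image given forward caches; returns gradients in
# the same structure as `params`.
cnn_backward <- function(fw, y_index, plan, params) {
  dp <- fw$p
  dp[y_index] <- dp[y_index] - 1
  g <- list(conv = vector("list",
                          sum(vapply(plan, function(l) l$type == "conv",
                                     TRUE))),
            fc = list(W = fw$features %o% dp, b = dp))
  dflat <- drop(params$fc$W %*% dp)

  ci <- length(g$conv)
  for (li in rev(seq_along(plan))) {
    ly <- plan[[li]]
    if (ly$type == "conv") {
      P <- nrow(ly$idx)
      dY <- matrix(dflat, P, ly$out)
      dY[!fw$caches[[li]]$mask] <- 0
      g$conv[[ci]] <- list(W = crossprod(fw$caches[[li]]$Xcol, dY),
                           b = colSums(dY))
      dXcol <- dY %*% t(params$conv[[ci]]$W)
      dx <- numeric(ly$in_len)
      for (j in seq_len(ncol(ly$idx))) {
        dx[ly$idx[, j]] <- dx[ly$idx[, j]] + dXcol[, j]
      }
      dflat <- dx
      ci <- ci - 1L
    } else {
      amax <- fw$caches[[li]]$amax
      dx <- numeric(ly$in_len)
      tgt <- ly$idx[cbind(seq_along(amax), amax)]
      dx[tgt] <- dflat
      dflat <- dx
    }
  }
  g
}
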