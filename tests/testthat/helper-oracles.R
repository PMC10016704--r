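# Independent brute-force oracles used to cross-check the vectorized
# implementation. These deliberately loop over every index of the
# formulas and never share code with the package internals.

# alpha[i,k] = exp(W_i' tanh(V_i h_k)) / sum_j exp(W_i' tanh(V_i h_j))
oracle_attention <- function(H, V_list, W_list) {
  C <- length(V_list)
  N <- nrow(H)
  A <- matrix(0, C, N)
  for (i in seq_len(C)) {
    e <- numeric(N)
    for (k in seq_len(N)) {
      hk <- H[k, ]
      t_ik <- tanh(as.numeric(V_list[[i]] %*% hk))
      e[k] <- sum(W_list[[i]] * t_ik)
    }
    denom <- 0
    for (j in seq_len(N)) denom <- denom + exp(e[j])
    for (k in seq_len(N)) A[i, k] <- exp(e[k]) / denom
  }
  A
}

# z_i = sum_k alpha[i,k] h_k
oracle_pool <- function(H, A) {
  C <- nrow(A)
  Z <- matrix(0, ncol(H), C)
  for (i in seq_len(C)) {
    for (k in seq_len(nrow(H))) {
      Z[, i] <- Z[, i] + A[i, k] * H[k, ]
    }
  }
  Z
}

# s_i = u_i' z_i + b_i (per-class head) or s_i = u' z_i + b_i (shared
# weight vector recycled across classes); p = softmax(s)
oracle_classify <- function(Z, U, b) {
  C <- ncol(Z)
  s <- numeric(C)
  for (i in seq_len(C)) {
    u_i <- if (ncol(U) == 1L) U[, 1L] else U[, i]
    s[i] <- sum(u_i * Z[, i]) + b[i]
  }
  exp(s - max(s)) / sum(exp(s - max(s)))
}

# Random small mil_params with per-class V/W lists attached for the oracle.
make_random_params <- function(C = 3L, d = 6L, L = 8L, La = 4L, seed = 1L,
                               head = "per_class") {
  cfg <- mil_config(embed_dim = L, attention_dim = La, head = head,
                    classes = paste0("class", seq_len(C)), seed = seed)
  params <- mil_init(d, cfg)
  set.seed(seed + 999L)
  params$att_V <- matrix(rnorm(C * La * L, sd = 0.5), C * La, L)
  params$att_W <- matrix(rnorm(La * C, sd = 0.5), La, C)
  params$head_W <- matrix(rnorm(L * ncol(params$head_W), sd = 0.5),
                          L, ncol(params$head_W))
  params$head_b <- rnorm(C, sd = 0.2)
  V_list <- lapply(seq_len(C), function(i) {
    params$att_V[((i - 1L) * La + 1L):(i * La), , drop = FALSE]
  })
  W_list <- lapply(seq_len(C), function(i) params$att_W[, i])
  list(params = params, V_list = V_list, W_list = W_list)
}

# Unvectorized Canny re-implementation (same algorithm definition as the
# package: Sobel with replicate borders, L1 magnitude, 4-bin non-max
# suppression, two-threshold hysteresis with 8-connectivity), written as
# plain per-pixel loops.
oracle_canny <- function(gray, low = 100, high = 200) {
  if (max(gray) <= 1 + 1e-9) gray <- gray * 255
  H <- nrow(gray); W <- ncol(gray)
  gp <- function(y, x) gray[min(max(y, 1), H), min(max(x, 1), W)]
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  for (y in seq_len(H)) {
    for (x in seq_len(W)) {
      gx[y, x] <- (gp(y - 1, x + 1) + 2 * gp(y, x + 1) + gp(y + 1, x + 1)) -
        (gp(y - 1, x - 1) + 2 * gp(y, x - 1) + gp(y + 1, x - 1))
      gy[y, x] <- (gp(y + 1, x - 1) + 2 * gp(y + 1, x) + gp(y + 1, x + 1)) -
        (gp(y - 1, x - 1) + 2 * gp(y - 1, x) + gp(y - 1, x + 1))
    }
  }
  mag <- abs(gx) + abs(gy)
  nms <- matrix(0, H, W)
  mg <- function(y, x) if (y < 1 || y > H || x < 1 || x > W) Inf else mag[y, x]
  for (y in seq_len(H)) {
    for (x in seq_len(W)) {
      ang <- atan2(gy[y, x], gx[y, x]) * 180 / pi
      if (ang < 0) ang <- ang + 180
      if (ang < 22.5 || ang >= 157.5) {
        n1 <- mg(y, x - 1); n2 <- mg(y, x + 1)
      } else if (ang < 67.5) {
        n1 <- mg(y + 1, x - 1); n2 <- mg(y - 1, x + 1)
      } else if (ang < 112.5) {
        n1 <- mg(y + 1, x); n2 <- mg(y - 1, x)
      } else {
        n1 <- mg(y + 1, x + 1); n2 <- mg(y - 1, x - 1)
      }
      if (mag[y, x] >= n1 && mag[y, x] >= n2) nms[y, x] <- mag[y, x]
    }
  }
  strong <- nms > high
  weak <- nms > low
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (y in seq_len(H)) {
      for (x in seq_len(W)) {
        if (!strong[y, x] && weak[y, x]) {
          for (dy in -1:1) {
            for (dx in -1:1) {
              yy <- y + dy; xx <- x + dx
              if (yy >= 1 && yy <= H && xx >= 1 && xx <= W &&
                  strong[yy, xx]) {
                strong[y, x] <- TRUE
                changed <- TRUE
              }
            }
          }
        }
      }
    }
  }
  matrix(as.integer(strong) * 255L, H, W)
}
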