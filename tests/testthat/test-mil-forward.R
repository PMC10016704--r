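test_that("instance embedding is an instance-wise map", {
  rp <- make_random_params(C = 3L, d = 6L, L = 8L, La = 4L, seed = 2L)
  p <- rp$params
  set.seed(5)
  X <- matrix(rnorm(5 * 6), 5, 6)
  bag <- new_bag(X, "p1", "class1", classes = p$classes)
  H <- embed_instances(bag, p)
  expect_identical(dim(H), c(5L, 8L))
  # permuting the bag permutes rows of H
  perm <- c(3L, 1L, 5L, 2L, 4L)
  H2 <- embed_instances(X[perm, ], p)
  expect_equal(H2, H[perm, ], tolerance = 1e-12)
  # singleton bag
  expect_identical(dim(embed_instances(X[1L, , drop = FALSE], p)), c(1L, 8L))
  # zero weights and bias force the activation of zero
  p0 <- p
  p0$emb_W[] <- 0
  p0$emb_b[] <- 0
  expect_true(all(embed_instances(X, p0) == 0))
  # dimension mismatch is caught
  expect_error(embed_instances(matrix(0, 2, 4), p), "dimension")
})

test_that("class-wise attention matches the brute-force formula", {
  for (case in 1:20) {
    C <- sample(2:5, 1L)
    N <- sample(1:20, 1L)
    L <- sample(2:16, 1L)
    La <- sample(2:8, 1L)
    rp <- make_random_params(C, d = 4L, L = L, La = La, seed = case)
    set.seed(case * 7L)
    H <- matrix(rnorm(N * L), N, L)
    A <- classwise_attention(H, rp$params)$A
    expect_lt(max(abs(A - oracle_attention(H, rp$V_list, rp$W_list))), 1e-6)
    expect_equal(rowSums(A), rep(1, C), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("attention degenerates correctly in forced cases", {
  rp <- make_random_params(C = 3L, d = 4L, L = 8L, La = 4L, seed = 3L)
  p <- rp$params
  set.seed(1)
  H <- matrix(rnorm(6 * 8), 6, 8)
  # W_i = 0 makes all scores of class i constant -> uniform attention row
  p$att_W[, 2L] <- 0
  A <- classwise_attention(H, p)$A
  expect_equal(A[2L, ], rep(1 / 6, 6), tolerance = 1e-12,
               ignore_attr = TRUE)
  # N = 1: every row is the softmax of a singleton
  A1 <- classwise_attention(H[1L, , drop = FALSE], p)$A
  expect_equal(as.numeric(A1), rep(1, 3), tolerance = 1e-12)
  expect_error(classwise_attention(H * NA, p), "finite")
})

test_that("attention pooling matches the brute-force double loop", {
  for (case in 1:20) {
    set.seed(case)
    N <- sample(1:15, 1L)
    L <- sample(2:12, 1L)
    C <- sample(2:5, 1L)
    H <- matrix(rnorm(N * L), N, L)
    A <- matrix(rexp(C * N), C, N)
    A <- A / rowSums(A)
    expect_lt(max(abs(attention_pool(H, A) - oracle_pool(H, A))), 1e-6)
  }
  # uniform attention pools to the row mean; one-hot selects one instance
  H <- matrix(rnorm(4 * 3), 4, 3)
  Au <- matrix(1 / 4, 2, 4)
  expect_equal(attention_pool(H, Au)[, 1L], colMeans(H),
               tolerance = 1e-12, ignore_attr = TRUE)
  Ah <- matrix(0, 2, 4)
  Ah[, 3L] <- 1
  expect_equal(attention_pool(H, Ah)[, 2L], H[3L, ],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(attention_pool(H, matrix(1, 2, 5)), "columns")
})

test_that("bag classification matches the linear head formula in both modes", {
  for (case in 1:20) {
    rp <- make_random_params(C = sample(2:5, 1L), d = 4L,
                             L = sample(2:12, 1L), La = 3L, seed = case,
                             head = if (case %% 2L) "per_class" else
                               "shared")
    p <- rp$params
    set.seed(case + 50L)
    Z <- matrix(rnorm(p$embed_dim * length(p$classes)),
                p$embed_dim, length(p$classes))
    pred <- classify_bag(Z, p)
    expect_lt(max(abs(pred$p - oracle_classify(Z, p$head_W, p$head_b))),
              1e-6)
    expect_equal(sum(pred$p), 1, tolerance = 1e-6)
  }
  # all logits equal -> uniform probabilities, tie broken to class index 1
  rp <- make_random_params(C = 4L, d = 4L, L = 6L, La = 3L, seed = 9L)
  p <- rp$params
  p$head_W[] <- 0
  p$head_b[] <- 0
  pred <- classify_bag(matrix(1, 6, 4), p)
  expect_equal(as.numeric(pred$p), rep(0.25, 4), tolerance = 1e-12)
  expect_identical(pred$label_index, 1L)
  # one dominant logit saturates the softmax
  p$head_b <- c(0, 50, 0, 0)
  pred2 <- classify_bag(matrix(0, 6, 4), p)
  expect_equal(as.numeric(pred2$p), c(0, 1, 0, 0), tolerance = 1e-6)
})

test_that("the full forward pass is permutation invariant", {
  rp <- make_random_params(C = 3L, d = 6L, L = 8L, La = 4L, seed = 4L)
  set.seed(10)
  X <- matrix(rnorm(12 * 6), 12, 6)
  bag <- new_bag(X, "p", "class2", classes = rp$params$classes)
  fwd <- mil_forward(bag, rp$params)
  rev_bag <- new_bag(X[12:1, ], "p", "class2", classes = rp$params$classes)
  fwd_rev <- mil_forward(rev_bag, rp$params)
  expect_identical(fwd$label, fwd_rev$label)
  expect_lt(max(abs(fwd$p - fwd_rev$p)), 1e-5)
  # chained oracle equivalence of the composition
  H <- embed_instances(bag, rp$params)
  A <- oracle_attention(H, rp$V_list, rp$W_list)
  p_oracle <- oracle_classify(oracle_pool(H, A), rp$params$head_W,
                              rp$params$head_b)
  expect_lt(max(abs(fwd$p - p_oracle)), 1e-6)
})

test_that("singleton bags give unit attention for every class", {
  rp <- make_random_params(C = 4L, d = 5L, L = 6L, La = 3L, seed = 6L)
  bag <- new_bag(matrix(rnorm(5), 1, 5), "p", "class1",
                 classes = rp$params$classes)
  fwd <- mil_forward(bag, rp$params)
  expect_equal(as.numeric(fwd$A), rep(1, 4), tolerance = 1e-12)
  expect_equal(as.numeric(fwd$attention), 1, tolerance = 1e-12)
})

test_that("perturbing one class's attention weights leaves other rows unchanged", {
  rp <- make_random_params(C = 5L, d = 6L, L = 8L, La = 4L, seed = 8L)
  p <- rp$params
  set.seed(2)
  H <- matrix(rnorm(10 * 8), 10, 8)
  A0 <- classwise_attention(H, p)$A
  # perturb class 3's V block and W column
  La <- p$attention_dim
  rows3 <- ((3L - 1L) * La + 1L):(3L * La)
  p$att_V[rows3, ] <- p$att_V[rows3, ] + 0.7
  p$att_W[, 3L] <- p$att_W[, 3L] * -2
  A1 <- classwise_attention(H, p)$A
  expect_identical(A0[-3L, ], A1[-3L, ])
  expect_gt(max(abs(A0[3L, ] - A1[3L, ])), 0)
})
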