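test_that("backbone feature dimension is pure layer arithmetic", {
  r34 <- build_backbone("resnet34", 144L)
  expect_identical(unname(r34$feature_shape), c(512L, 5L, 5L))
  expect_identical(r34$feature_dim, 12800L)
  expect_identical(feature_dim("resnet34", 144L), 12800L)

  tiny <- build_backbone("tiny_cnn", 144L)
  expect_identical(unname(tiny$feature_shape), c(8L, 3L, 3L))
  expect_identical(tiny$feature_dim, 72L)

  # dimension depends only on backbone + input size, not data
  expect_identical(feature_dim("resnet34", 144L),
                   build_backbone("resnet34", 144L)$feature_dim)
  # a different input size changes the map arithmetic (224 -> 512 x 7 x 7)
  expect_identical(feature_dim("resnet34", 224L), 512L * 7L * 7L)
  expect_error(build_backbone("tiny_cnn", 16L), "too small")
})

test_that("declared tiny_cnn dimension matches an actual forward pass", {
  bb <- build_backbone("tiny_cnn", 96L)
  plan <- cytomil:::cnn_plan(bb)
  params <- cytomil:::cnn_init_params(bb, 3L, seed = 1L)
  set.seed(2)
  x <- runif(96L * 96L * 3L)
  fw <- cytomil:::cnn_forward(x, plan, params)
  expect_length(fw$features, bb$feature_dim)
  expect_equal(sum(fw$p), 1, tolerance = 1e-9)
})

test_that("im2col convolution equals a direct sliding-window loop", {
  H <- 9L; W <- 9L; C <- 2L; k <- 3L; s <- 2L
  set.seed(4)
  x <- array(rnorm(H * W * C), c(H, W, C))
  idx <- cytomil:::im2col_index(H, W, C, k, s)
  Wm <- matrix(rnorm(k * k * C * 4L), k * k * C, 4L)
  Y <- matrix(as.vector(x)[idx], nrow(idx)) %*% Wm
  os <- attr(idx, "out_shape")
  # direct evaluation: out[oy,ox,f] = sum over dy,dx,c of patch * weight
  for (f in 1:4) {
    for (oy in seq_len(os[1L])) {
      for (ox in seq_len(os[2L])) {
        acc <- 0
        for (cc in seq_len(C)) {
          for (dx in seq_len(k)) {
            for (dy in seq_len(k)) {
              wrow <- dy + (dx - 1L) * k + (cc - 1L) * k * k
              acc <- acc + x[(oy - 1L) * s + dy, (ox - 1L) * s + dx, cc] *
                Wm[wrow, f]
            }
          }
        }
        expect_equal(Y[oy + (ox - 1L) * os[1L], f], acc,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("CNN analytic gradients match finite differences", {
  bb <- build_backbone("tiny_cnn", 96L)
  plan <- cytomil:::cnn_plan(bb)
  params <- cytomil:::cnn_init_params(bb, 3L, seed = 5L)
  set.seed(6)
  x <- runif(96L * 96L * 3L) - 0.5
  fw <- cytomil:::cnn_forward(x, plan, params, keep_cache = TRUE)
  g <- cytomil:::cnn_backward(fw, 2L, plan, params)
  loss_at <- function(p) {
    -log(cytomil:::cnn_forward(x, plan, p)$p[2L])
  }
  base <- loss_at(params)
  eps <- 1e-6
  set.seed(7)
  for (li in seq_along(params$conv)) {
    for (j in sample(length(params$conv[[li]]$W), 4L)) {
      p2 <- params
      p2$conv[[li]]$W[j] <- p2$conv[[li]]$W[j] + eps
      expect_equal(g$conv[[li]]$W[j], (loss_at(p2) - base) / eps,
                   tolerance = 5e-3, ignore_attr = TRUE)
    }
  }
  for (j in sample(length(params$fc$W), 4L)) {
    p2 <- params
    p2$fc$W[j] <- p2$fc$W[j] + eps
    expect_equal(g$fc$W[j], (loss_at(p2) - base) / eps, tolerance = 5e-3,
                 ignore_attr = TRUE)
  }
})
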