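# Canny edge detection on 8-bit grayscale images, following the classic
# recipe used by mainstream computer-vision libraries: 3x3 Sobel gradients
# on the raw grayscale image, L1 gradient magnitude, non-maximum
# suppression with the direction quantized to 4 bins, and two-threshold
# hysteresis (8-connectivity) on the suppressed magnitude.

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Convert an RGB array (H x W x 3, values in [0,1] or [0,255]) or a
# grayscale matrix to 8-bit-scale grayscale using standard luma weights.
to_gray255 <- function(img) {
  if (is.matrix(img)) {
    g <- img
  } else if (length(dim(img)) == 3L) {
    g <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
  } else {
    stop_field("image", "must be a matrix or an H x W x 3 array")
  }
  if (max(g) <= 1 + 1e-9) g <- g * 255
  g
}

# Sobel gradients with replicate border handling.
sobel_gradients <- function(g) {
  pr <- rbind(g[1, , drop = FALSE], g, g[nrow(g), , drop = FALSE])
  p <- cbind(pr[, 1, drop = FALSE], pr, pr[, ncol(pr), drop = FALSE])
  nr <- nrow(g); nc <- ncol(g)
  idx <- function(dr, dc) p[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  # x = column direction, y = row direction
  a <- idx(0, 0); b <- idx(0, 1); cc <- idx(0, 2)
  d <- idx(1, 0); f <- idx(1, 2)
  g2 <- idx(2, 0); h <- idx(2, 1); i <- idx(2, 2)
  gx <- (cc + 2 * f + i) - (a + 2 * d + g2)
  gy <- (g2 + 2 * h + i) - (a + 2 * b + cc)
  list(gx = gx, gy = gy)
}

#' Canny edge map
#'
#' Computes a binary edge map (edge pixels valued 255, others 0) from an
#' image: grayscale conversion by luma weighting, 3x3 Sobel gradients, L1
#' gradient magnitude, non-maximum suppression along the quantized
#' gradient direction, and hysteresis thresholding -- pixels above `high`
#' are edges, pixels between `low` and `high` are edges only if connected
#' (8-neighborhood) to one.
#'
#' @param img RGB array (H x W x 3) or grayscale matrix, values in
#'   `[0, 1]` or `[0, 255]`.
#' @param low,high Hysteresis thresholds on the 8-bit-scale gradient
#'   magnitude; `low < high` required.
#' @return Integer matrix of 0/255 values, same size as the image.
#' @export
canny_edges <- function(img, low = 100, high = 200) {
  check_number(low, "low", min = 0)
  check_number(high, "high", min = 0)
  if (low >= high) stop_field("low", "must be strictly below high")
  g <- to_gray255(img)
  if (nrow(g) < 8L || ncol(g) < 8L) {
    stop_field("image", "must be at least 8 x 8 pixels")
  }
  sg <- sobel_gradients(g)
  mag <- abs(sg$gx) + abs(sg$gy)

  # quantize gradient direction to {0, 45, 90, 135} degrees
  ang <- atan2(sg$gy, sg$gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  dir <- integer(length(ang))
  dir[(ang < 22.5) | (ang >= 157.5)] <- 0L   # horizontal gradient
  dir[ang >= 22.5 & ang < 67.5] <- 45L
  dir[ang >= 67.5 & ang < 112.5] <- 90L
  dir[ang >= 112.5 & ang < 157.5] <- 135L
  dim(dir) <- dim(mag)

  # non-maximum suppression: keep pixels that are >= both neighbors
  # along the gradient direction
  n_e <- shift_mat(mag, 0, -1, Inf); n_w <- shift_mat(mag, 0, 1, Inf)
  n_n <- shift_mat(mag, 1, 0, Inf); n_s <- shift_mat(mag, -1, 0, Inf)
  n_ne <- shift_mat(mag, 1, -1, Inf); n_sw <- shift_mat(mag, -1, 1, Inf)
  n_nw <- shift_mat(mag, 1, 1, Inf); n_se <- shift_mat(mag, -1, -1, Inf)
  keep <- matrix(FALSE, nrow(mag), ncol(mag))
  s0 <- dir == 0L
  keep[s0] <- mag[s0] >= n_e[s0] & mag[s0] >= n_w[s0]
  s45 <- dir == 45L
  keep[s45] <- mag[s45] >= n_ne[s45] & mag[s45] >= n_sw[s45]
  s90 <- dir == 90L
  keep[s90] <- mag[s90] >= n_n[s90] & mag[s90] >= n_s[s90]
  s135 <- dir == 135L
  keep[s135] <- mag[s135] >= n_nw[s135] & mag[s135] >= n_se[s135]
  nms <- mag
  nms[!keep] <- 0

  strong <- nms > high
  weak <- nms > low
  # hysteresis: grow the strong set through weak pixels (8-connectivity)
  repeat {
    grown <- strong |
      shift_mat(strong, 1, 0) | shift_mat(strong, -1, 0) |
      shift_mat(strong, 0, 1) | shift_mat(strong, 0, -1) |
      shift_mat(strong, 1, 1) | shift_mat(strong, 1, -1) |
      shift_mat(strong, -1, 1) | shift_mat(strong, -1, -1)
    grown <- grown & weak
    if (identical(grown, strong)) break
    strong <- grown
  }
  matrix(as.integer(strong) * 255L, nrow(g), ncol(g))
}

#' Edge-sum sharpness score
#'
#' The sum of the 0/255-valued Canny edge map over the whole image -- the
#' blur score used for single-cell quality control. Blurred images have
#' weak gradients, few surviving edge pixels, and therefore a small edge
#' sum; the conventional exclusion rule drops images with an edge sum
#' below 5e4 (about 196 edge pixels).
#'
#' @inheritParams canny_edges
#' @param mode `"sum"` (sum of the 255-valued map, the default) or
#'   `"count"` (number of edge pixels).
#' @return Single non-negative number.
#' @export
edge_sum <- function(img, low = 100, high = 200, mode = c("sum", "count")) {
  mode <- match.arg(mode)
  e <- canny_edges(img, low = low, high = high)
  if (mode == "sum") sum(e) else sum(e > 0)
}
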