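#' Synthetic single-cell image specification
#'
#' Parameters for rendering synthetic stained-smear cell images: one
#' textured elliptical "cell" per image on a pale background, with
#' class-dependent cell radius, cytoplasmic granularity (speckle
#' amplitude, mimicking granulation) and nuclear lobedness (number of
#' overlapping nuclear lobes). A configurable fraction of images is
#' Gaussian-blurred to near-featurelessness so the blur QC filter has true
#' positives.
#'
#' @param image_size Square image side in pixels (default 144, the
#'   standard gallery-image size).
#' @param class_params `data.frame` with columns `label`, `radius`
#'   (pixels), `granularity` (speckle sd in intensity units), `lobes`
#'   (nuclear lobe count); defaults cover [cytomil_classes()].
#' @param blur_fraction Fraction of images rendered blurry, in `[0, 1]`.
#' @param blur_sigma Gaussian blur standard deviation in pixels.
#' @param seed Integer seed.
#' @return List of class `synthetic_image_spec`.
#' @export
synthetic_image_spec <- function(image_size = 144L,
                                 class_params = NULL,
                                 blur_fraction = 0,
                                 blur_sigma = 6,
                                 seed = 1L) {
  image_size <- check_count(image_size, "image_size", min = 16L)
  check_number(blur_fraction, "blur_fraction", min = 0, max = 1)
  check_number(blur_sigma, "blur_sigma", min = 0, strict_min = TRUE)
  if (is.null(class_params)) {
    class_params <- data.frame(
      label = cytomil_classes(),
      radius = c(46, 34, 40, 26, 30),
      granularity = c(0.30, 0.10, 0.18, 0.08, 0.12),
      lobes = c(2L, 1L, 3L, 1L, 4L),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("label", "radius", "granularity", "lobes") %in%
                  names(class_params)))
  structure(list(image_size = image_size, class_params = class_params,
                 blur_fraction = blur_fraction, blur_sigma = blur_sigma,
                 seed = as.integer(seed)),
            class = "synthetic_image_spec")
}

# 1-D Gaussian convolution matrix with replicate-edge normalization.
gauss_conv_matrix <- function(n, sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cols <- (i - r):(i + r)
    ok <- cols >= 1 & cols <= n
    K[i, cols[ok]] <- k[ok]
    K[i, ] <- K[i, ] / sum(K[i, ])
  }
  K
}

#' Gaussian blur of an image array
#'
#' Separable Gaussian filter with edge renormalization, applied per
#' channel.
#'
#' @param img H x W matrix or H x W x 3 array with values in `[0, 1]`.
#' @param sigma Standard deviation in pixels.
#' @return Blurred image of the same shape.
#' @export
gaussian_blur <- function(img, sigma) {
  if (is.matrix(img)) {
    K1 <- gauss_conv_matrix(nrow(img), sigma)
    K2 <- gauss_conv_matrix(ncol(img), sigma)
    return(K1 %*% img %*% t(K2))
  }
  out <- img
  K1 <- gauss_conv_matrix(dim(img)[1L], sigma)
  K2 <- gauss_conv_matrix(dim(img)[2L], sigma)
  for (ch in seq_len(dim(img)[3L])) {
    out[, , ch] <- K1 %*% img[, , ch] %*% t(K2)
  }
  out
}

# Render one synthetic cell image (H x W x 3, values in [0, 1]).
render_cell <- function(size, radius, granularity, lobes) {
  xs <- matrix(rep(seq_len(size), each = size), size, size)  # column coord
  ys <- matrix(rep(seq_len(size), times = size), size, size) # row coord
  cx <- size / 2 + stats::runif(1, -4, 4)
  cy <- size / 2 + stats::runif(1, -4, 4)
  rx <- radius * stats::runif(1, 0.9, 1.1)
  ry <- radius * stats::runif(1, 0.8, 1.05)
  cell <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1

  img <- array(0, c(size, size, 3L))
  bg <- c(0.93, 0.88, 0.91)      # pale eosin-stained background
  cyto <- c(0.78, 0.72, 0.88)    # basophilic cytoplasm
  nuc <- c(0.42, 0.28, 0.58)     # dense chromatin
  for (ch in 1:3) {
    img[, , ch] <- bg[ch] + stats::rnorm(size^2, sd = 0.015)
  }
  # cytoplasm with azurophilic granulation (speckle texture)
  speck <- stats::rnorm(size^2, sd = granularity)
  for (ch in 1:3) {
    layer <- img[, , ch]
    layer[cell] <- cyto[ch] + speck[cell]
    img[, , ch] <- layer
  }
  # nuclear lobes: overlapping disks on a ring inside the cell
  lobe_r <- radius * (0.55 - 0.08 * (lobes - 1))
  ring <- radius * 0.35 * (lobes > 1)
  phi0 <- stats::runif(1, 0, 2 * pi)
  for (l in seq_len(lobes)) {
    ang <- phi0 + 2 * pi * (l - 1) / max(lobes, 1)
    lx <- cx + ring * cos(ang)
    ly <- cy + ring * sin(ang)
    lob <- (xs - lx)^2 + (ys - ly)^2 <= lobe_r^2
    lob <- lob & cell
    chroma <- stats::rnorm(size^2, sd = 0.05)
    for (ch in 1:3) {
      layer <- img[, , ch]
      layer[lob] <- nuc[ch] + chroma[lob]
      img[, , ch] <- layer
    }
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Generate synthetic single-cell images
#'
#' Renders one image per entry of `labels` using that class's shape
#' parameters. A `blur_fraction` share of images (chosen at random) is
#' blurred with a wide Gaussian and contrast-compressed so that it fails
#' the default edge-sum QC filter. Deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_image_spec()].
#' @param labels Character vector of class labels (must appear in
#'   `spec$class_params$label`); may be empty.
#' @return List with one element per image: `pixels` (H x W x 3 array in
#'   `[0, 1]`), `label`, `blurred` (logical), `image_id`.
#' @export
generate_cell_images <- function(spec, labels) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  if (length(labels) == 0L) return(list())
  bad <- setdiff(unique(labels), spec$class_params$label)
  if (length(bad) > 0L) {
    stop_field("labels", paste("unknown class:", bad[1L]))
  }
  set.seed(child_seed(spec$seed, "images"))
  n <- length(labels)
  blurred <- rep(FALSE, n)
  n_blur <- round(spec$blur_fraction * n)
  if (n_blur > 0L) blurred[sample.int(n, n_blur)] <- TRUE
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cp <- spec$class_params[spec$class_params$label == labels[i], ][1L, ]
    img <- render_cell(spec$image_size, cp$radius, cp$granularity, cp$lobes)
    if (blurred[i]) {
      img <- gaussian_blur(img, spec$blur_sigma)
      # compress contrast toward the mean so no strong edges survive
      mu <- mean(img)
      img <- mu + 0.25 * (img - mu)
    }
    out[[i]] <- list(pixels = img, label = labels[i], blurred = blurred[i],
                     image_id = sprintf("img%05d", i))
  }
  out
}
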