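# Feature-extractor backbones. The feature contract is: features are the
# flattened activations of the last convolutional stage, before any final
# average pooling and the fully connected classification head, so the
# feature dimension is a pure function of backbone + input size.

conv_out_size <- function(n, k, s = 1L, p = 0L) {
  (n + 2L * p - k) %/% s + 1L
}

# Layer descriptor helpers.
ly_conv <- function(out, k, s = 1L, p = 0L) {
  list(type = "conv", out = out, k = k, s = s, p = p)
}
ly_pool <- function(k, s = k, p = 0L) {
  list(type = "maxpool", k = k, s = s, p = p)
}

# The tiny desk-scale CNN: three valid (unpadded) conv stages with
# interleaved 2x2 max pooling. At 144x144 input the spatial path is
# 144 -> 47 -> 23 -> 10 -> 5 -> 3, giving an 8 x 3 x 3 feature map
# (d = 72).
tiny_cnn_layers <- function() {
  list(ly_conv(8L, 6L, 3L), ly_pool(2L),
       ly_conv(8L, 5L, 2L), ly_pool(2L),
       ly_conv(8L, 3L, 1L))
}

# ResNet34 feature path: 7x7/2 stem, 3x3/2 max pool, then four stages of
# basic blocks (3, 4, 6, 3 blocks; 64/128/256/512 channels; stages 2-4
# downsample by 2 in their first block). Only the shape-relevant
# structure is described: each basic block keeps its stage's channel
# count and all 3x3 convs use padding 1, so per block only the first
# (possibly strided) conv changes the spatial size.
resnet34_layers <- function() {
  layers <- list(ly_conv(64L, 7L, 2L, 3L), ly_pool(3L, 2L, 1L))
  stages <- list(c(64L, 3L, 1L), c(128L, 4L, 2L),
                 c(256L, 6L, 2L), c(512L, 3L, 2L))
  for (st in stages) {
    for (b in seq_len(st[2L])) {
      s <- if (b == 1L) st[3L] else 1L
      layers <- c(layers, list(ly_conv(st[1L], 3L, s, 1L),
                               ly_conv(st[1L], 3L, 1L, 1L)))
    }
  }
  layers
}

#' Build a feature-extractor backbone
#'
#' Constructs the layer structure of the requested backbone and computes
#' the shape of its final convolutional feature map at the given input
#' size, hence the length `d` of the flattened pre-pooling feature vector.
#' For `"resnet34"` at 144 x 144 input the final map is 512 x 5 x 5,
#' d = 12800; for `"tiny_cnn"` it is 8 x 3 x 3, d = 72.
#'
#' @param backbone `"tiny_cnn"` or `"resnet34"`.
#' @param input_size Square input side in pixels.
#' @param in_channels Input channels (3 for RGB).
#' @return List of class `cytomil_backbone` with `layers`,
#'   `feature_shape` (channels, height, width) and `feature_dim`.
#' @export
build_backbone <- function(backbone = c("tiny_cnn", "resnet34"),
                           input_size = 144L, in_channels = 3L) {
  backbone <- match.arg(backbone)
  input_size <- check_count(input_size, "input_size", min = 16L)
  layers <- switch(backbone, tiny_cnn = tiny_cnn_layers(),
                   resnet34 = resnet34_layers())
  n <- input_size
  ch <- in_channels
  for (ly in layers) {
    n2 <- conv_out_size(n, ly$k, ly$s, ly$p)
    if (n2 < 1L) {
      stop_field("input_size",
                 sprintf("too small for backbone '%s'", backbone))
    }
    n <- n2
    if (ly$type == "conv") ch <- ly$out
  }
  structure(list(backbone = backbone, input_size = input_size,
                 in_channels = in_channels, layers = layers,
                 feature_shape = c(channels = ch, height = n, width = n),
                 feature_dim = ch * n * n),
            class = "cytomil_backbone")
}

#' @export
print.cytomil_backbone <- function(x, ...) {
  cat(sprintf("<cytomil_backbone> %s @ %dx%d -> %d x %d x %d (d = %d)\n",
              x$backbone, x$input_size, x$input_size,
              x$feature_shape[1L], x$feature_shape[2L], x$feature_shape[3L],
              x$feature_dim))
  invisible(x)
}

#' Feature dimension of a backbone
#'
#' @param backbone Backbone name or a `cytomil_backbone`.
#' @param input_size Square input side in pixels (ignored when a built
#'   backbone is passed).
#' @return Integer flattened feature length `d`.
#' @export
feature_dim <- function(backbone, input_size = 144L) {
  if (inherits(backbone, "cytomil_backbone")) return(backbone$feature_dim)
  build_backbone(backbone, input_size)$feature_dim
}
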