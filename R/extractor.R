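#' Feature-extractor configuration
#'
#' Training recipe for the single-cell classifier whose pre-pooling
#' activations serve as instance features. Two backbones are configured:
#' `"tiny_cnn"`, the small network with a trainable implementation in this
#' package, and `"resnet34"`, the full-scale recipe (ImageNet
#' initialization, SGD at 5e-4, patience 10) kept as configuration for
#' users training on their own annotated corpus with a deep-learning
#' framework. Training augments images by random horizontal/vertical
#' flips, right-angle rotation, translation, rescaling and random erasing
#' of small areas, and addresses class imbalance by probabilistic
#' oversampling (sampling probability inversely proportional to class
#' frequency).
#'
#' @param backbone `"tiny_cnn"` or `"resnet34"`.
#' @param input_size Square image side in pixels.
#' @param num_classes Number of single-cell classes (>= 2).
#' @param init `"random"` or `"pretrained-imagenet"` (resnet34 recipe).
#' @param optimizer `"adam"` or `"sgd"`.
#' @param lr Learning rate.
#' @param patience Early-stopping patience in epochs.
#' @param max_epochs Epoch cap.
#' @param batch_size Minibatch size.
#' @param augment Named logical flags: `hflip`, `vflip`, `rotate`,
#'   `translate`, `rescale`, `erase`.
#' @param oversample Probabilistic oversampling on/off.
#' @param exclude_classes Class labels dropped before training (e.g.
#'   classes with too few examples).
#' @param seed Master seed.
#' @return List of class `extractor_config`.
#' @export
extractor_config <- function(backbone = c("tiny_cnn", "resnet34"),
                             input_size = 144L, num_classes = 2L,
                             init = c("random", "pretrained-imagenet"),
                             optimizer = c("adam", "sgd"),
                             lr = NULL, patience = 10L, max_epochs = 60L,
                             batch_size = 16L,
                             augment = c(hflip = TRUE, vflip = TRUE,
                                         rotate = TRUE, translate = TRUE,
                                         rescale = FALSE, erase = FALSE),
                             oversample = TRUE,
                             exclude_classes = character(),
                             seed = 1L) {
  backbone <- match.arg(backbone)
  init <- match.arg(init)
  optimizer <- match.arg(optimizer)
  num_classes <- check_count(num_classes, "num_classes", min = 2L)
  patience <- check_count(patience, "patience")
  max_epochs <- check_count(max_epochs, "max_epochs")
  if (is.null(lr)) lr <- if (backbone == "resnet34") 5e-4 else 3e-3
  check_number(lr, "lr", min = 0, strict_min = TRUE)
  check_flag(oversample, "oversample")
  structure(list(backbone = backbone,
                 input_size = check_count(input_size, "input_size", 16L),
                 num_classes = num_classes, init = init,
                 optimizer = optimizer, lr = lr, patience = patience,
                 max_epochs = max_epochs,
                 batch_size = check_count(batch_size, "batch_size"),
                 augment = augment, oversample = oversample,
                 exclude_classes = exclude_classes,
                 seed = as.integer(seed)),
            class = "extractor_config")
}

# ---- augmentation ----------------------------------------------------------

rot90_img <- function(img, k) {
  k <- k %% 4L
  for (i in seq_len(k)) {
    img <- aperm(img, c(2L, 1L, 3L))[dim(img)[2L]:1L, , , drop = FALSE]
  }
  img
}

translate_img <- function(img, dy, dx) {
  H <- dim(img)[1L]; W <- dim(img)[2L]
  out <- array(mean(img[c(1L, H), , ]), dim(img))  # border fill
  ys <- max(1, 1 + dy):min(H, H + dy)
  xs <- max(1, 1 + dx):min(W, W + dx)
  out[ys, xs, ] <- img[ys - dy, xs - dx, , drop = FALSE]
  out
}

rescale_img <- function(img, factor) {
  H <- dim(img)[1L]; W <- dim(img)[2L]
  src_y <- pmin(H, pmax(1, round((seq_len(H) - H / 2) / factor + H / 2)))
  src_x <- pmin(W, pmax(1, round((seq_len(W) - W / 2) / factor + W / 2)))
  img[src_y, src_x, , drop = FALSE]
}

erase_img <- function(img, size = 20L) {
  H <- dim(img)[1L]; W <- dim(img)[2L]
  y <- sample.int(H - size, 1L)
  x <- sample.int(W - size, 1L)
  img[y:(y + size - 1L), x:(x + size - 1L), ] <-
    stats::runif(size * size * dim(img)[3L])
  img
}

augment_image <- function(img, flags) {
  if (isTRUE(flags[["hflip"]]) && stats::runif(1) < 0.5) {
    img <- img[, dim(img)[2L]:1L, , drop = FALSE]
  }
  if (isTRUE(flags[["vflip"]]) && stats::runif(1) < 0.5) {
    img <- img[dim(img)[1L]:1L, , , drop = FALSE]
  }
  if (isTRUE(flags[["rotate"]])) {
    img <- rot90_img(img, sample(0:3, 1L))
  }
  if (isTRUE(flags[["translate"]])) {
    img <- translate_img(img, sample(-6:6, 1L), sample(-6:6, 1L))
  }
  if (isTRUE(flags[["rescale"]]) && stats::runif(1) < 0.5) {
    img <- rescale_img(img, stats::runif(1, 0.9, 1.1))
  }
  if (isTRUE(flags[["erase"]]) && stats::runif(1) < 0.5) {
    img <- erase_img(img)
  }
  img
}

#' Oversampling probabilities
#'
#' Per-example sampling probabilities inversely proportional to the
#' frequency of the example's class, so the expected class-sampling
#' distribution is uniform.
#'
#' @param labels Character/factor vector of class labels.
#' @return Numeric vector of probabilities summing to 1.
#' @export
oversample_probs <- function(labels) {
  freq <- table(labels)
  w <- 1 / as.numeric(freq[as.character(labels)])
  w / sum(w)
}

# Stratified 60/20/20 split of indices by label.
stratified_split <- function(labels, fractions = c(0.6, 0.2, 0.2),
                             seed = 1L) {
  set.seed(child_seed(seed, "ext-split"))
  train <- val <- test <- integer()
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    n_tr <- round(fractions[1L] * n)
    n_va <- round(fractions[2L] * n)
    train <- c(train, idx[seq_len(n_tr)])
    val <- c(val, idx[n_tr + seq_len(min(n_va, n - n_tr))])
    test <- c(test, idx[setdiff(seq_len(n), seq_len(n_tr + n_va))])
  }
  list(train = train, val = val, test = test)
}

adam_step_nested <- function(params, grads, st, lr) {
  st$t <- st$t + 1L
  bc1 <- 1 - 0.9^st$t; bc2 <- 1 - 0.999^st$t
  upd <- function(p, g, m, v) {
    m <- 0.9 * m + 0.1 * g
    v <- 0.999 * v + 0.001 * g * g
    list(p = p - lr * (m / bc1) / (sqrt(v / bc2) + 1e-8), m = m, v = v)
  }
  for (i in seq_along(params$conv)) {
    for (nm in c("W", "b")) {
      u <- upd(params$conv[[i]][[nm]], grads$conv[[i]][[nm]],
               st$m$conv[[i]][[nm]], st$v$conv[[i]][[nm]])
      params$conv[[i]][[nm]] <- u$p
      st$m$conv[[i]][[nm]] <- u$m
      st$v$conv[[i]][[nm]] <- u$v
    }
  }
  for (nm in c("W", "b")) {
    u <- upd(params$fc[[nm]], grads$fc[[nm]],
             st$m$fc[[nm]], st$v$fc[[nm]])
    params$fc[[nm]] <- u$p
    st$m$fc[[nm]] <- u$m
    st$v$fc[[nm]] <- u$v
  }
  list(params = params, state = st)
}

zero_like <- function(params) rapply(params, function(x) x * 0, how = "replace")

#' Train the single-cell feature extractor
#'
#' Trains the configured backbone as a supervised single-cell classifier
#' by categorical cross-entropy, with augmentation and probabilistic
#' oversampling, early-stopping on validation loss, and keeping the
#' best-validation weights. Only `"tiny_cnn"` has a trainable
#' implementation here; requesting `"resnet34"` raises an error pointing
#' at its role as configuration for framework-based training.
#'
#' @param images List of H x W x 3 arrays (values in `[0, 1]`), all of
#'   size `cfg$input_size`.
#' @param labels Character vector of single-cell class labels.
#' @param cfg An [extractor_config()].
#' @param split Optional list of `train`/`val`/`test` index vectors;
#'   defaults to a stratified 60/20/20 split.
#' @param verbose Print per-epoch losses.
#' @return Object of class `cytomil_extractor`: `params`, `backbone`,
#'   `classes`, `confusion` (test-set confusion matrix), `test_accuracy`,
#'   `log`, `config`.
#' @export
train_extractor <- function(images, labels, cfg = extractor_config(),
                            split = NULL, verbose = FALSE) {
  if (cfg$backbone != "tiny_cnn") {
    stop("backbone 'resnet34' is configuration for framework-based ",
         "training; the trainable desk-scale backbone is 'tiny_cnn'",
         call. = FALSE)
  }
  keep <- !labels %in% cfg$exclude_classes
  images <- images[keep]
  labels <- labels[keep]
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop_field("labels", "need at least 2 classes after exclusions")
  }
  if (any(vapply(images, function(im) any(dim(im)[1:2] != cfg$input_size),
                 TRUE))) {
    stop_field("images", sprintf("all images must be %d x %d",
                                 cfg$input_size, cfg$input_size))
  }
  backbone <- build_backbone(cfg$backbone, cfg$input_size)
  plan <- cnn_plan(backbone)
  params <- cnn_init_params(backbone, length(classes), seed = cfg$seed)
  st <- list(t = 0L, m = zero_like(params), v = zero_like(params))
  y <- match(labels, classes)

  if (is.null(split)) split <- stratified_split(labels, seed = cfg$seed)
  set.seed(child_seed(cfg$seed, "ext-train"))
  probs <- if (cfg$oversample) oversample_probs(labels[split$train]) else
    rep(1 / length(split$train), length(split$train))

  # inputs are centered ([0,1] -> [-0.5, 0.5]) before entering the network
  eval_loss <- function(idx) {
    mean(vapply(idx, function(i) {
      fw <- cnn_forward(as.vector(images[[i]]) - 0.5, plan, params)
      -log(max(fw$p[y[i]], 1e-12))
    }, numeric(1)))
  }

  best <- list(loss = Inf, epoch = 0L, params = params)
  log_rows <- list()
  n_tr <- length(split$train)
  for (epoch in seq_len(cfg$max_epochs)) {
    order_idx <- sample(split$train, n_tr, replace = cfg$oversample,
                        prob = if (cfg$oversample) probs else NULL)
    tl <- 0
    batch_starts <- seq(1L, n_tr, by = cfg$batch_size)
    for (bs in batch_starts) {
      batch <- order_idx[bs:min(bs + cfg$batch_size - 1L, n_tr)]
      acc <- NULL
      for (i in batch) {
        img <- augment_image(images[[i]], cfg$augment)
        fw <- cnn_forward(as.vector(img) - 0.5, plan, params,
                          keep_cache = TRUE)
        if (!is.finite(fw$p[y[i]])) {
          stop("non-finite extractor loss; aborting", call. = FALSE)
        }
        tl <- tl - log(max(fw$p[y[i]], 1e-12))
        g <- cnn_backward(fw, y[i], plan, params)
        acc <- if (is.null(acc)) g else
          rapply2_add(acc, g)
      }
      sc <- 1 / length(batch)
      acc <- rapply(acc, function(x) x * sc, how = "replace")
      if (cfg$optimizer == "adam") {
        u <- adam_step_nested(params, acc, st, cfg$lr)
        params <- u$params; st <- u$state
      } else {
        params <- sgd_step_nested(params, acc, cfg$lr)
      }
    }
    vl <- eval_loss(split$val)
    log_rows[[epoch]] <- data.frame(epoch = epoch, train_loss = tl / n_tr,
                                    val_loss = vl)
    if (verbose) message(sprintf("extractor epoch %3d train %.4f val %.4f",
                                 epoch, tl / n_tr, vl))
    if (vl < best$loss) best <- list(loss = vl, epoch = epoch,
                                     params = params)
    if (epoch - best$epoch >= cfg$patience) break
  }
  params <- best$params

  test_pred <- vapply(split$test, function(i) {
    which.max(cnn_forward(as.vector(images[[i]]) - 0.5, plan, params)$p)
  }, integer(1))
  cm <- confusion_matrix(classes[y[split$test]], classes[test_pred],
                         classes)
  structure(list(params = params, backbone = backbone, plan = plan,
                 classes = classes, confusion = cm,
                 test_accuracy = mean(test_pred == y[split$test]),
                 split = split,
                 log = do.call(rbind, log_rows),
                 best_epoch = best$epoch,
                 config = cfg),
            class = "cytomil_extractor")
}

rapply2_add <- function(a, b) {
  for (i in seq_along(a$conv)) {
    a$conv[[i]]$W <- a$conv[[i]]$W + b$conv[[i]]$W
    a$conv[[i]]$b <- a$conv[[i]]$b + b$conv[[i]]$b
  }
  a$fc$W <- a$fc$W + b$fc$W
  a$fc$b <- a$fc$b + b$fc$b
  a
}

sgd_step_nested <- function(params, grads, lr) {
  for (i in seq_along(params$conv)) {
    params$conv[[i]]$W <- params$conv[[i]]$W - lr * grads$conv[[i]]$W
    params$conv[[i]]$b <- params$conv[[i]]$b - lr * grads$conv[[i]]$b
  }
  params$fc$W <- params$fc$W - lr * grads$fc$W
  params$fc$b <- params$fc$b - lr * grads$fc$b
  params
}

#' @export
print.cytomil_extractor <- function(x, ...) {
  cat(sprintf("<cytomil_extractor> %s, %d classes, d = %d, test acc %.3f\n",
              x$backbone$backbone, length(x$classes),
              x$backbone$feature_dim, x$test_accuracy))
  invisible(x)
}

#' Extract instance features from images
#'
#' Runs images through the trained extractor in inference mode (no
#' augmentation) and returns the flattened activations of the last
#' convolutional stage -- the network with pooling and classification head
#' removed. Deterministic; output row order equals input order.
#'
#' @param extractor A trained [train_extractor()] object.
#' @param images List of H x W x 3 arrays matching the training input
#'   size, or file paths readable by [read_cell_image()].
#' @return Numeric matrix N x d.
#' @export
extract_features <- function(extractor, images) {
  stopifnot(inherits(extractor, "cytomil_extractor"))
  sz <- extractor$backbone$input_size
  out <- matrix(0, length(images), extractor$backbone$feature_dim)
  for (i in seq_along(images)) {
    img <- if (is.character(images[[i]])) read_cell_image(images[[i]]) else
      images[[i]]
    if (any(dim(img)[1:2] != sz)) {
      stop_field("images", sprintf("image %d is %dx%d, expected %dx%d",
                                   i, dim(img)[1L], dim(img)[2L], sz, sz))
    }
    out[i, ] <- cnn_forward(as.vector(img) - 0.5, extractor$plan,
                            extractor$params)$features
  }
  out
}

#' Export per-patient feature bags
#'
#' Groups extracted features by patient and writes one bag file per
#' patient (see [write_bag()]), preserving the within-patient image order
#' so attention values can be joined back to images by row.
#'
#' @param features N x d feature matrix from [extract_features()].
#' @param image_ids Character vector of image identifiers (row-aligned).
#' @param patient_ids Character vector mapping each row to a patient.
#' @param manifest Cohort manifest with `patient_id` and `label`.
#' @param out_dir Output directory for the bag files.
#' @param classes Allowed labels.
#' @return List of the written [new_bag()] objects, invisibly.
#' @export
export_bags <- function(features, image_ids, patient_ids, manifest,
                        out_dir, classes = cytomil_classes()) {
  orphans <- setdiff(unique(patient_ids), manifest$patient_id)
  if (length(orphans) > 0L) {
    stop(sprintf("images reference patients missing from manifest: %s",
                 paste(orphans, collapse = ", ")), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bags <- list()
  for (pid in unique(patient_ids)) {
    rows <- which(patient_ids == pid)
    label <- manifest$label[manifest$patient_id == pid]
    bag <- new_bag(features[rows, , drop = FALSE], pid, label,
                   classes = classes, cell_ids = image_ids[rows])
    write_bag(bag, file.path(out_dir, paste0(pid, ".tsv")))
    bags[[pid]] <- bag
  }
  invisible(bags)
}
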