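# One trained extractor shared by the tests below: 3 visually distinct
# classes, 48 images each.
trained_extractor <- function() {
  memo("trained_extractor", {
    labs <- rep(c("PML_RARA", "NPM1", "control"), each = 60L)
    imgs <- generate_cell_images(synthetic_image_spec(seed = 31L), labs)
    pix <- lapply(imgs, `[[`, "pixels")
    cfg <- extractor_config(num_classes = 3L, max_epochs = 45L,
                            patience = 10L, seed = 17L)
    list(ext = train_extractor(pix, labs, cfg), pix = pix, labs = labs)
  })
}

test_that("the tiny CNN learns separable synthetic cell classes", {
  tr <- trained_extractor()
  expect_gt(tr$ext$test_accuracy, 0.9)
  # validation loss improved over training
  expect_lt(min(tr$ext$log$val_loss), tr$ext$log$val_loss[1L])
})

test_that("feature extraction is deterministic and augmentation-free", {
  tr <- trained_extractor()
  f1 <- extract_features(tr$ext, tr$pix[1:4])
  f2 <- extract_features(tr$ext, tr$pix[1:4])
  expect_identical(f1, f2)
  expect_identical(dim(f1), c(4L, 72L))
  expect_true(all(is.finite(f1)))
  bad <- list(array(0, c(32L, 32L, 3L)))
  expect_error(extract_features(tr$ext, bad), "expected 144x144")
})

test_that("oversampling probabilities equalize expected class draws", {
  labels <- c(rep("big", 100L), rep("small", 10L))
  pr <- oversample_probs(labels)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  # expected draws per class are uniform: sum of probs per class equal
  expect_equal(sum(pr[labels == "big"]), sum(pr[labels == "small"]),
               tolerance = 1e-12)
  # empirical check: per-class sampling counts within 5% of equality
  set.seed(3)
  draws <- sample(labels, 20000L, replace = TRUE, prob = pr)
  expect_lt(abs(mean(draws == "big") - 0.5), 0.05 * 0.5)
})

test_that("the resnet34 recipe is configuration, not a trainable path", {
  cfg <- extractor_config(backbone = "resnet34", num_classes = 21L,
                          init = "pretrained-imagenet",
                          optimizer = "sgd", lr = 5e-4, patience = 10L)
  expect_identical(cfg$lr, 5e-4)
  expect_identical(cfg$patience, 10L)
  expect_error(train_extractor(list(), character(), cfg), "tiny_cnn")
})

test_that("class exclusion lists drop rare classes before training", {
  labs <- rep(c("a", "b", "erythroblast"), times = c(5L, 5L, 2L))
  imgs <- lapply(seq_along(labs), function(i) array(runif(16L^2 * 3L),
                                                    c(16L, 16L, 3L)))
  cfg <- extractor_config(num_classes = 2L, input_size = 16L,
                          exclude_classes = c("a", "b"))
  expect_error(train_extractor(imgs, labs, cfg), "2 classes")
})

test_that("exported bags round-trip and rows join back to their images", {
  tr <- trained_extractor()
  n <- 12L
  feats <- extract_features(tr$ext, tr$pix[seq_len(n)])
  image_ids <- sprintf("img%03d", seq_len(n))
  patient_ids <- rep(c("pA", "pB"), each = 6L)
  manifest <- data.frame(patient_id = c("pA", "pB"),
                         label = c("NPM1", "control"))
  out <- withr::local_tempdir()
  bags <- export_bags(feats, image_ids, patient_ids, manifest, out)
  expect_identical(dim(bags$pA$features), c(6L, 72L))
  back <- read_bag(file.path(out, "pA.tsv"), "pA", "NPM1")
  expect_equal(back$features, bags$pA$features, tolerance = 1e-6,
               ignore_attr = TRUE)
  # row k of the index maps to the image whose features equal row k
  expect_identical(back$cell_ids, image_ids[1:6])
  expect_equal(unname(back$features[3L, ]), unname(feats[3L, ]),
               tolerance = 1e-6)
  expect_error(export_bags(feats, image_ids, rep("ghost", n), manifest,
                           out), "ghost")
})
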