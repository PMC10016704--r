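test_that("bag generation is deterministic and respects the spec", {
  spec <- synthetic_cohort_spec(n_classes = 3L, bags_per_class = 4L,
                                bag_size_range = c(10L, 30L),
                                feature_dim = 16L,
                                classes = c("PML_RARA", "NPM1", "control"),
                                seed = 7L)
  b1 <- generate_feature_bags(spec)
  b2 <- generate_feature_bags(spec)
  expect_identical(b1, b2)
  expect_length(b1, 12L)
  sizes <- vapply(b1, bag_size, integer(1))
  expect_true(all(sizes >= 10L & sizes <= 30L))
  expect_true(all(vapply(b1, function(b) ncol(b$features), integer(1)) == 16L))
})

test_that("control bags never contain planted instances", {
  bags <- generate_feature_bags(small_spec())
  ctrl <- Filter(function(b) b$label == "control", bags)
  expect_true(length(ctrl) > 0L)
  expect_true(all(vapply(ctrl, function(b) !any(b$planted), logical(1))))
})

test_that("zero planted fraction yields no planted instances anywhere", {
  spec <- synthetic_cohort_spec(n_classes = 3L, bags_per_class = 3L,
                                bag_size_range = c(5L, 10L),
                                feature_dim = 8L, planted_fraction = 0,
                                classes = c("PML_RARA", "NPM1", "control"),
                                seed = 1L)
  bags <- generate_feature_bags(spec)
  expect_false(any(unlist(lapply(bags, function(b) b$planted))))
})

test_that("planted instances carry the class signature mean", {
  spec <- synthetic_cohort_spec(bags_per_class = 40L, feature_dim = 64L,
                                signature_separation = 4, noise_sd = 1,
                                seed = 13L)
  bags <- generate_feature_bags(spec)
  cls1 <- Filter(function(b) b$label == cytomil_classes()[1L], bags)
  planted <- do.call(rbind, lapply(cls1, function(b) {
    b$features[b$planted, , drop = FALSE]
  }))
  # expected mean: separation along the first canonical direction; test
  # the projection on that direction at 3 standard errors and keep the
  # orthogonal coordinates within a Bonferroni-safe 4.5 SE band
  mu_hat <- colMeans(planted)
  se <- apply(planted, 2L, sd) / sqrt(nrow(planted))
  expect_lt(abs(mu_hat[1L] - 4), 3 * se[1L])
  expect_true(all(abs(mu_hat[-1L]) <= 4.5 * se[-1L]))
})

test_that("planted and background populations are linearly separable", {
  bags <- generate_feature_bags(synthetic_cohort_spec(
    bags_per_class = 5L, seed = 3L))
  # within one class, planted cells sit 4 noise-sd from background along
  # that class's signature direction
  aml <- Filter(function(b) b$label == "NPM1" && any(b$planted), bags)
  X <- do.call(rbind, lapply(aml, function(b) b$features))
  y <- unlist(lapply(aml, function(b) b$planted))
  # train/test split; logistic regression as the reference separator
  set.seed(1)
  tr <- sample(length(y), floor(0.7 * length(y)))
  df <- data.frame(y = y, X)
  fit <- suppressWarnings(glm(y ~ ., data = df[tr, ], family = binomial))
  pred <- predict(fit, df[-tr, ], type = "response") > 0.5
  expect_gt(mean(pred == y[-tr]), 0.95)
})

test_that("invalid cohort specs are rejected with the offending field", {
  expect_error(synthetic_cohort_spec(bag_size_range = c(0L, 5L)),
               "bag_size_range")
  expect_error(synthetic_cohort_spec(planted_fraction = 1.2),
               "planted_fraction")
  expect_error(synthetic_cohort_spec(
    planted_fraction = c(0.2, 0.2, 0.2, 0.2, 0.1)), "planted_fraction")
  expect_error(synthetic_cohort_spec(noise_sd = 0), "noise_sd")
  expect_error(synthetic_cohort_spec(n_classes = 3L), "classes")
})

test_that("synthesized manifests tie blast percentage to planted content", {
  bags <- generate_feature_bags(small_spec())
  low_id <- bags[[1L]]$patient_id
  man <- synthesize_manifest(bags, low_blast_ids = low_id, seed = 5L)
  expect_identical(nrow(man), length(bags))
  blast <- man$pct_myeloblasts + man$pct_promyelocytes + man$pct_myelocytes
  expect_lt(blast[man$patient_id == low_id], 20)
  aml <- man$label != "control" & man$patient_id != low_id
  expect_true(all(blast[aml] > 20))
  expect_true(all(blast[man$label == "control"] < 5))
})
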