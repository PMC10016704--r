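test_that("blur filter partitions images and honours strict inequality", {
  imgs <- generate_cell_images(synthetic_image_spec(blur_fraction = 0,
                                                    seed = 12L),
                               rep(c("NPM1", "control"), 5L))
  pix <- lapply(imgs, `[[`, "pixels")
  res <- filter_blurry(pix)
  expect_identical(nrow(res$kept) + nrow(res$excluded), 10L)
  expect_length(intersect(res$kept$image, res$excluded$image), 0L)

  # threshold 0: edge_sum >= 0 can never be strictly below it
  res0 <- filter_blurry(pix, edge_filter_config(edge_sum_threshold = 0))
  expect_identical(nrow(res0$excluded), 0L)

  # an image exactly at the threshold is kept (strict "<" semantics)
  s <- edge_sum(pix[[1L]])
  at <- filter_blurry(pix[1L],
                      edge_filter_config(edge_sum_threshold = s))
  expect_identical(nrow(at$excluded), 0L)
  above <- filter_blurry(pix[1L],
                         edge_filter_config(edge_sum_threshold = s + 1))
  expect_identical(nrow(above$excluded), 1L)
})

test_that("blast filter excludes below 20% with controls exempt", {
  man <- data.frame(
    patient_id = c("a", "b", "c", "d"),
    label = c("NPM1", "NPM1", "NPM1", "control"),
    pct_myeloblasts = c(10, 12, 30, 0),
    pct_promyelocytes = c(5, 5, 10, 0),
    pct_myelocytes = c(4, 3, 5, 0))
  res <- filter_low_blast(man)
  # a: 19% -> excluded; b: exactly 20% -> kept; c: 45% -> kept; control kept
  expect_identical(res$excluded$patient_id, "a")
  expect_identical(res$kept$patient_id, c("b", "c", "d"))
  expect_identical(res$excluded$reason, "low_blast")

  man_missing <- man[, setdiff(names(man), "pct_myelocytes")]
  expect_error(filter_low_blast(man_missing), "pct_myelocytes")
})

test_that("manual exclusions drop listed patients and warn on unknowns", {
  man <- data.frame(patient_id = c("a", "b", "c"),
                    label = c("NPM1", "NPM1", "control"))
  expect_identical(apply_manual_exclusions(man)$kept, man)
  res <- apply_manual_exclusions(man, c("a", "c"))
  expect_identical(res$kept$patient_id, "b")
  expect_warning(res2 <- apply_manual_exclusions(man, c("a", "ghost")),
                 "ghost")
  expect_identical(res2$kept$patient_id, c("b", "c"))
  expect_identical(res2$unknown_ids, "ghost")
})

test_that("the QC cascade reports constructed exclusion counts exactly", {
  # 3 patients x 8 images; patient p2 gets 3 blurred images by rendering
  # them separately; p3 is low-blast by manifest construction
  sharp_spec <- synthetic_image_spec(blur_fraction = 0, seed = 21L)
  blur_spec <- synthetic_image_spec(blur_fraction = 1, seed = 22L)
  imgs <- list(
    p1 = generate_cell_images(sharp_spec, rep("NPM1", 8L)),
    p2 = c(generate_cell_images(sharp_spec, rep("NPM1", 5L)),
           generate_cell_images(blur_spec, rep("NPM1", 3L))),
    p3 = generate_cell_images(sharp_spec, rep("control", 8L)))
  cohort <- list(
    manifest = data.frame(
      patient_id = c("p1", "p2", "p3"),
      label = c("NPM1", "NPM1", "control"),
      pct_myeloblasts = c(30, 10, 0),
      pct_promyelocytes = c(10, 4, 0),
      pct_myelocytes = c(5, 2, 0)),
    images = lapply(imgs, function(v) lapply(v, `[[`, "pixels")))
  rep1 <- run_qc_cascade(cohort, manual_exclusions = "p1")

  expect_identical(rep1$stages$n_images,
                   c(24L, 21L, 16L, 8L))   # 3 blurry, then p2 low-blast, p1 manual
  expect_identical(rep1$stages$n_patients, c(3L, 3L, 2L, 1L))
  expect_identical(nrow(rep1$image_exclusions), 3L)
  expect_setequal(rep1$patient_exclusions$patient_id, c("p2", "p1"))
  expect_identical(rep1$manifest$patient_id, "p3")

  # counts are monotone non-increasing along the cascade
  expect_true(all(diff(rep1$stages$n_images) <= 0))
  expect_true(all(diff(rep1$stages$n_patients) <= 0))

  # idempotence: re-running on the cleaned output excludes nothing
  rep2 <- run_qc_cascade(list(manifest = rep1$manifest,
                              images = rep1$images))
  expect_identical(rep2$stages$n_images[1L],
                   rep2$stages$n_images[4L])
  expect_identical(rep2$stages$n_patients[1L], rep2$stages$n_patients[4L])

  # JSON serialization round-trips the stage counts
  path <- withr::local_tempfile(fileext = ".json")
  write_consort_json(rep1, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(as.integer(parsed$stages$n_images),
                   rep1$stages$n_images)
})
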