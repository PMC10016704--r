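test_that("instance predictions agree with singleton-bag forward passes", {
  st <- small_trained()
  bag <- st$test_bags[[1L]]
  inst <- predict_instances(st$fit$params, bag)
  expect_identical(nrow(inst), bag_size(bag))
  expect_identical(inst$cell_id, bag$cell_ids)
  classes <- st$fit$params$classes
  probs <- as.matrix(inst[, classes])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(inst)),
               tolerance = 1e-6)
  for (k in c(1L, bag_size(bag))) {
    single <- new_bag(bag$features[k, , drop = FALSE], "s", bag$label,
                      classes = classes)
    fwd <- mil_forward(single, st$fit$params)
    expect_lt(max(abs(fwd$p - probs[k, ])), 1e-6)
    expect_identical(fwd$label, inst$pred[k])
  }
})

test_that("planted cells are recovered better than background cells", {
  st <- small_trained()
  correct <- Filter(function(b) {
    mil_forward(b, st$fit$params)$label == b$label && b$label != "control" &&
      any(b$planted) && !all(b$planted)
  }, st$test_bags)
  expect_gt(length(correct), 0L)
  rates <- vapply(correct, function(b) {
    inst <- predict_instances(st$fit$params, b)
    hit <- inst$pred == b$label
    c(planted = mean(hit[b$planted]), background = mean(hit[!b$planted]))
  }, numeric(2))
  expect_gt(mean(rates["planted", ]), mean(rates["background", ]))
})

test_that("attention ranking is a stable permutation", {
  st <- small_trained()
  pred <- mil_forward(st$test_bags[[1L]], st$fit$params)
  rk <- rank_by_attention(pred)
  expect_setequal(rk$cell_id, st$test_bags[[1L]]$cell_ids)
  expect_identical(rk$attention, sort(as.numeric(pred$attention)))
  # agreement with an independent sort oracle
  expect_identical(rk$bag_index,
                   order(as.numeric(pred$attention)))
  # ties keep bag order (stable sort)
  tied <- pred
  tied$attention <- rep(0.25, 4L)
  tied$cell_ids <- letters[1:4]
  rk2 <- rank_by_attention(tied)
  expect_identical(rk2$cell_id, letters[1:4])
})

test_that("quartile summaries have balanced sizes and unit fractions", {
  ranked <- data.frame(rank = 1:10,
                       cell_id = sprintf("c%02d", 1:10),
                       bag_index = 1:10,
                       attention = seq(0.01, 0.19, length.out = 10L))
  ann <- data.frame(cell_id = sprintf("c%02d", 1:10),
                    relevance_group = c(rep("healthy", 8L),
                                        rep("relevant", 2L)))
  qs <- quartile_concordance(ranked, ann,
                             relevant_groups = "relevant")
  expect_identical(qs$counts, c(2L, 3L, 2L, 3L))
  expect_lte(max(qs$counts) - min(qs$counts), 1L)
  expect_identical(sum(qs$counts), 10L)
  expect_true(all(abs(rowSums(qs$composition) - 1) < 1e-12))
  # the two top-attention cells sit in the top quartile of 3 cells
  expect_equal(unname(qs$relevant_fraction["Q4"]), 2 / 3,
               tolerance = 1e-12)
  expect_equal(unname(qs$relevant_fraction["Q1"]), 0, tolerance = 1e-12)

  # all cells one group -> every quartile composition is 100% that group
  ann_one <- transform(ann, relevance_group = "only")
  qs_one <- quartile_concordance(ranked, ann_one)
  expect_true(all(qs_one$composition[, "only"] == 1))

  # duplicate annotations are ambiguous
  expect_error(quartile_concordance(ranked, rbind(ann, ann[1L, ])),
               "duplicate")
  # unannotated cells are excluded from fractions but counted
  qs_m <- quartile_concordance(ranked, ann[1:8, ],
                               relevant_groups = "relevant")
  expect_identical(qs_m$n_unannotated, 2L)
})

test_that("top-quartile cells are enriched for planted instances", {
  st <- small_trained()
  res <- attention_planted_auroc(st$fit$params, st$test_bags)
  expect_gt(res$n_used, 0L)
  expect_gt(res$mean_auroc, 0.5)
  expect_gt(mean(res$per_bag$top_quartile_planted_fraction),
            mean(res$per_bag$base_rate))
})

test_that("representative cells are the per-fold activation maxima", {
  st <- small_trained()
  inst <- do.call(rbind, lapply(seq_along(st$test_bags), function(i) {
    out <- predict_instances(st$fit$params, st$test_bags[[i]])
    out$fold <- (i %% 2L) + 1L   # pretend two folds
    out
  }))
  classes <- st$fit$params$classes
  top <- representative_cells(inst, classes = classes, k_per_fold = 2L)
  expect_true(all(table(top$class) <= 4L))   # 2 folds x 2 cells
  for (cl in classes) {
    for (f in 1:2) {
      sel <- top[top$class == cl & top$fold == f, ]
      rest <- inst[inst$fold == f & !inst$cell_id %in% sel$cell_id, ]
      expect_gte(min(sel$activation), max(rest[[cl]]))
    }
  }
  # deterministic under re-evaluation
  expect_identical(top, representative_cells(inst, classes = classes,
                                             k_per_fold = 2L))
})

test_that("subsampling at full bag size reproduces full-bag results", {
  st <- small_trained()
  rob <- subsample_robustness(st$fit$params, st$test_bags,
                              sizes = c(1L, 2L, 5L, 10L, 20L),
                              reps = 10L, seed = 4L)
  full_rows <- rob$by_patient[rob$by_patient$size ==
                                rob$by_patient$full_size, ]
  # the full-size draw is deterministic: accuracy is 0 or 1 per patient
  expect_true(all(full_rows$accuracy %in% c(0, 1)))
  direct <- vapply(st$test_bags, function(b) {
    as.numeric(mil_forward(b, st$fit$params)$label == b$label)
  }, numeric(1))
  expect_identical(mean(direct), rob$full_bag_accuracy)
  expect_identical(mean(direct), mean(full_rows$accuracy))

  # size-1 accuracy equals the fraction of matching single-cell votes in
  # expectation; check it lies within a binomial envelope of the
  # predict_instances rate for one bag
  bag <- st$test_bags[[1L]]
  inst <- predict_instances(st$fit$params, bag)
  p1 <- mean(inst$pred == bag$label)
  r1 <- rob$by_patient[rob$by_patient$patient_id == bag$patient_id &
                         rob$by_patient$size == 1L, "accuracy"]
  expect_lt(abs(r1 - p1), 3 * sqrt(p1 * (1 - p1) / 10) + 1e-9)

  # sizes exceeding a bag are skipped for that patient
  small_bag <- st$test_bags[[which.min(vapply(st$test_bags, bag_size,
                                              integer(1)))]]
  sizes_seen <- rob$by_patient$size[rob$by_patient$patient_id ==
                                      small_bag$patient_id]
  expect_true(all(sizes_seen <= bag_size(small_bag)))

  # baseline exists and covers the ladder
  expect_true(!is.null(rob$baseline))
})
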