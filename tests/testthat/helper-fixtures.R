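# Shared test fixtures. Expensive objects (trained models, the full
# synthetic-cohort cross-validation) are computed once per test run and
# memoized in this environment so several test files can reuse them.
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# A small, quickly separable cohort for unit tests of training,
# explainability and reporting: 3 classes (control last), tiny bags.
small_spec <- function(seed = 7L) {
  synthetic_cohort_spec(
    n_classes = 3L, bags_per_class = 10L, bag_size_range = c(16L, 30L),
    feature_dim = 8L, planted_fraction = 0.4, signature_separation = 6,
    noise_sd = 1, classes = c("PML_RARA", "NPM1", "control"), seed = seed)
}

small_cfg <- function(seed = 3L) {
  mil_config(embed_dim = 16L, attention_dim = 8L, lr = 2e-3,
             patience = 5L, max_epochs = 40L, seed = seed,
             classes = c("PML_RARA", "NPM1", "control"))
}

small_trained <- function() {
  memo("small_trained", {
    bags <- generate_feature_bags(small_spec())
    ids <- vapply(bags, function(b) b$patient_id, character(1))
    man <- data.frame(patient_id = ids,
                      label = vapply(bags, function(b) b$label, character(1)))
    split <- make_folds(man, k = 5L, seed = 2L)[[1L]]
    fit <- train_mil(bags, split, small_cfg())
    list(bags = bags, split = split, fit = fit,
         test_bags = bags[ids %in% split$test])
  })
}

# The full synthetic study: default cohort (5 classes x 40 bags, bag
# sizes 99-500, d = 64, planted fraction 0.2, separation 4 sd) with
# 5-fold cross-validation under the width-matched study configuration.
default_cohort_cv <- function() {
  memo("default_cohort_cv", {
    spec <- synthetic_cohort_spec(seed = 101L)
    bags <- generate_feature_bags(spec)
    cv <- cross_validate(bags, cfg = synthetic_study_config(seed = 11L),
                         k = 5L, seed = 5L)
    list(spec = spec, bags = bags, cv = cv)
  })
}
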