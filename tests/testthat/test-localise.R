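# Random-forest SOZ localisation: separable and null behaviour, AUC
# invariances, up-sampling containment, chance calibration, contributions.

make_table <- function(n_soz = 10, n_non = 20, n_feat = 20, delta = 0,
                       seed = 1, label_copy = FALSE) {
  set.seed(seed)
  n <- n_soz + n_non
  soz <- rep(c(TRUE, FALSE), c(n_soz, n_non))
  cols <- sprintf("M%02d__f", seq_len(n_feat))
  X <- matrix(rnorm(n * n_feat), n, dimnames = list(NULL, cols))
  X[soz, 1] <- X[soz, 1] + delta
  if (label_copy) X[, 1] <- as.numeric(soz)
  out <- data.frame(patient = "p", contact = 1:n, soz = soz, X,
                    check.names = FALSE)
  class(out) <- c("feature_table", "data.frame")
  out
}

test_that("the internal AUC matches pROC and is monotone-transform invariant", {
  set.seed(1)
  scores <- rnorm(40)
  labels <- runif(40) < 0.4
  ours <- auc_score(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
  # strictly monotone transforms leave AUC unchanged
  expect_equal(auc_score(exp(scores), labels), ours)
  expect_equal(auc_score(rank(scores), labels), ours)
})

test_that("a label-copy feature is perfectly separable", {
  tab <- make_table(label_copy = TRUE)
  cfg <- classifier_config(n_upsample_repeats = 2, seed = 1)
  cv <- train_eval_cv(tab, cfg)
  expect_equal(cv$auc, 1.0)
})

test_that("label-independent features give chance-level AUC", {
  tab <- make_table(n_soz = 20, n_non = 40, seed = 2)
  cfg <- classifier_config(n_upsample_repeats = 60, seed = 3)
  cv <- train_eval_cv(tab, cfg)
  expect_lt(abs(cv$auc - 0.5), 0.07)
})

test_that("one informative feature among noise is learnable when pooled", {
  tab <- make_table(n_soz = 60, n_non = 140, n_feat = 78, delta = 2,
                    seed = 4)
  cfg <- classifier_config(n_upsample_repeats = 3, seed = 5)
  cv <- train_eval_cv(tab, cfg)
  expect_gt(cv$auc, 0.8)
})

test_that("test rows are never duplicated and folds stay stratified", {
  y <- rep(c(TRUE, FALSE), c(4, 16))
  idx <- sozflow:::upsample_idx(y)
  expect_equal(sum(y[idx]), sum(!y[idx]))            # exact balance
  expect_identical(idx[1:20], 1:20)                  # originals untouched
  expect_true(all(y[idx[-(1:20)]]))                  # only minority repeated
  set.seed(6)
  folds <- sozflow:::make_folds(y, 4)
  expect_true(all(table(folds, y)[, "TRUE"] == 1))   # stratification
  # up-sampling happens strictly inside the train fold: per fold, the
  # union of train indices after up-sampling never meets the test fold
  for (f in 1:4) {
    tr <- which(folds != f)
    ui <- tr[sozflow:::upsample_idx(y[folds != f])]
    expect_length(intersect(ui, which(folds == f)), 0)
  }
})

test_that("fold counts shrink with tiny minority classes, with a warning", {
  tab <- make_table(n_soz = 3, n_non = 17, delta = 3, seed = 7)
  cfg <- classifier_config(n_folds = 10, n_upsample_repeats = 1, seed = 8)
  expect_warning(cv <- train_eval_cv(tab, cfg), "folds reduced")
  expect_equal(cv$n_folds, 3)
  expect_error(train_eval_cv(make_table(n_soz = 1, n_non = 10)),
               "unsplittable")
})

test_that("classification is deterministic given the seed", {
  tab <- make_table(n_soz = 8, n_non = 16, delta = 1, seed = 9)
  cfg <- classifier_config(n_folds = 8, n_upsample_repeats = 3, seed = 10)
  expect_equal(train_eval_cv(tab, cfg)$auc, train_eval_cv(tab, cfg)$auc,
               tolerance = 1e-12)
})

test_that("chance distributions centre on 0.5 and flag separable tables", {
  tab <- make_table(n_soz = 10, n_non = 20, label_copy = TRUE, seed = 11)
  cfg <- classifier_config(n_upsample_repeats = 1, n_chance_shuffles = 150,
                           seed = 12)
  ch <- chance_distribution(tab, cfg)
  expect_length(ch$chance_aucs, 150)
  expect_lt(abs(ch$chance_mean - 0.5), 0.03)
  expect_gt(ch$true_auc, quantile(ch$chance_aucs, 0.99))
  expect_gt(ch$bf$bf10, 1)
})

test_that("shuffled-label tables do not beat their own chance distribution", {
  h1 <- 0
  for (s in 1:10) {
    tab <- make_table(n_soz = 8, n_non = 16, seed = 300 + s)
    cfg <- classifier_config(n_upsample_repeats = 1, n_chance_shuffles = 40,
                             seed = 400 + s)
    ch <- suppressWarnings(chance_distribution(tab, cfg))
    if (identical(ch$bf$evidence, "H1")) h1 <- h1 + 1
  }
  expect_lte(h1, 1)
})

test_that("permutation contributions rank a dominant predictor first", {
  tab <- make_table(n_soz = 12, n_non = 24, n_feat = 12, label_copy = TRUE,
                    seed = 13)
  cfg <- classifier_config(n_upsample_repeats = 1, seed = 14)
  fc <- feature_contribution(tab, cfg)
  expect_identical(names(which.max(fc$contribution)), "M01__f")
  expect_length(fc$contribution, 12)
})

test_that("all-noise contributions hover around zero", {
  tab <- make_table(n_soz = 15, n_non = 30, n_feat = 30, seed = 15)
  cfg <- classifier_config(n_upsample_repeats = 2, seed = 16)
  fc <- feature_contribution(tab, cfg)
  centred <- abs(fc$contribution - mean(fc$contribution))
  expect_gte(mean(centred <= 2 * sd(fc$contribution)), 0.7)
})

test_that("run_localisation aggregates patients and reports a group BF", {
  tabs <- lapply(1:5, function(i)
    make_table(n_soz = 6, n_non = 12, delta = 3, seed = 500 + i))
  names(tabs) <- sprintf("p%02d", 1:5)
  tabs <- lapply(names(tabs), function(nm) {
    t <- tabs[[nm]]; t$patient <- nm; t
  })
  names(tabs) <- sprintf("p%02d", 1:5)
  cfg <- classifier_config(n_upsample_repeats = 2, n_chance_shuffles = 30,
                           seed = 17)
  lr <- run_localisation(tabs, cfg)
  expect_s3_class(lr, "localisation_result")
  expect_equal(nrow(lr$auc), 5)
  expect_true(all(lr$auc$auc >= 0 & lr$auc$auc <= 1))
  expect_gt(mean(lr$auc$auc), 0.8)
  expect_false(is.null(lr$group_bf))
})
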