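# SOZ localisation: bagged decision-tree classification of contacts with
# stratified cross-validation, train-fold up-sampling, label-shuffle chance
# distributions and OOB permutation feature contributions.

#' Classifier configuration
#'
#' @param n_trees trees in the bagged ensemble (default 50).
#' @param n_folds cross-validation folds (default 10; reduced with a warning
#'   when the minority class is smaller).
#' @param n_upsample_repeats full classification repetitions with fresh fold
#'   and bootstrap randomness (default 100; 1000 restores the full protocol).
#' @param n_chance_shuffles label permutations for the chance distribution
#'   (default 1000).
#' @param seed integer seed.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(n_trees = 50L, n_folds = 10L,
                              n_upsample_repeats = 100L,
                              n_chance_shuffles = 1000L, seed = 1L) {
  stopifnot(n_folds >= 2, n_trees >= 1)
  structure(list(n_trees = as.integer(n_trees), n_folds = as.integer(n_folds),
                 n_upsample_repeats = as.integer(n_upsample_repeats),
                 n_chance_shuffles = as.integer(n_chance_shuffles),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Stratified fold assignment
#' @noRd
make_folds <- function(labels, n_folds) {
  f <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    f[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  f
}

#' Duplicate minority-class rows until exact balance
#' @noRd
upsample_idx <- function(labels) {
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == n0) return(seq_along(labels))
  minority <- if (n1 < n0) which(labels) else which(!labels)
  extra <- rep_len(minority, abs(n0 - n1))
  c(seq_along(labels), extra)
}

#' Cross-validated classification of SOZ vs non-SOZ contacts
#'
#' Stratified k-fold split; within each fold the features are z-scored on
#' training statistics only, the minority class is up-sampled (row
#' repetition) to exact balance in the training set only, and a bagged
#' ensemble of decision trees (bootstrap per tree, sqrt(p) candidate features
#' per split, Gini impurity, unlimited depth) is fitted. Test rows are scored
#' by the ensemble vote fraction and the AUC computed over the pooled
#' out-of-fold scores. The whole procedure is repeated
#' `n_upsample_repeats` times with fresh fold/bootstrap randomness and the
#' final AUC is the mean.
#'
#' @param features a `feature_table` (one patient's contacts, typically).
#' @param config a [classifier_config()].
#' @param keep_fits retain the per-fold forests of the last repeat (needed by
#'   [feature_contribution()]).
#' @return list: `auc` (mean over repeats), `auc_repeats`, `scores`
#'   (out-of-fold vote fractions, last repeat), `labels`, `fits` (optional).
#' @export
train_eval_cv <- function(features, config = classifier_config(),
                          keep_fits = FALSE) {
  fc <- feature_cols(features)
  X <- as.matrix(features[fc])
  y <- as.logical(features$soz)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 < 2 || n0 < 2) stop("unsplittable: need >= 2 contacts per class")
  k <- min(config$n_folds, n1, n0)
  if (k < config$n_folds)
    warning("folds reduced to ", k, " (minority class size)")
  mtry <- max(1L, floor(sqrt(length(fc))))

  with_seed(config$seed, {
    aucs <- numeric(config$n_upsample_repeats)
    scores <- labels <- NULL
    fits <- NULL
    for (rep_i in seq_len(config$n_upsample_repeats)) {
      folds <- make_folds(y, k)
      sc <- rep(NA_real_, length(y))
      rep_fits <- if (keep_fits && rep_i == config$n_upsample_repeats)
        vector("list", k) else NULL
      for (fold in seq_len(k)) {
        tr <- folds != fold; te <- !tr
        mu <- colMeans(X[tr, , drop = FALSE])
        sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
        sdv[sdv == 0] <- 1
        Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
        Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sdv, "/")
        ui <- upsample_idx(y[tr])
        fit <- randomForest::randomForest(
          x = Xtr[ui, , drop = FALSE],
          y = factor(y[tr][ui], levels = c(FALSE, TRUE)),
          ntree = config$n_trees, mtry = mtry,
          importance = !is.null(rep_fits))
        sc[te] <- stats::predict(fit, Xte, type = "prob")[, "TRUE"]
        if (!is.null(rep_fits)) rep_fits[[fold]] <- fit
      }
      aucs[rep_i] <- auc_score(sc, y)
      scores <- sc; labels <- y
      if (!is.null(rep_fits)) fits <- rep_fits
    }
    out <- list(auc = mean(aucs), auc_repeats = aucs,
                scores = scores, labels = labels, n_folds = k)
    if (keep_fits) out$fits <- fits
    out
  })
}

#' Label-shuffle chance distribution and Bayes factor versus chance
#'
#' Permutes the SOZ labels `n_chance_shuffles` times, re-runs
#' [train_eval_cv()] with a single repeat each, and tests the true AUC
#' against the chance distribution with a JZS Bayes factor whose t-statistic
#' is the standardised position of the true AUC within the chance
#' distribution, `(true - mean(chance)) / sd(chance)`. (A naive one-sample
#' t-test on the (true - chance) differences would scale its t-statistic
#' with the square root of the number of shuffles and flag null tables as
#' significant; the standardised form stays calibrated under label
#' shuffling.)
#'
#' @param features a `feature_table`.
#' @param config a [classifier_config()].
#' @param true_auc the observed AUC (computed fresh when NULL).
#' @return list: `chance_aucs`, `chance_mean`, `true_auc`, `bf` (a
#'   `bf_result`).
#' @export
chance_distribution <- function(features, config = classifier_config(),
                                true_auc = NULL) {
  if (is.null(true_auc))
    true_auc <- train_eval_cv(features, config)$auc
  cfg1 <- config
  cfg1$n_upsample_repeats <- 1L
  chance <- with_seed(sub_seed(config$seed, "chance"), {
    vapply(seq_len(config$n_chance_shuffles), function(i) {
      shuf <- features
      shuf$soz <- sample(shuf$soz)
      cfg1$seed <- sub_seed(config$seed, "shuffle", i)
      suppressWarnings(train_eval_cv(shuf, cfg1)$auc)
    }, numeric(1))
  })
  z <- (true_auc - mean(chance)) / max(stats::sd(chance), 1e-12)
  bf <- jzs_bf_ttest(t_stat = z, n = length(chance))
  list(chance_aucs = chance, chance_mean = mean(chance),
       true_auc = true_auc, bf = bf)
}

#' OOB permutation feature contributions
#'
#' For each feature, its values are permuted among the out-of-bag rows of
#' every tree and the contribution is the mean increase in OOB
#' misclassification error divided by its standard deviation across trees
#' (the standard permutation-importance definition), averaged over the
#' cross-validation folds. Grouped summaries concatenate the per-feature
#' contributions by measure (13 groups of 6) and by metric (6 groups of 13).
#'
#' @param features a `feature_table`.
#' @param config a [classifier_config()].
#' @return list: `contribution` (named per-feature vector), `by_measure`,
#'   `by_metric` (lists of concatenated group samples).
#' @export
feature_contribution <- function(features, config = classifier_config()) {
  cv <- suppressWarnings(train_eval_cv(features, config, keep_fits = TRUE))
  imp <- rowMeans(vapply(cv$fits, function(f)
    randomForest::importance(f, type = 1, scale = TRUE)[, 1],
    numeric(length(feature_cols(features)))))
  names(imp) <- feature_cols(features)
  parts <- strsplit(names(imp), "__", fixed = TRUE)
  measure <- vapply(parts, `[[`, "", 1L)
  metric <- vapply(parts, `[[`, "", 2L)
  list(contribution = imp,
       by_measure = split(unname(imp), measure),
       by_metric = split(unname(imp), metric),
       auc = cv$auc)
}

#' Run the localisation analysis over a cohort of feature tables
#'
#' Applies [train_eval_cv()] (and optionally the chance analysis) per
#' patient, then tests the patient AUCs against their chance means with a
#' paired JZS Bayes-factor t-test at the group level. Feature contributions
#' are pooled across patients for the grouped measure/metric comparisons.
#'
#' @param features_by_patient named list of per-patient `feature_table`s.
#' @param config a [classifier_config()].
#' @param chance run the label-shuffle chance analysis (default TRUE).
#' @param contributions collect permutation feature contributions.
#' @return object of class `localisation_result`: per-patient data frame
#'   `auc` (patient, auc, chance_mean, bf10, evidence), `group_bf`
#'   (`bf_result` of AUC vs chance across patients), `contributions`
#'   (patients x features matrix or NULL).
#' @export
run_localisation <- function(features_by_patient,
                             config = classifier_config(),
                             chance = TRUE, contributions = FALSE) {
  res <- lapply(names(features_by_patient), function(pid) {
    tab <- features_by_patient[[pid]]
    cfg <- config
    cfg$seed <- sub_seed(config$seed, "localise", pid)
    cv <- suppressWarnings(train_eval_cv(tab, cfg))
    row <- list(patient = pid, auc = cv$auc)
    if (chance) {
      ch <- chance_distribution(tab, cfg, true_auc = cv$auc)
      row$chance_mean <- ch$chance_mean
      row$bf10 <- ch$bf$bf10
      row$evidence <- ch$bf$evidence
    }
    contrib <- if (contributions)
      feature_contribution(tab, cfg)$contribution else NULL
    list(row = as.data.frame(row), contrib = contrib)
  })
  auc_tab <- do.call(rbind, lapply(res, `[[`, "row"))
  group_bf <- if (chance && nrow(auc_tab) >= 3)
    jzs_bf_ttest(auc_tab$auc - auc_tab$chance_mean) else NULL
  contrib_mat <- if (contributions)
    do.call(rbind, lapply(res, `[[`, "contrib")) else NULL
  if (!is.null(contrib_mat)) rownames(contrib_mat) <- auc_tab$patient
  structure(list(auc = auc_tab, group_bf = group_bf,
                 contributions = contrib_mat),
            class = "localisation_result")
}

#' @export
print.localisation_result <- function(x, ...) {
  cat(sprintf("SOZ localisation: %d patients, mean AUC = %.3f\n",
              nrow(x$auc), mean(x$auc$auc)))
  if (!is.null(x$group_bf))
    cat(sprintf("  group AUC vs chance: BF10 = %.4g (%s)\n",
                x$group_bf$bf10, x$group_bf$evidence))
  invisible(x)
}
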