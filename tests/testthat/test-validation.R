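test_that("grouped stratified splits partition samples without leakage", {
  ss <- generate_study(study_design(samples_per_class = 10,
                                    spectra_per_sample = 2,
                                    short_sample_spectra = 2,
                                    axis_step = 50, seed = 3))
  folds <- grouped_stratified_split(ss, 3, seed = 7)
  labs <- sample_labels(ss)
  test_ids <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(test_ids)), sort(names(labs)))
  for (i in 1:2) for (j in (i + 1):3)
    expect_length(intersect(test_ids[[i]], test_ids[[j]]), 0)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_length(f$test, 10)
    per_class <- table(labs[f$test])
    expect_true(all(per_class >= 3 & per_class <= 4))
    # no test spectrum's sample occurs in the training side
    expect_false(any(ss$meta$sample_id[ss$meta$sample_id %in% f$test] %in%
                       f$train))
  }
  expect_error(grouped_stratified_split(ss, 11), "need >= 11")
})

test_that("majority vote matches an exhaustive counting oracle", {
  cfg <- cv_config()
  classes <- c("NORMAL", "MSS", "MSI_H")
  onehot <- function(counts) {
    votes <- rep(classes, counts)
    m <- matrix(0, length(votes), 3, dimnames = list(NULL, classes))
    m[cbind(seq_along(votes), match(votes, classes))] <- 1
    m
  }
  oracle <- function(counts) {
    names(counts) <- classes
    winners <- names(counts)[counts == max(counts)]
    winners[order(match(winners, cfg$tie_break_order))][1]
  }
  for (n in 1:6) {
    for (a in 0:n) for (b in 0:(n - a)) {
      counts <- c(a, b, n - a - b)
      if (sum(counts) == 0) next
      expect_identical(majority_vote(onehot(counts), cfg), oracle(counts))
    }
  }
  expect_error(majority_vote(onehot(c(0, 0, 0))[0, , drop = FALSE], cfg),
               "at least one")
})

test_that("two-class votes threshold on MSS and ties break to MSI-H", {
  cfg <- cv_config()
  p <- function(mss) cbind(MSS = mss, MSI_H = 1 - mss)
  expect_identical(majority_vote(p(c(rep(0.9, 20), rep(0.1, 10))), cfg), "MSS")
  # 25/25 tie resolves to the clinically worst label
  expect_identical(majority_vote(p(c(rep(0.9, 25), rep(0.1, 25))), cfg),
                   "MSI_H")
  # threshold is configurable: at 0.95, a 0.9 spectrum votes MSI-H
  strict <- cv_config(decision_threshold = 0.95)
  expect_identical(majority_vote(p(rep(0.9, 3)), strict), "MSI_H")
})

test_that("inner CV selects the better grid point by log loss", {
  ss <- generate_study(small_design(seed = 61), separable_profiles())
  grid <- list(model_spec("pca_lda", n_components = 5),
               model_spec("pca_lda", n_components = 1))
  aug <- augmentation_config(factor = 2)
  sel <- select_hyperparameters(ss, grid, aug, seed = 4)
  expect_equal(sel$hyperparameters$n_components, 5)
  # determinism and the singleton shortcut
  sel2 <- select_hyperparameters(ss, grid, aug, seed = 4)
  expect_identical(sel, sel2)
  expect_identical(select_hyperparameters(ss, grid[2], aug, seed = 4),
                   grid[[2]])
  expect_error(select_hyperparameters(ss, list(), aug), "empty")
  # infeasible grid points are excluded with a warning; all-failing errors
  bad <- model_spec("pca_lda", n_components = 500)
  expect_warning(sel3 <- select_hyperparameters(ss, list(bad, grid[[1]]),
                                                aug, seed = 4),
                 "excluding")
  expect_equal(sel3$hyperparameters$n_components, 5)
  expect_error(suppressWarnings(
    select_hyperparameters(ss, list(bad, model_spec("pca_lda",
                                                    n_components = 600)),
                           aug, seed = 4)),
    "every grid point failed")
})

test_that("nested CV emits repeats x folds results with no sample leakage", {
  ss <- generate_study(small_design(seed = 67), separable_profiles())
  cfg <- cv_config(outer_folds = 3, repeats = 2, seed = 11)
  folds <- nested_cv(ss, list(model_spec("pca_lda", n_components = 5),
                              model_spec("pca_lda", n_components = 8)),
                     augmentation_config(factor = 2), cfg = cfg)
  expect_length(folds, 6)
  for (fr in folds) {
    expect_length(intersect(fr$train_samples, fr$test_samples), 0)
    expect_identical(unname(fr$voted %in% raman_classes()),
                     rep(TRUE, length(fr$voted)))
    expect_true(all(abs(rowSums(fr$sample_probs) - 1) < 1e-6))
  }
  # within one repeat every sample is tested exactly once
  for (r in 1:2) {
    tested <- unlist(lapply(Filter(function(f) f$repeat_index == r, folds),
                            `[[`, "test_samples"))
    expect_equal(sort(tested), sort(names(sample_labels(ss))))
  }
  # augmented input is refused outright
  aug <- augment_training_set(ss, augmentation_config(factor = 2, seed = 1))
  expect_error(nested_cv(aug, list(model_spec("pca_lda")), cfg = cfg),
               "augmented")
})

test_that("metrics are exact for perfect and uniform predictions", {
  classes <- c("NORMAL", "MSS", "MSI_H")
  truth <- rep(classes, each = 2)
  perfect <- matrix(0, 6, 3, dimnames = list(NULL, classes))
  perfect[cbind(1:6, match(truth, classes))] <- 1
  fr <- make_fold_result(truth, perfect, truth)
  m <- compute_metrics(list(fr))
  expect_equal(m$per_fold$accuracy, 1)
  expect_lt(m$per_fold$log_loss, 1e-10)
  expect_true(all(diag(m$confusion) == 100))
  # uniform three-class probabilities score log loss = ln 3
  uni <- matrix(1 / 3, 6, 3, dimnames = list(NULL, classes))
  fr_u <- make_fold_result(truth, uni, rep("MSI_H", 6))
  expect_equal(compute_metrics(list(fr_u))$per_fold$log_loss, log(3),
               tolerance = 1e-12)
})

test_that("binary metrics agree with a hand-counted rank oracle", {
  probs_pos <- c(0.9, 0.8, 0.8, 0.6, 0.55)
  probs_neg <- c(0.7, 0.4, 0.3, 0.2, 0.1)
  truth <- c(rep("MSS", 5), rep("MSI_H", 5))
  p <- cbind(MSS = c(probs_pos, probs_neg),
             MSI_H = 1 - c(probs_pos, probs_neg))
  cfg <- cv_config()
  voted <- ifelse(p[, "MSS"] >= 0.5, "MSS", "MSI_H")
  fr <- make_fold_result(truth, p, voted, classes = c("MSS", "MSI_H"))
  m <- compute_metrics(list(fr), cfg)
  # oracle: direct counts at threshold 0.5
  expect_equal(m$per_fold$sensitivity, mean(probs_pos >= 0.5))
  expect_equal(m$per_fold$specificity, mean(probs_neg < 0.5))
  expect_equal(m$per_fold$sensitivity, 1.0)
  expect_equal(m$per_fold$specificity, 0.8)
  # oracle AUROC: exhaustive pair counting with half-credit for ties
  pairs <- expand.grid(pos = probs_pos, neg = probs_neg)
  auc_oracle <- mean(ifelse(pairs$pos > pairs$neg, 1,
                            ifelse(pairs$pos == pairs$neg, 0.5, 0)))
  expect_equal(m$per_fold$auroc, auc_oracle, tolerance = 1e-12)
  expect_equal(auc_oracle, 23 / 25)
})

test_that("log loss over constant predictors is minimised by the prior", {
  truth <- c(rep("NORMAL", 5), rep("MSS", 3), rep("MSI_H", 2))
  prior <- c(NORMAL = 0.5, MSS = 0.3, MSI_H = 0.2)
  const <- function(q) matrix(rep(q, each = 10), 10, 3,
                              dimnames = list(NULL, names(prior)))
  at_prior <- log_loss(const(prior), truth)
  # closed form: the entropy of the label distribution
  expect_equal(at_prior, -sum(prior * log(prior)), tolerance = 1e-12)
  for (shift in list(c(0.6, 0.2, 0.2), c(0.4, 0.4, 0.2), c(1, 2, 2) / 5))
    expect_gt(log_loss(const(shift), truth), at_prior)
})

test_that("ROC curves behave at the perfect and chance extremes", {
  cfg <- cv_config()
  # perfect separation: curve passes through (0, 1)
  truth <- c(rep("MSS", 4), rep("MSI_H", 4))
  p <- cbind(MSS = c(0.9, 0.85, 0.8, 0.75, 0.3, 0.2, 0.15, 0.1))
  p <- cbind(p, MSI_H = 1 - p[, 1])
  fr <- make_fold_result(truth, p, truth, classes = c("MSS", "MSI_H"))
  rc <- roc_curve(list(fr), cfg)
  expect_equal(rc$mean$tpr_mean[rc$mean$fpr == 0][1], 1)
  expect_true(all(diff(rc$mean$tpr_mean) >= 0))
  pf <- rc$per_fold
  expect_true(all(diff(pf$fpr) >= 0) && all(diff(pf$tpr) >= 0))
  expect_equal(compute_metrics(list(fr), cfg)$per_fold$auroc, 1)
  # label-independent scores: AUROC near 1/2 at large n
  set.seed(29)
  n <- 400
  truth2 <- sample(rep(c("MSS", "MSI_H"), each = n / 2))
  s <- runif(n)
  p2 <- cbind(MSS = s, MSI_H = 1 - s)
  fr2 <- make_fold_result(truth2, p2,
                          ifelse(s >= 0.5, "MSS", "MSI_H"),
                          classes = c("MSS", "MSI_H"))
  expect_lt(abs(compute_metrics(list(fr2), cfg)$per_fold$auroc - 0.5), 0.1)
})
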