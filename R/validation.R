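#' Cross-validation configuration
#'
#' @param outer_folds Outer folds per repeat (>= 2); default 3.
#' @param repeats Number of re-seeded repeats (>= 1); default 5. The default
#'   3 x 5 design yields 15 outer-fold performance estimates.
#' @param inner_folds Folds of the inner hyperparameter-selection loop;
#'   default 3.
#' @param decision_threshold Probability threshold for the two-class
#'   spectrum vote (default 0.5, applied to the MSS probability).
#' @param seed Base integer seed; each repeat derives its own substream.
#' @param tie_break_order Classes ordered from clinically worst to best;
#'   voting ties resolve to the earliest entry. Default puts MSI-H first
#'   (it triggers the Lynch-syndrome follow-up cascade), then MSS, then
#'   NORMAL.
#' @return A `cv_config` object.
#' @export
cv_config <- function(outer_folds = 3, repeats = 5, inner_folds = 3,
                      decision_threshold = 0.5, seed = 1,
                      tie_break_order = c("MSI_H", "MSS", "NORMAL")) {
  if (outer_folds < 2) stop("outer_folds must be >= 2")
  if (repeats < 1) stop("repeats must be >= 1")
  if (inner_folds < 2) stop("inner_folds must be >= 2")
  if (decision_threshold <= 0 || decision_threshold >= 1)
    stop("decision_threshold must be in (0, 1)")
  if (anyDuplicated(tie_break_order))
    stop("tie_break_order must not repeat classes")
  structure(list(outer_folds = as.integer(outer_folds),
                 repeats = as.integer(repeats),
                 inner_folds = as.integer(inner_folds),
                 decision_threshold = decision_threshold,
                 seed = as.integer(seed),
                 tie_break_order = tie_break_order),
            class = "cv_config")
}

#' Sample-grouped, class-stratified k-fold partition
#'
#' Partitions the distinct samples (never individual spectra) of a
#' `sample_set` into `k` folds, stratified by class, so that all spectra of
#' one sample travel together and no sample appears in both the training
#' and test side of any fold.
#'
#' @param ss A `sample_set`.
#' @param k Number of folds; every class must have at least `k` samples.
#' @param seed Optional integer seed for the shuffle.
#' @return List of `k` folds, each `list(train = , test = )` of sample ids.
#' @export
grouped_stratified_split <- function(ss, k, seed = NULL) {
  labs <- sample_labels(ss)
  if (!is.null(seed)) set.seed(seed)
  fold_of <- integer(0)
  offset <- 0L  # rotate the starting fold per class so extras spread evenly
  for (cl in unique(labs)) {
    ids <- names(labs)[labs == cl]
    if (length(ids) < k)
      stop("class ", cl, " has ", length(ids), " samples; need >= ", k)
    ids <- sample(ids)
    fold_of[ids] <- ((offset + seq_along(ids) - 1L) %% k) + 1L
    offset <- (offset + length(ids)) %% k
  }
  lapply(seq_len(k), function(f)
    list(train = names(fold_of)[fold_of != f],
         test = names(fold_of)[fold_of == f]))
}

clip_prob <- function(p, eps = 1e-15) pmin(pmax(p, eps), 1 - eps)

#' Multiclass log loss
#'
#' Mean negative log probability assigned to the true class, with
#' probabilities clipped to `[eps, 1 - eps]`. The proper scoring rule used
#' for hyperparameter selection and reporting.
#'
#' @param probs Probability matrix with classes as named columns.
#' @param truth Character vector of true classes, one per row.
#' @param eps Clipping bound (default 1e-15).
#' @return Non-negative scalar.
#' @export
log_loss <- function(probs, truth, eps = 1e-15) {
  stopifnot(nrow(probs) == length(truth), all(truth %in% colnames(probs)))
  p <- probs[cbind(seq_along(truth), match(truth, colnames(probs)))]
  mean(-log(clip_prob(p, eps)))
}

# per-spectrum hard votes from a probability matrix
spectrum_votes <- function(probs, cfg) {
  cls <- colnames(probs)
  if (setequal(cls, c("MSS", "MSI_H"))) {
    ifelse(probs[, "MSS"] >= cfg$decision_threshold, "MSS", "MSI_H")
  } else {
    apply(probs, 1, function(p) {
      cands <- cls[p == max(p)]
      if (length(cands) > 1L)
        cands <- cands[order(match(cands, cfg$tie_break_order))][1]
      cands
    })
  }
}

#' Majority-vote consensus label for one sample
#'
#' Classifies each spectrum to its most probable class (two-class task:
#' threshold on the MSS probability), then returns the most frequent class
#' over the sample's spectra. Any tie — at the spectrum or the sample level
#' — resolves to the clinically worst class, i.e. the earliest entry of
#' `cfg$tie_break_order`.
#'
#' @param probs Probability matrix for one sample's spectra (classes as
#'   named columns, one row per spectrum).
#' @param cfg A [cv_config()].
#' @return A single class label.
#' @export
majority_vote <- function(probs, cfg = cv_config()) {
  if (is.null(dim(probs)) || nrow(probs) < 1L)
    stop("majority_vote needs at least one spectrum prediction")
  miss <- setdiff(colnames(probs), cfg$tie_break_order)
  if (length(miss))
    stop("tie_break_order lacks class(es): ", paste(miss, collapse = ", "))
  votes <- spectrum_votes(probs, cfg)
  tab <- table(factor(votes, levels = colnames(probs)))
  winners <- names(tab)[tab == max(tab)]
  winners[order(match(winners, cfg$tie_break_order))][1]
}

#' Select hyperparameters by inner grouped cross-validation
#'
#' Runs a sample-grouped, class-stratified inner CV on the (raw-stage)
#' training partition: each inner training split is augmented, preprocessed
#' and fitted for every grid point, and the point minimising the mean
#' spectrum-level log loss on the inner validation spectra wins. Ties break
#' deterministically by grid order. A grid point that fails to fit on every
#' inner fold is excluded with a warning; a singleton grid is returned
#' directly.
#'
#' @param train_raw Raw-stage training `sample_set`.
#' @param grid Non-empty list of [model_spec()]s.
#' @param aug_cfg An [augmentation_config()].
#' @param prep_cfg A [preprocess_config()].
#' @param cfg A [cv_config()] (supplies `inner_folds`).
#' @param seed Integer seed for the inner split, augmentation and fits.
#' @return The selected `model_spec`.
#' @export
select_hyperparameters <- function(train_raw, grid,
                                   aug_cfg = augmentation_config(),
                                   prep_cfg = preprocess_config(),
                                   cfg = cv_config(), seed = 1) {
  if (!length(grid)) stop("empty hyperparameter grid")
  if (length(grid) == 1L) return(grid[[1]])
  folds <- grouped_stratified_split(train_raw, cfg$inner_folds,
                                    derive_seed(seed, "inner-split"))
  losses <- matrix(NA_real_, length(grid), length(folds))
  for (f in seq_along(folds)) {
    tr <- subset_samples(train_raw, folds[[f]]$train)
    va <- subset_samples(train_raw, folds[[f]]$test)
    acfg <- aug_cfg
    acfg$seed <- derive_seed(seed, "inner-aug", f)
    tr_pp <- preprocess_set(augment_training_set(tr, acfg), prep_cfg)
    va_pp <- preprocess_set(va, prep_cfg)
    for (g in seq_along(grid)) {
      fitted <- tryCatch(
        fit_model(grid[[g]], tr_pp, seed = derive_seed(seed, "inner-fit", f, g)),
        error = function(e) NULL)
      if (is.null(fitted)) next
      losses[g, f] <- log_loss(predict_proba(fitted, va_pp),
                               va_pp$meta$class_label)
    }
  }
  ok <- rowSums(!is.na(losses)) > 0
  if (!any(ok)) stop("every grid point failed on every inner fold")
  if (!all(ok))
    warning("excluding grid point(s) that failed on every inner fold: ",
            paste(which(!ok), collapse = ", "))
  mean_loss <- rowMeans(losses, na.rm = TRUE)
  mean_loss[!ok] <- Inf
  grid[[which.min(mean_loss)]]
}

#' Repeated nested cross-validation with sample-grouped splits
#'
#' For every repeat (with its own derived seed) the samples are partitioned
#' into `outer_folds` grouped, stratified folds. Per outer fold:
#' hyperparameters are selected by [select_hyperparameters()] on the outer
#' training partition only, that partition is augmented and preprocessed,
#' the model is fitted, the held-out spectra are scored, and each held-out
#' sample receives the mean of its spectra's probability vectors plus a
#' [majority_vote()] label. Augmented spectra can never be scored as test
#' data (enforced via the stage marker).
#'
#' @param ss Raw-stage `sample_set`.
#' @param grid List of candidate [model_spec()]s (usually one family).
#' @param aug_cfg An [augmentation_config()].
#' @param prep_cfg A [preprocess_config()].
#' @param cfg A [cv_config()].
#' @return List of `outer_folds * repeats` fold results, each with the
#'   repeat/fold indices, the selected spec, the train/test sample ids, and
#'   per-sample truths, voted labels and mean probability vectors.
#' @export
nested_cv <- function(ss, grid, aug_cfg = augmentation_config(),
                      prep_cfg = preprocess_config(), cfg = cv_config()) {
  validate_sample_set(ss)
  if (any(ss$meta$stage == "augmented"))
    stop("nested_cv input must not contain augmented spectra")
  results <- vector("list", cfg$repeats * cfg$outer_folds)
  i <- 0L
  for (r in seq_len(cfg$repeats)) {
    folds <- grouped_stratified_split(ss, cfg$outer_folds,
                                      derive_seed(cfg$seed, "outer", r))
    for (f in seq_along(folds)) {
      i <- i + 1L
      results[[i]] <- tryCatch(
        run_outer_fold(ss, folds[[f]], grid, aug_cfg, prep_cfg, cfg, r, f),
        error = function(e)
          stop("repeat ", r, ", outer fold ", f, ": ", conditionMessage(e),
               call. = FALSE))
    }
  }
  results
}

run_outer_fold <- function(ss, fold, grid, aug_cfg, prep_cfg, cfg, r, f) {
  train_raw <- subset_samples(ss, fold$train)
  test_raw <- subset_samples(ss, fold$test)
  if (length(intersect(fold$train, fold$test)))
    stop("train/test sample overlap")
  if (any(test_raw$meta$stage == "augmented"))
    stop("augmented spectra in a test fold")
  sel <- select_hyperparameters(train_raw, grid, aug_cfg, prep_cfg, cfg,
                                derive_seed(cfg$seed, "select", r, f))
  acfg <- aug_cfg
  acfg$seed <- derive_seed(cfg$seed, "aug", r, f)
  train_pp <- preprocess_set(augment_training_set(train_raw, acfg), prep_cfg)
  test_pp <- preprocess_set(test_raw, prep_cfg)
  model <- fit_model(sel, train_pp, seed = derive_seed(cfg$seed, "fit", r, f))
  probs <- predict_proba(model, test_pp)
  sid <- test_pp$meta$sample_id
  ids <- unique(sid)
  sample_probs <- t(vapply(ids, function(id)
    colMeans(probs[sid == id, , drop = FALSE]),
    numeric(length(model$class_order))))
  colnames(sample_probs) <- model$class_order
  truth <- sample_labels(test_pp)[ids]
  voted <- vapply(ids, function(id)
    majority_vote(probs[sid == id, , drop = FALSE], cfg), character(1))
  structure(list(repeat_index = r, fold_index = f, spec = sel,
                 class_order = model$class_order,
                 train_samples = fold$train, test_samples = ids,
                 truth = truth, voted = voted, sample_probs = sample_probs),
            class = "fold_result")
}

#' Summarise nested-CV fold results
#'
#' Per fold: accuracy of the voted sample labels, sample-level log loss on
#' the mean probability vectors and — for the two-class MSS/MSI-H task —
#' sensitivity (true MSS detected), specificity (true MSI-H detected) and
#' AUROC over the sample-level MSS probabilities. The summary reports the
#' unweighted mean and standard deviation across folds (standard deviations
#' are descriptive; overlapping folds admit no confidence intervals) and a
#' pooled row-normalised confusion matrix in percent.
#'
#' @param folds List of fold results from [nested_cv()].
#' @param cfg A [cv_config()].
#' @return A `metrics_summary`: `per_fold` data frame, `summary` data frame
#'   (metric, mean, sd), `confusion` (percent, rows = truth) and
#'   `confusion_counts`.
#' @export
compute_metrics <- function(folds, cfg = cv_config()) {
  stopifnot(length(folds) >= 1)
  classes <- folds[[1]]$class_order
  binary <- setequal(classes, c("MSS", "MSI_H"))
  rows <- lapply(folds, function(fr) {
    out <- data.frame(repeat_index = fr$repeat_index,
                      fold_index = fr$fold_index,
                      accuracy = mean(fr$voted == fr$truth),
                      log_loss = log_loss(fr$sample_probs, fr$truth))
    if (binary) {
      out$sensitivity <- if (any(fr$truth == "MSS"))
        mean(fr$voted[fr$truth == "MSS"] == "MSS") else NA_real_
      out$specificity <- if (any(fr$truth == "MSI_H"))
        mean(fr$voted[fr$truth == "MSI_H"] == "MSI_H") else NA_real_
      if (length(unique(fr$truth)) < 2) {
        warning("fold with single-class truth: AUROC undefined, excluded")
        out$auroc <- NA_real_
      } else {
        out$auroc <- as.numeric(pROC::auc(
          response = factor(fr$truth, levels = c("MSI_H", "MSS")),
          predictor = fr$sample_probs[, "MSS"],
          direction = "<", quiet = TRUE))
      }
    }
    out
  })
  per_fold <- do.call(rbind, rows)
  metrics <- setdiff(names(per_fold), c("repeat_index", "fold_index"))
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_fold[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(per_fold[[m]], na.rm = TRUE),
                numeric(1)),
    row.names = NULL)
  truth_all <- unlist(lapply(folds, `[[`, "truth"))
  voted_all <- unlist(lapply(folds, `[[`, "voted"))
  counts <- table(truth = factor(truth_all, levels = classes),
                  voted = factor(voted_all, levels = classes))
  confusion <- 100 * prop.table(counts, margin = 1)
  structure(list(per_fold = per_fold, summary = summary,
                 confusion = confusion, confusion_counts = counts,
                 class_order = classes),
            class = "metrics_summary")
}

#' @export
print.metrics_summary <- function(x, ...) {
  cat(sprintf("<metrics_summary> %d folds, classes: %s\n",
              nrow(x$per_fold), paste(x$class_order, collapse = ", ")))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  cat("  confusion (% of truth):\n")
  print(round(x$confusion, 1))
  invisible(x)
}

#' Per-fold and mean ROC curves
#'
#' Builds the ROC staircase of each two-class fold over the sample-level
#' MSS probabilities, then averages vertically on a fixed
#' false-positive-rate grid; the band is +/- 1 standard deviation across
#' folds.
#'
#' @param folds List of two-class fold results.
#' @param cfg A [cv_config()].
#' @param fpr_grid False-positive-rate grid for vertical averaging.
#' @return List with `per_fold` (repeat, fold, fpr, tpr points) and `mean`
#'   (fpr, tpr_mean, tpr_sd) data frames.
#' @export
roc_curve <- function(folds, cfg = cv_config(), fpr_grid = seq(0, 1, 0.02)) {
  classes <- folds[[1]]$class_order
  if (!setequal(classes, c("MSS", "MSI_H")))
    stop("ROC curves are defined for the two-class MSS/MSI-H task")
  per_fold <- list()
  tpr_mat <- matrix(NA_real_, length(folds), length(fpr_grid))
  for (i in seq_along(folds)) {
    fr <- folds[[i]]
    if (length(unique(fr$truth)) < 2) {
      warning("fold with single-class truth: ROC undefined, excluded")
      next
    }
    pos <- fr$truth == "MSS"
    ord <- order(fr$sample_probs[, "MSS"], decreasing = TRUE)
    tp <- cumsum(pos[ord]) / sum(pos)
    fp <- cumsum(!pos[ord]) / sum(!pos)
    fpr <- c(0, fp); tpr <- c(0, tp)
    per_fold[[length(per_fold) + 1L]] <-
      data.frame(repeat_index = fr$repeat_index, fold_index = fr$fold_index,
                 fpr = fpr, tpr = tpr)
    # staircase value at each grid point: highest tpr reached at fpr <= g
    tpr_mat[i, ] <- vapply(fpr_grid,
                           function(g) max(tpr[fpr <= g + 1e-12]), numeric(1))
  }
  if (!length(per_fold)) stop("no fold with both classes present")
  list(per_fold = do.call(rbind, per_fold),
       mean = data.frame(fpr = fpr_grid,
                         tpr_mean = colMeans(tpr_mat, na.rm = TRUE),
                         tpr_sd = apply(tpr_mat, 2, stats::sd, na.rm = TRUE)))
}
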