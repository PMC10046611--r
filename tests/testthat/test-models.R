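fast_cnn <- function(...) model_spec("cnn_1d", epochs = 8, ...)

train_test_split <- function(ss, n_train_per_class = 4) {
  labs <- sample_labels(ss)
  train_ids <- unlist(lapply(split(names(labs), labs),
                             utils::head, n_train_per_class))
  list(train = subset_samples(ss, train_ids),
       test = subset_samples(ss, setdiff(names(labs), train_ids)))
}

make_separable_split <- function(seed = 41) {
  ss <- generate_study(small_design(seed = seed), separable_profiles())
  sp <- train_test_split(ss)
  list(train = preprocess_set(sp$train), test = preprocess_set(sp$test))
}

test_that("all families emit probability vectors on the simplex", {
  d <- make_separable_split()
  for (spec in list(model_spec("pca_lda", n_components = 5),
                    model_spec("svm_rbf"), fast_cnn())) {
    m <- fit_model(spec, d$train, seed = 2)
    p <- predict_proba(m, d$test)
    expect_equal(colnames(p), m$class_order)
    expect_true(all(p >= 0 & p <= 1))
    expect_true(all(abs(rowSums(p) - 1) < 1e-6))
    # permuting inputs permutes outputs identically
    perm <- rev(seq_len(n_spectra(d$test)))
    expect_equal(predict_proba(m, subset_spectra(d$test, perm)), p[perm, ])
    # empty input gives an empty prediction set
    expect_equal(nrow(predict_proba(m, d$test$intensities[0, , drop = FALSE])), 0)
  }
})

test_that("separable classes are fitted to >= 0.99 training accuracy", {
  d <- make_separable_split()
  truth <- d$train$meta$class_label
  for (spec in list(model_spec("pca_lda", n_components = 5),
                    model_spec("svm_rbf"), fast_cnn())) {
    m <- fit_model(spec, d$train, seed = 3)
    p <- predict_proba(m, d$train)
    pred <- colnames(p)[max.col(p)]
    expect_gte(mean(pred == truth), 0.99)
  }
  # binary model on its own separable training data: true-class
  # probability clears 0.5 for >= 99% of spectra
  two <- subset_spectra(d$train, d$train$meta$class_label != "NORMAL")
  for (spec in list(model_spec("pca_lda", n_components = 5),
                    model_spec("svm_rbf"), fast_cnn())) {
    m2 <- fit_model(spec, two, seed = 3)
    p2 <- predict_proba(m2, two)
    expect_equal(colnames(p2), c("MSS", "MSI_H"))
    i <- cbind(seq_len(nrow(p2)), match(two$meta$class_label, colnames(p2)))
    expect_gte(mean(p2[i] > 0.5), 0.99)
  }
})

test_that("without class signal, held-out probabilities track the priors", {
  ss <- generate_study(small_design(seed = 43, samples_per_class = 6,
                                    spectra_per_sample = 8),
                       flat_profiles(c("MSS", "MSI_H")))
  # unbalanced training: 4 MSS vs 2 MSI_H samples
  labs <- sample_labels(ss)
  train_ids <- c(head(names(labs)[labs == "MSS"], 4),
                 head(names(labs)[labs == "MSI_H"], 2))
  train <- preprocess_set(subset_samples(ss, train_ids))
  test <- preprocess_set(subset_samples(ss, setdiff(names(labs), train_ids)))
  m <- fit_model(model_spec("pca_lda", n_components = 3), train, seed = 5)
  p <- predict_proba(m, test)
  expect_lt(abs(mean(p[, "MSS"]) - 4 / 6), 0.15)
  for (spec in list(model_spec("svm_rbf"), fast_cnn())) {
    p <- predict_proba(fit_model(spec, train, seed = 5), test)
    expect_lt(abs(mean(p[, "MSS"]) - 4 / 6), 0.3)
  }
})

test_that("CNN refits are deterministic given the seed", {
  d <- make_separable_split(seed = 47)
  m1 <- fit_model(fast_cnn(), d$train, seed = 7)
  m2 <- fit_model(fast_cnn(), d$train, seed = 7)
  expect_identical(predict_proba(m1, d$test), predict_proba(m2, d$test))
  m3 <- fit_model(fast_cnn(), d$train, seed = 8)
  expect_false(identical(predict_proba(m3, d$test), predict_proba(m1, d$test)))
})

test_that("CNN gradients match finite differences", {
  set.seed(1)
  hp <- list(learning_rate = 1e-3, epochs = 1, batch_size = 4,
             channels = c(3, 4), kernel_sizes = c(5, 3), pool = 2, dropout = 0)
  X <- matrix(rnorm(6 * 40), 6, 40)
  y <- c(1L, 2L, 3L, 1L, 2L, 3L)
  params <- ramanmsi:::cnn_init(40, 3, hp)
  lg <- ramanmsi:::cnn_loss_grad(params, X, y, hp)
  eps <- 1e-6
  for (nm in names(params)) {
    for (j in sample(length(params[[nm]]), min(6, length(params[[nm]])))) {
      pp <- params; pp[[nm]][j] <- pp[[nm]][j] + eps
      pm <- params; pm[[nm]][j] <- pm[[nm]][j] - eps
      num <- (ramanmsi:::cnn_loss_grad(pp, X, y, hp)$loss -
              ramanmsi:::cnn_loss_grad(pm, X, y, hp)$loss) / (2 * eps)
      expect_lt(abs(num - lg$grads[[nm]][j]), 1e-6)
    }
  }
})

test_that("hyperparameter and input contracts are enforced", {
  d <- make_separable_split(seed = 53)
  expect_error(model_spec("pca_lda", cost = 2), "unknown hyperparameter")
  # rank-deficient request
  few <- subset_spectra(d$train, c(1:4, which(d$train$meta$class_label == "MSS")[1:4]))
  expect_error(fit_model(model_spec("pca_lda", n_components = 50), few),
               "feasible rank")
  # single-class training set
  mss_only <- subset_spectra(d$train, d$train$meta$class_label == "MSS")
  expect_error(fit_model(model_spec("pca_lda", n_components = 3), mss_only),
               ">= 2 classes")
  # raw spectra are refused, channel mismatches are caught
  raw <- generate_study(small_design(seed = 3, samples_per_class = 2,
                                     spectra_per_sample = 2), flat_profiles())
  expect_error(fit_model(model_spec("pca_lda"), raw), "raw-stage")
  m <- fit_model(model_spec("pca_lda", n_components = 5), d$train)
  expect_error(predict_proba(m, d$train$intensities[, 1:10]), "channels")
})

test_that("PCA-LDA agrees with an eigendecomposition oracle on a toy case", {
  set.seed(9)
  X <- matrix(rnorm(6 * 5), 6, 5) +
    matrix(rep(c(0, 0, 0, 2, 2, 2), 5), 6, 5)
  labels <- c("MSS", "MSS", "MSS", "MSI_H", "MSI_H", "MSI_H")
  ss <- sample_set(c(400, 500, 600, 700, 800), abs(X),
                   data.frame(spectrum_id = paste0("sp", 1:6),
                              sample_id = paste0("s", 1:6),
                              class_label = labels, stage = "raw"))
  pp <- snv_normalize(truncate_spectra(ss, preprocess_config(0, 1000)))
  m <- fit_model(model_spec("pca_lda", n_components = 2), pp, seed = 1)
  Xp <- pp$intensities

  # oracle PCA: eigenvectors of the sample covariance matrix
  ev <- eigen(stats::cov(Xp), symmetric = TRUE)
  Xc <- sweep(Xp, 2, colMeans(Xp))
  scores_oracle <- Xc %*% ev$vectors[, 1:2]
  scores_model <- sweep(Xp, 2, m$fit$center) %*% m$fit$rotation
  for (j in 1:2) {
    err <- min(max(abs(scores_model[, j] - scores_oracle[, j])),
               max(abs(scores_model[, j] + scores_oracle[, j])))
    expect_lt(err, 1e-6)
  }

  # oracle LDA direction on the scores: Sw^-1 (m1 - m2)
  grp <- split(seq_len(6), labels)
  Sw <- Reduce(`+`, lapply(grp, function(i) {
    Sc <- sweep(scores_oracle[i, ], 2, colMeans(scores_oracle[i, ]))
    crossprod(Sc)
  })) / (6 - 2)
  w_oracle <- solve(Sw, colMeans(scores_oracle[grp$MSS, ]) -
                        colMeans(scores_oracle[grp$MSI_H, ]))
  w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
  # model discriminant scores on its own components
  ld <- as.vector(scores_model %*% m$fit$lda$scaling)
  ld_oracle <- as.vector(scores_oracle %*% w_oracle)
  a <- scale(ld)[, 1]; b <- scale(ld_oracle)[, 1]
  expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-6)
})
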