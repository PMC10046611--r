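#' Specify a classifier
#'
#' One specification object covers the three model families behind the
#' common fit/predict-probability contract:
#' \describe{
#'   \item{`pca_lda`}{Principal-component projection of the training spectra
#'     followed by linear discriminant analysis. Hyperparameter:
#'     `n_components` (default 10).}
#'   \item{`svm_rbf`}{Support vector machine with a radial basis function
#'     kernel and calibrated probability outputs. Hyperparameters: `cost`
#'     (default 1) and `gamma` (default `NULL` = 1 / n_channels).}
#'   \item{`cnn_1d`}{A small one-dimensional convolutional network (stacked
#'     conv/ReLU/max-pool blocks, flattened into a dense softmax head so
#'     band positions stay informative) trained with Adam on the
#'     cross-entropy. Hyperparameters:
#'     `learning_rate`, `epochs`, `batch_size`, `channels`, `kernel_sizes`,
#'     `pool`, `dropout`.}
#' }
#'
#' @param family One of `"pca_lda"`, `"svm_rbf"`, `"cnn_1d"`.
#' @param ... Named hyperparameters overriding the family defaults.
#' @return A `model_spec` object.
#' @export
model_spec <- function(family = c("pca_lda", "svm_rbf", "cnn_1d"), ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    pca_lda = list(n_components = 10),
    svm_rbf = list(cost = 1, gamma = NULL),
    cnn_1d = cnn_defaults())
  hp <- list(...)
  bad <- setdiff(names(hp), names(defaults))
  if (length(bad))
    stop("unknown hyperparameter(s) for ", family, ": ",
         paste(bad, collapse = ", "))
  defaults[names(hp)] <- hp
  structure(list(family = family, hyperparameters = defaults),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  hp <- vapply(x$hyperparameters,
               function(v) paste(format(v), collapse = ","), character(1))
  cat(sprintf("<model_spec> %s (%s)\n", x$family,
              paste(names(hp), hp, sep = "=", collapse = ", ")))
  invisible(x)
}

model_matrix <- function(ss) {
  if (inherits(ss, "sample_set")) ss$intensities else as.matrix(ss)
}

#' Fit a classifier on a training sample_set
#'
#' @param spec A [model_spec()].
#' @param train A preprocessed `sample_set` (stage normalized or augmented;
#'   raw spectra are refused) with at least two classes present.
#' @param seed Integer seed controlling every stochastic element of the fit
#'   (CNN initialisation and batch order, SVM probability calibration), so a
#'   refit with the same seed reproduces identical predictions.
#' @return A `fitted_model` carrying the spec, the fitted state and the
#'   class order its probability columns refer to. For the two-class
#'   MSS/MSI-H task the first column is MSS, the orientation in which a
#'   probability of 1 means MSS and 0 means MSI-H.
#' @export
fit_model <- function(spec, train, seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  validate_sample_set(train)
  if (any(train$meta$stage == "raw"))
    stop("models are fitted on preprocessed spectra; found raw-stage input")
  labels <- train$meta$class_label
  class_order <- intersect(raman_classes(), unique(labels))
  if (length(class_order) < 2) stop("training set must contain >= 2 classes")
  # two-class MSS/MSI-H orientation: first column is MSS (probability 1 =
  # MSS, 0 = MSI-H)
  if (setequal(class_order, c("MSS", "MSI_H"))) class_order <- c("MSS", "MSI_H")
  X <- model_matrix(train)
  y <- factor(labels, levels = class_order)
  set.seed(seed)
  fit <- switch(spec$family,
    pca_lda = fit_pca_lda(X, y, spec$hyperparameters),
    svm_rbf = fit_svm_rbf(X, y, spec$hyperparameters),
    cnn_1d = cnn_fit(X, as.integer(y), length(class_order),
                     spec$hyperparameters, seed))
  structure(list(spec = spec, fit = fit, class_order = class_order,
                 n_channels = ncol(X)),
            class = "fitted_model")
}

fit_pca_lda <- function(X, y, hp) {
  nc <- hp$n_components
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  if (nc > ncol(pca$rotation))
    stop("n_components = ", nc, " exceeds feasible rank ", ncol(pca$rotation))
  scores <- pca$x[, seq_len(nc), drop = FALSE]
  lda <- MASS::lda(scores, grouping = y)
  list(center = pca$center, rotation = pca$rotation[, seq_len(nc), drop = FALSE],
       lda = lda)
}

fit_svm_rbf <- function(X, y, hp) {
  args <- list(x = X, y = y, kernel = "radial", cost = hp$cost,
               probability = TRUE)
  if (!is.null(hp$gamma)) args$gamma <- hp$gamma
  do.call(e1071::svm, args)
}

#' Predict class probabilities
#'
#' @param m A `fitted_model`.
#' @param newdata A `sample_set` or intensity matrix with the same channel
#'   count as the training spectra.
#' @return Matrix of probability vectors, one row per spectrum, columns
#'   named by the model's `class_order`; rows sum to 1.
#' @export
predict_proba <- function(m, newdata) {
  stopifnot(inherits(m, "fitted_model"))
  X <- model_matrix(newdata)
  k <- length(m$class_order)
  if (nrow(X) == 0)
    return(matrix(numeric(0), 0, k, dimnames = list(NULL, m$class_order)))
  if (ncol(X) != m$n_channels)
    stop("input has ", ncol(X), " channels; model was trained on ",
         m$n_channels)
  probs <- switch(m$spec$family,
    pca_lda = {
      scores <- sweep(X, 2, m$fit$center) %*% m$fit$rotation
      stats::predict(m$fit$lda, scores)$posterior
    },
    svm_rbf = {
      pr <- stats::predict(m$fit, X, probability = TRUE)
      attr(pr, "probabilities")
    },
    cnn_1d = {
      p <- cnn_predict(m$fit, X)
      colnames(p) <- m$class_order
      p
    })
  probs <- probs[, m$class_order, drop = FALSE]
  rownames(probs) <- NULL
  probs / rowSums(probs)
}
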