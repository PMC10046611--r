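#' Augmentation configuration
#'
#' @param factor Integer expansion factor (>= 1); the training set grows to
#'   `factor` times its size (1 original + `factor - 1` perturbed copies per
#'   spectrum). Default 8.
#' @param max_shift Bound on the random wavenumber shift in cm-1 (>= 0);
#'   shifts are drawn uniformly from `[-max_shift, +max_shift]`. Default 6.
#' @param poisson_rescale Expected-counts scale (> 0) used to convert
#'   intensities to a counts-like range before drawing shot noise: a channel
#'   with intensity `x` is replaced by `rpois(x * poisson_rescale) /
#'   poisson_rescale`, so the perturbation is unbiased with variance
#'   `x / poisson_rescale`. Default 1 — raw synthetic spectra are already
#'   photon counts.
#' @param seed Optional integer seed for the augmentation stream.
#' @return An `augmentation_config` object.
#' @export
augmentation_config <- function(factor = 8, max_shift = 6,
                                poisson_rescale = 1, seed = NULL) {
  if (factor < 1) stop("factor must be >= 1")
  if (max_shift < 0) stop("max_shift must be >= 0")
  if (poisson_rescale <= 0) stop("poisson_rescale must be > 0")
  structure(list(factor = as.integer(factor), max_shift = max_shift,
                 poisson_rescale = poisson_rescale, seed = seed),
            class = "augmentation_config")
}

#' Perturb spectra with Poisson shot noise
#'
#' Replaces each channel by a Poisson draw whose mean is the channel's
#' (rescaled) intensity, then rescales back, so the expectation equals the
#' input. Applied to raw (pre-normalization) intensities only, honouring the
#' physical origin of shot noise in photon counting.
#'
#' @param ss A `sample_set` at stage `"raw"`.
#' @param cfg An [augmentation_config()].
#' @return The perturbed `sample_set`, still raw-stage.
#' @export
poisson_perturb <- function(ss, cfg = augmentation_config()) {
  if (any(ss$meta$stage != "raw"))
    stop("Poisson perturbation applies to raw-stage spectra only")
  X <- ss$intensities
  if (any(X < 0)) stop("negative intensity encountered before Poisson noise")
  r <- cfg$poisson_rescale
  Y <- matrix(stats::rpois(length(X), as.vector(X) * r) / r,
              nrow(X), ncol(X))
  sample_set(ss$wavenumber, Y, ss$meta)
}

#' Shift spectra along the wavenumber axis
#'
#' Displaces the spectrum by `delta` cm-1 (positive `delta` moves features
#' to higher wavenumbers) and linearly interpolates back onto the original
#' axis; edge channels take the nearest-edge value. Emulates small
#' calibration drift between acquisitions.
#'
#' @param ss A `sample_set`.
#' @param delta Shift in cm-1; `|delta|` must not exceed `max_shift`.
#' @param max_shift Contract bound in cm-1 (default 6).
#' @return The shifted `sample_set`.
#' @export
wavenumber_shift <- function(ss, delta, max_shift = 6) {
  if (abs(delta) > max_shift)
    stop("|delta| = ", abs(delta), " exceeds max_shift = ", max_shift)
  if (delta == 0) return(ss)
  w <- ss$wavenumber
  X <- ss$intensities
  for (i in seq_len(nrow(X)))
    X[i, ] <- stats::approx(w + delta, X[i, ], xout = w, rule = 2)$y
  sample_set(w, X, ss$meta)
}

#' Expand a training set by Poisson noise + wavenumber shift
#'
#' Produces `factor` times the input: every original spectrum plus
#' `factor - 1` perturbed copies, each obtained by Poisson shot noise on the
#' raw intensities followed by a wavenumber shift drawn uniformly from
#' `[-max_shift, +max_shift]`. Copies inherit their source's sample and
#' class and are marked stage `"augmented"` so the validation layer can
#' refuse them in test folds. Intended strictly for training partitions
#' inside cross-validation folds.
#'
#' @param train A `sample_set` of raw-stage training spectra.
#' @param cfg An [augmentation_config()].
#' @return A `sample_set` of size `factor * n_spectra(train)`; the realised
#'   shift draws are attached as attribute `"aug_shifts"`.
#' @export
augment_training_set <- function(train, cfg = augmentation_config()) {
  if (n_spectra(train) == 0) stop("empty training set")
  if (any(train$meta$stage != "raw"))
    stop("augmentation requires raw-stage training spectra")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  out <- train
  if (cfg$factor == 1L) return(out)
  w <- train$wavenumber
  all_shifts <- numeric(0)
  for (k in seq_len(cfg$factor - 1L)) {
    copy <- poisson_perturb(train, cfg)
    X <- copy$intensities
    deltas <- stats::runif(nrow(X), -cfg$max_shift, cfg$max_shift)
    all_shifts <- c(all_shifts, deltas)
    for (i in seq_len(nrow(X)))
      X[i, ] <- stats::approx(w + deltas[i], X[i, ], xout = w, rule = 2)$y
    meta <- copy$meta
    meta$spectrum_id <- sprintf("%s_aug%d", meta$spectrum_id, k)
    meta$stage <- "augmented"
    out <- bind_spectra(out, sample_set(w, X, meta))
  }
  # the realised shift draws, for auditing the +/- max_shift contract
  attr(out, "aug_shifts") <- all_shifts
  out
}
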