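#' Preprocessing configuration
#'
#' @param truncate_low,truncate_high Closed truncation interval in cm-1;
#'   defaults 400 and 1800 retain the biological fingerprint region.
#' @param variance_floor Smallest admissible intensity variance for SNV;
#'   spectra at or below it are rejected as (numerically) constant.
#' @return A `preprocess_config` object.
#' @export
preprocess_config <- function(truncate_low = 400, truncate_high = 1800,
                              variance_floor = 1e-10) {
  if (truncate_low >= truncate_high) stop("truncate_low must be < truncate_high")
  if (variance_floor <= 0) stop("variance_floor must be > 0")
  structure(list(truncate_low = truncate_low, truncate_high = truncate_high,
                 variance_floor = variance_floor),
            class = "preprocess_config")
}

# population-convention SNV of one intensity vector
snv_vector <- function(x, variance_floor = 1e-10, id = "<spectrum>") {
  mu <- mean(x)
  v <- mean((x - mu)^2)
  if (v <= variance_floor)
    stop("cannot SNV-normalize spectrum ", id,
         ": intensity variance ", format(v), " at or below floor")
  (x - mu) / sqrt(v)
}

#' Standard normal variate (SNV) normalization
#'
#' Centres and scales every spectrum to zero mean and unit variance
#' (population convention, dividing by n), removing multiplicative
#' intensity effects such as focus and laser-power variation. Applied after
#' truncation so the statistics reflect only the modelled window.
#'
#' @param ss A `sample_set`.
#' @param cfg A [preprocess_config()] (only `variance_floor` is used).
#' @return The `sample_set` with every spectrum normalized and stages
#'   `"raw"` relabelled `"normalized"` (augmented copies keep their marker).
#' @export
snv_normalize <- function(ss, cfg = preprocess_config()) {
  validate_sample_set(ss)
  X <- ss$intensities
  for (i in seq_len(nrow(X)))
    X[i, ] <- snv_vector(X[i, ], cfg$variance_floor, ss$meta$spectrum_id[i])
  meta <- ss$meta
  meta$stage[meta$stage == "raw"] <- "normalized"
  sample_set(ss$wavenumber, X, meta)
}

#' Truncate spectra to a wavenumber window
#'
#' Retains exactly the channels whose wavenumber lies in the closed interval
#' `[truncate_low, truncate_high]`; a pure selection, no resampling.
#'
#' @param ss A `sample_set`.
#' @param cfg A [preprocess_config()].
#' @return The truncated `sample_set`.
#' @export
truncate_spectra <- function(ss, cfg = preprocess_config()) {
  keep <- ss$wavenumber >= cfg$truncate_low & ss$wavenumber <= cfg$truncate_high
  if (!any(keep))
    stop("truncation window [", cfg$truncate_low, ", ", cfg$truncate_high,
         "] contains no axis points")
  sample_set(ss$wavenumber[keep], ss$intensities[, keep, drop = FALSE], ss$meta)
}

#' Truncate then SNV-normalize a whole sample_set
#'
#' The fixed preprocessing applied before modelling: truncation to the
#' fingerprint window, then per-spectrum SNV. No baseline correction is
#' performed.
#'
#' @param ss A `sample_set`.
#' @param cfg A [preprocess_config()].
#' @return The preprocessed `sample_set`; sample structure and labels are
#'   unchanged.
#' @export
preprocess_set <- function(ss, cfg = preprocess_config()) {
  snv_normalize(truncate_spectra(ss, cfg), cfg)
}
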