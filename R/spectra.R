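#' Canonical class labels
#'
#' The three tissue classes handled by the pipeline, in canonical order:
#' normal colonic mucosa, microsatellite-stable adenocarcinoma (MSS) and
#' microsatellite-unstable adenocarcinoma (MSI-H).
#'
#' @return Character vector `c("NORMAL", "MSS", "MSI_H")`.
#' @export
raman_classes <- function() c("NORMAL", "MSS", "MSI_H")

#' Construct a collection of spectra grouped by sample
#'
#' A `sample_set` is the unit the whole pipeline operates on: a shared
#' wavenumber axis, an intensity matrix with one row per spectrum, and
#' per-spectrum metadata tying each spectrum to a sample and a class.
#' Samples — not spectra — are the unit of cross-validation splitting and of
#' final prediction.
#'
#' @param wavenumber Numeric vector of wavenumbers (cm-1), strictly
#'   increasing and uniformly spaced.
#' @param intensities Numeric matrix, `n_spectra x length(wavenumber)`.
#' @param meta Data frame with columns `spectrum_id`, `sample_id`,
#'   `class_label` and `stage` (one of `"raw"`, `"normalized"`,
#'   `"augmented"`), one row per row of `intensities`.
#' @return An object of class `sample_set`.
#' @export
sample_set <- function(wavenumber, intensities, meta) {
  if (!is.matrix(intensities)) intensities <- matrix(intensities, nrow = 1)
  ss <- structure(
    list(wavenumber = as.numeric(wavenumber),
         intensities = intensities,
         meta = as.data.frame(meta, stringsAsFactors = FALSE)),
    class = "sample_set")
  validate_sample_set(ss)
  ss
}

#' Validate a sample_set's structural invariants
#'
#' Checks axis monotonicity, dimensional agreement between axis, intensity
#' matrix and metadata, label consistency within each sample (one class per
#' `sample_id`), valid stage markers, and non-negativity of raw-stage
#' intensities.
#'
#' @param ss A `sample_set`.
#' @return `ss`, invisibly; errors otherwise.
#' @export
validate_sample_set <- function(ss) {
  stopifnot(inherits(ss, "sample_set"))
  w <- ss$wavenumber
  if (length(w) < 2L || any(diff(w) <= 0))
    stop("wavenumber axis must be strictly increasing")
  if (ncol(ss$intensities) != length(w))
    stop("intensity matrix has ", ncol(ss$intensities),
         " channels but axis has ", length(w))
  m <- ss$meta
  need <- c("spectrum_id", "sample_id", "class_label", "stage")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("meta lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(m) != nrow(ss$intensities))
    stop("meta has ", nrow(m), " rows for ", nrow(ss$intensities), " spectra")
  if (anyDuplicated(m$spectrum_id))
    stop("duplicate spectrum ids")
  bad_stage <- setdiff(unique(m$stage), c("raw", "normalized", "augmented"))
  if (length(bad_stage)) stop("unknown stage: ", paste(bad_stage, collapse = ", "))
  bad_cls <- setdiff(unique(m$class_label), raman_classes())
  if (length(bad_cls)) stop("unknown class label: ", paste(bad_cls, collapse = ", "))
  lab_per_sample <- tapply(m$class_label, m$sample_id,
                           function(x) length(unique(x)))
  if (any(lab_per_sample > 1L))
    stop("sample(s) with inconsistent class labels: ",
         paste(names(lab_per_sample)[lab_per_sample > 1L], collapse = ", "))
  raw <- m$stage == "raw"
  if (any(raw) && any(ss$intensities[raw, , drop = FALSE] < 0))
    stop("raw-stage intensities must be non-negative")
  invisible(ss)
}

#' @export
print.sample_set <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<sample_set> %d spectra / %d samples, %d channels (%g-%g cm-1)\n",
              nrow(m), length(unique(m$sample_id)), length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber)))
  tab <- table(sample_labels(x))
  cat("  samples per class:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  stages:", paste(unique(m$stage), collapse = ", "), "\n")
  invisible(x)
}

#' Number of spectra in a sample_set
#' @param ss A `sample_set`.
#' @return Integer count of spectra (rows).
#' @export
n_spectra <- function(ss) nrow(ss$intensities)

#' Per-sample class labels
#' @param ss A `sample_set`.
#' @return Named character vector mapping `sample_id` to class label.
#' @export
sample_labels <- function(ss) {
  m <- ss$meta[!duplicated(ss$meta$sample_id), ]
  stats::setNames(m$class_label, m$sample_id)
}

#' Subset a sample_set by spectrum index
#' @param ss A `sample_set`.
#' @param i Integer or logical index over spectra (rows).
#' @return A `sample_set` containing the selected spectra.
#' @export
subset_spectra <- function(ss, i) {
  sample_set(ss$wavenumber, ss$intensities[i, , drop = FALSE], ss$meta[i, ])
}

#' Subset a sample_set by sample identifiers
#' @param ss A `sample_set`.
#' @param ids Character vector of `sample_id`s to keep.
#' @return A `sample_set` containing all spectra of the selected samples.
#' @export
subset_samples <- function(ss, ids) {
  keep <- ss$meta$sample_id %in% ids
  if (!any(keep)) stop("no spectra for requested sample ids")
  subset_spectra(ss, keep)
}

#' Row-bind two sample_sets sharing an axis
#' @param a,b `sample_set`s with identical wavenumber axes.
#' @return The combined `sample_set`.
#' @export
bind_spectra <- function(a, b) {
  if (!isTRUE(all.equal(a$wavenumber, b$wavenumber)))
    stop("cannot bind sample_sets with different axes")
  sample_set(a$wavenumber, rbind(a$intensities, b$intensities),
             rbind(a$meta, b$meta))
}

# Deterministic substream seeds: a small polynomial hash of the base seed and
# a stream label, kept below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h + 1)
}
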