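#' Per-class mean spectrum with standard deviation
#'
#' @param ss A `sample_set` (normalized spectra expected for plotting
#'   comparability, but any stage is accepted).
#' @param label Class to average; must have at least 2 spectra.
#' @return A `mean_spectrum`: wavenumber axis, per-channel mean and SD,
#'   class label and spectrum count.
#' @export
class_mean <- function(ss, label) {
  label <- match.arg(label, raman_classes())
  keep <- ss$meta$class_label == label
  if (sum(keep) < 2) stop("need >= 2 spectra of class ", label)
  X <- ss$intensities[keep, , drop = FALSE]
  structure(list(wavenumber = ss$wavenumber,
                 mean = colMeans(X),
                 sd = apply(X, 2, stats::sd),
                 class_label = label,
                 n_spectra = nrow(X)),
            class = "mean_spectrum")
}

#' Channelwise difference of two class-mean spectra
#'
#' Conventionally computed as MSI-H minus MSS to expose the subtle
#' compositional differences between the two adenocarcinoma phenotypes.
#'
#' @param a,b `mean_spectrum`s on identical axes.
#' @return A `diff_spectrum` with the axis and `a$mean - b$mean`.
#' @export
difference_spectrum <- function(a, b) {
  if (!isTRUE(all.equal(a$wavenumber, b$wavenumber)))
    stop("mean spectra are on different axes")
  structure(list(wavenumber = a$wavenumber,
                 intensity = a$mean - b$mean,
                 label = paste0(a$class_label, " - ", b$class_label)),
            class = "diff_spectrum")
}

#' Reference Raman band assignments for colorectal tissue
#'
#' Literature assignments of the fingerprint-region bands used to interpret
#' difference spectra, plus the nucleic-acid- and collagen-associated
#' regions implicated in MSS vs MSI-H discrimination.
#'
#' @return Data frame with `wavenumber` (cm-1) and `assignment`.
#' @export
raman_assignments <- function() {
  data.frame(
    wavenumber = c(494, 529, 695, 714, 732, 787, 815, 852, 885,
                   1003, 1034, 1081, 1110, 1302, 1366, 1445, 1583, 1672),
    assignment = c(
      "glycogen, nucleic acids",
      "amino acids",
      "DNA ring breathing, C-S of methionine, C-N of phospholipids and adenine (680-710 region)",
      "lipids",
      "phosphatidylserine, adenine",
      "nucleic acids",
      "RNA ring breathing / O-P-O stretch, nucleic acid PO2-, collagen and proline C-C (800-830 region)",
      "ring-breathing mode of proline, hydroxyproline, tyrosine",
      "collagen C-C stretch, C-O-C skeletal mode of saccharides and adenine (870-900 region)",
      "phenylalanine, polysaccharides",
      "phenylalanine, polysaccharides",
      "lipids",
      "lipids, proteins",
      "lipids",
      "tryptophan, lipids, guanine",
      "lipids",
      "C-C bending mode of phenylalanine",
      "cholesterol"),
    stringsAsFactors = FALSE)
}

#' Annotate difference-spectrum peaks with band assignments
#'
#' Finds local extrema of the absolute difference intensity above a
#' prominence threshold and matches each to the nearest assignment-table
#' entry within a wavenumber tolerance; unmatched peaks are reported as
#' unassigned.
#'
#' @param diff A `diff_spectrum` from [difference_spectrum()].
#' @param table Assignment table (default [raman_assignments()]).
#' @param prominence_threshold Minimum `|intensity|` for a peak.
#' @param match_tolerance Maximum centre distance for a match, in cm-1
#'   (default 5).
#' @return Data frame of peaks: `wavenumber`, `intensity`, `assignment`
#'   (`NA` when unassigned), sorted by `|intensity|` descending.
#' @export
annotate_peaks <- function(diff, table = raman_assignments(),
                           prominence_threshold = 0,
                           match_tolerance = 5) {
  if (!nrow(table)) stop("empty assignment table")
  y <- abs(diff$intensity)
  n <- length(y)
  is_peak <- rep(FALSE, n)
  if (n >= 3) {
    core <- 2:(n - 1)
    is_peak[core] <- y[core] >= y[core - 1] & y[core] >= y[core + 1] &
      (y[core] > y[core - 1] | y[core] > y[core + 1])
  }
  is_peak <- is_peak & y > prominence_threshold
  idx <- which(is_peak)
  if (!length(idx))
    return(data.frame(wavenumber = numeric(0), intensity = numeric(0),
                      assignment = character(0)))
  w <- diff$wavenumber[idx]
  nearest <- vapply(w, function(wi) which.min(abs(table$wavenumber - wi)),
                    integer(1))
  dist <- abs(table$wavenumber[nearest] - w)
  out <- data.frame(
    wavenumber = w,
    intensity = diff$intensity[idx],
    assignment = ifelse(dist <= match_tolerance,
                        table$assignment[nearest], NA_character_),
    stringsAsFactors = FALSE)
  out[order(-abs(out$intensity)), , drop = FALSE]
}

#' Occlusion sensitivity map of a fitted model
#'
#' Sequentially blanks overlapping wavenumber windows of every input
#' spectrum, re-queries the model, and records the drop in the probability
#' of the spectrum's true class (whole-spectrum minus occluded). A positive
#' mean delta marks a window the model relies on.
#'
#' @param m A `fitted_model`.
#' @param ss Preprocessed `sample_set` whose spectra (and true class
#'   labels) are probed.
#' @param window_width Window width in cm-1 (default 30, comparable to a
#'   Raman band width).
#' @param stride Window step in cm-1 (default 10, overlapping windows).
#' @param fill Replacement value for occluded channels (default 0, the
#'   post-SNV mean and thus the least informative value), or `NULL` for no
#'   blanking (all deltas exactly zero; a self-check).
#' @return An `occlusion_map` data frame: `window_start`, `window_end`,
#'   `mean_delta`, `n`.
#' @export
occlusion_study <- function(m, ss, window_width = 30, stride = 10,
                            fill = 0) {
  w <- ss$wavenumber
  if (window_width > diff(range(w)))
    stop("occlusion window wider than the modelling range")
  X <- ss$intensities
  truth <- ss$meta$class_label
  if (!all(truth %in% m$class_order))
    stop("spectra carry classes the model does not know")
  tcol <- match(truth, m$class_order)
  base <- predict_proba(m, X)[cbind(seq_len(nrow(X)), tcol)]
  starts <- seq(min(w), max(w) - window_width, by = stride)
  if (max(starts) + window_width < max(w))
    starts <- c(starts, max(w) - window_width)
  out <- data.frame(window_start = starts,
                    window_end = starts + window_width,
                    mean_delta = NA_real_, n = nrow(X))
  for (i in seq_along(starts)) {
    inside <- w >= starts[i] & w <= starts[i] + window_width
    if (is.null(fill)) {
      occ <- X
    } else {
      occ <- X
      occ[, inside] <- fill
    }
    p <- predict_proba(m, occ)[cbind(seq_len(nrow(X)), tcol)]
    out$mean_delta[i] <- mean(base - p)
  }
  class(out) <- c("occlusion_map", "data.frame")
  out
}
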