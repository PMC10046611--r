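#' Define a Raman band
#'
#' @param center Band centre in cm-1.
#' @param amplitude Peak amplitude in arbitrary units (>= 0).
#' @param width Full width at half maximum in cm-1 (> 0).
#' @param shape `"lorentzian"` (the conventional lineshape for Raman
#'   transitions) or `"gaussian"`.
#' @return A `band` object.
#' @export
band <- function(center, amplitude, width, shape = c("lorentzian", "gaussian")) {
  shape <- match.arg(shape)
  if (width <= 0) stop("band width must be > 0")
  if (amplitude < 0) stop("band amplitude must be >= 0")
  structure(list(center = center, amplitude = amplitude,
                 width = width, shape = shape), class = "band")
}

band_values <- function(b, wavenumber) {
  if (b$shape == "lorentzian") {
    hw <- b$width / 2
    b$amplitude * hw^2 / ((wavenumber - b$center)^2 + hw^2)
  } else {
    b$amplitude * exp(-4 * log(2) * (wavenumber - b$center)^2 / b$width^2)
  }
}

#' Per-class generative recipe for synthetic tissue spectra
#'
#' A profile is the noiseless description of one tissue class: a set of
#' Raman bands on top of a smooth fluorescence baseline, plus the scale of
#' photon counting and of biological variation.
#'
#' @param class_label One of [raman_classes()].
#' @param bands List of [band()] objects.
#' @param baseline_coefficients Polynomial coefficients (intercept first) of
#'   the fluorescence background, evaluated in the scaled coordinate
#'   `wavenumber / 2100`.
#' @param mean_total_counts Expected total photon counts per spectrum
#'   (> 0). The clean band + baseline sum is rescaled so that its channel sum
#'   equals this value before Poisson sampling.
#' @param sample_sd Log-scale SD of the per-sample multiplicative amplitude
#'   factor (biological / sectioning variation between tissue samples); also
#'   jitters the baseline coefficients per sample.
#' @param spectrum_sd Log-scale SD of the per-spectrum multiplicative factor
#'   (focus and positioning variation between point acquisitions).
#' @return A `spectral_profile` object.
#' @export
spectral_profile <- function(class_label, bands, baseline_coefficients,
                             mean_total_counts = 5e5,
                             sample_sd = 0.05, spectrum_sd = 0.02) {
  class_label <- match.arg(class_label, raman_classes())
  if (mean_total_counts <= 0) stop("mean_total_counts must be > 0")
  if (sample_sd < 0 || spectrum_sd < 0) stop("variation SDs must be >= 0")
  structure(list(class_label = class_label, bands = bands,
                 baseline_coefficients = as.numeric(baseline_coefficients),
                 mean_total_counts = mean_total_counts,
                 sample_sd = sample_sd, spectrum_sd = spectrum_sd),
            class = "spectral_profile")
}

profile_baseline <- function(coef, wavenumber) {
  u <- wavenumber / 2100
  drop(outer(u, seq_along(coef) - 1, `^`) %*% coef)
}

#' Evaluate a profile's noiseless spectrum
#'
#' Sums the profile's bands and fluorescence baseline on a wavenumber axis,
#' without scaling to photon counts.
#'
#' @param profile A [spectral_profile()].
#' @param wavenumber Numeric axis in cm-1.
#' @return Numeric vector of clean intensities.
#' @export
profile_intensity <- function(profile, wavenumber) {
  y <- profile_baseline(profile$baseline_coefficients, wavenumber)
  for (b in profile$bands) y <- y + band_values(b, wavenumber)
  y
}

# Shared band skeleton: centre, FWHM, and per-class amplitudes. All classes
# share every band; only the designated differential bands (695, 787, 815,
# 885 cm-1, i.e. the 680-710 / 800-830 / 870-900 cm-1 regions plus the
# nucleic-acid line at 787 cm-1) carry class-dependent amplitudes. The
# NORMAL-vs-cancer offsets are deliberately larger than the MSS-vs-MSI-H
# offsets: separating the two adenocarcinoma phenotypes is the hard task.
default_band_table <- function() {
  tab <- read.table(header = TRUE, text = "
center width  normal   mss    msih
   494    14   0.30   0.30   0.30
   529    13   0.25   0.25   0.25
   695    16   0.5625 0.45   0.486
   714    14   0.35   0.35   0.35
   732    13   0.30   0.30   0.30
   787    12   0.48   0.60   0.648
   815    15   0.48   0.40   0.436
   852    13   0.40   0.40   0.40
   885    15   0.41   0.53   0.50
  1003     9   0.90   0.90   0.90
  1034    11   0.35   0.35   0.35
  1081    14   0.45   0.45   0.45
  1110    14   0.30   0.30   0.30
  1302    15   0.55   0.55   0.55
  1366    14   0.30   0.30   0.30
  1445    18   0.85   0.85   0.85
  1583    13   0.25   0.25   0.25
  1672    20   0.60   0.60   0.60
")
  tab
}

#' Default class profiles for the three-class colorectal design
#'
#' Returns one [spectral_profile()] per class. The three profiles share a
#' common skeleton of tissue Raman bands (phenylalanine at 1003 cm-1, CH2
#' deformation at 1445 cm-1, amide I at 1672 cm-1, ...) over a smooth
#' fluorescence baseline; they differ only in small amplitude offsets
#' concentrated at 680-710, 787, 800-830 and 870-900 cm-1 — the
#' nucleic-acid- and collagen-associated regions where MSS and MSI-H tissue
#' differ. NORMAL is offset from the cancers more strongly than the cancers
#' are from each other.
#'
#' @param differential_scale Multiplier (>= 0) applied to every
#'   class-differential amplitude offset; 1 reproduces the default subtle
#'   contrast, larger values make the classes easier to separate, 0 makes
#'   all classes identical.
#' @inheritParams spectral_profile
#' @return Named list of three `spectral_profile`s (`NORMAL`, `MSS`,
#'   `MSI_H`).
#' @export
default_profiles <- function(differential_scale = 1,
                             mean_total_counts = 5e5,
                             sample_sd = 0.05, spectrum_sd = 0.02) {
  if (differential_scale < 0) stop("differential_scale must be >= 0")
  tab <- default_band_table()
  base <- c(2.5, 3.0, -4.0, 1.2)
  mk <- function(label, col) {
    amp <- tab$mss + differential_scale * (tab[[col]] - tab$mss)
    bands <- mapply(function(c0, a, w) band(c0, a, w),
                    tab$center, amp, tab$width, SIMPLIFY = FALSE)
    spectral_profile(label, bands, base,
                     mean_total_counts = mean_total_counts,
                     sample_sd = sample_sd, spectrum_sd = spectrum_sd)
  }
  list(NORMAL = mk("NORMAL", "normal"),
       MSS = mk("MSS", "mss"),
       MSI_H = mk("MSI_H", "msih"))
}

#' Wavenumber regions where the default class profiles differ
#'
#' @return Data frame of `low`/`high` bounds (cm-1) of the differential
#'   bands planted by [default_profiles()].
#' @export
differential_regions <- function() {
  data.frame(low = c(680, 779, 800, 870),
             high = c(710, 795, 830, 900))
}

#' Describe a synthetic study design
#'
#' Mirrors the acquisition design the pipeline assumes: a fixed number of
#' tissue samples per class, a fixed number of point spectra per sample with
#' one designated short sample, and a uniform wavenumber axis.
#'
#' @param samples_per_class Samples per class (> 0); default 10.
#' @param spectra_per_sample Spectra per sample (> 0); default 50.
#' @param short_sample_spectra Spectrum count for the one designated short
#'   sample (the last sample generated); default 40. Must not exceed
#'   `spectra_per_sample`.
#' @param axis_min,axis_max,axis_step Wavenumber axis specification in cm-1;
#'   default 0-2100 cm-1 at 1 cm-1 spacing (2101 channels).
#' @param seed Integer seed making the whole study reproducible.
#' @return A `study_design` object.
#' @export
study_design <- function(samples_per_class = 10, spectra_per_sample = 50,
                         short_sample_spectra = 40,
                         axis_min = 0, axis_max = 2100, axis_step = 1,
                         seed = 1) {
  if (samples_per_class < 1 || spectra_per_sample < 1 || short_sample_spectra < 1)
    stop("all counts must be > 0")
  if (short_sample_spectra > spectra_per_sample)
    stop("short_sample_spectra must be <= spectra_per_sample")
  if (axis_min >= axis_max || axis_step <= 0) stop("invalid axis specification")
  structure(list(samples_per_class = samples_per_class,
                 spectra_per_sample = spectra_per_sample,
                 short_sample_spectra = short_sample_spectra,
                 wavenumber = seq(axis_min, axis_max, by = axis_step),
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Generate the spectra of one tissue sample
#'
#' Draws one multiplicative per-sample amplitude factor (and a per-sample
#' jitter of the baseline coefficients), then for each spectrum sums the
#' profile's bands and baseline, rescales to the profile's expected total
#' counts, applies a per-spectrum multiplicative factor, and draws
#' Poisson-distributed photon counts per channel.
#'
#' @param profile A [spectral_profile()].
#' @param n_spectra Number of spectra to generate (> 0).
#' @param sample_id Identifier shared by all generated spectra.
#' @param wavenumber Axis in cm-1.
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used (so [generate_study()] controls one stream for the whole study).
#' @return A `sample_set` of `n_spectra` raw-stage spectra.
#' @export
generate_sample <- function(profile, n_spectra, sample_id, wavenumber,
                            seed = NULL) {
  if (n_spectra < 1) stop("n_spectra must be > 0")
  if (!is.null(seed)) set.seed(seed)
  L <- length(wavenumber)
  coef <- profile$baseline_coefficients
  if (profile$sample_sd > 0)
    coef <- coef * stats::rlnorm(length(coef), 0, profile$sample_sd)
  clean <- profile_baseline(coef, wavenumber)
  for (b in profile$bands) clean <- clean + band_values(b, wavenumber)
  if (any(clean <= 0))
    stop("non-positive expected intensity in profile for sample ", sample_id)
  clean <- clean * (profile$mean_total_counts / sum(clean))
  sf <- if (profile$sample_sd > 0)
    stats::rlnorm(1, -profile$sample_sd^2 / 2, profile$sample_sd) else 1
  pf <- if (profile$spectrum_sd > 0)
    stats::rlnorm(n_spectra, -profile$spectrum_sd^2 / 2, profile$spectrum_sd)
  else rep(1, n_spectra)
  counts <- matrix(0, n_spectra, L)
  for (i in seq_len(n_spectra))
    counts[i, ] <- stats::rpois(L, clean * sf * pf[i])
  meta <- data.frame(
    spectrum_id = sprintf("%s_sp%03d", sample_id, seq_len(n_spectra)),
    sample_id = sample_id,
    class_label = profile$class_label,
    stage = "raw",
    stringsAsFactors = FALSE)
  sample_set(wavenumber, counts, meta)
}

#' Generate a full multi-sample synthetic study
#'
#' Realises a [study_design()] with one [spectral_profile()] per class:
#' `samples_per_class` samples for each class in `profiles`, each with
#' `spectra_per_sample` spectra except the last sample generated, which
#' receives `short_sample_spectra`. With the default design this yields 30
#' samples and 1490 spectra (10 per class, 50 spectra each, one sample with
#' 40).
#'
#' @param design A [study_design()].
#' @param profiles Named list of profiles, one per class (default
#'   [default_profiles()]).
#' @return A `sample_set` at stage `"raw"`.
#' @export
generate_study <- function(design, profiles = default_profiles()) {
  stopifnot(inherits(design, "study_design"))
  bad <- setdiff(names(profiles), raman_classes())
  if (length(bad)) stop("profiles for unknown classes: ", paste(bad, collapse = ", "))
  if (!length(profiles)) stop("no profiles supplied")
  classes <- intersect(raman_classes(), names(profiles))
  set.seed(design$seed)
  out <- NULL
  n_samples <- length(classes) * design$samples_per_class
  idx <- 0
  for (cl in classes) {
    for (i in seq_len(design$samples_per_class)) {
      idx <- idx + 1
      n <- if (idx == n_samples) design$short_sample_spectra
           else design$spectra_per_sample
      smp <- generate_sample(profiles[[cl]], n,
                             sprintf("%s_%02d", cl, i), design$wavenumber)
      out <- if (is.null(out)) smp else bind_spectra(out, smp)
    }
  }
  out
}
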