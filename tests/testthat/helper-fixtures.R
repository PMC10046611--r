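# Fixtures shared across the suite. All synthetic, built in code.

# Strongly separable three-class profiles: each class carries one strong
# private band on top of a shared skeleton, so any competent classifier
# should recover the labels almost perfectly.
separable_profiles <- function(sample_sd = 0.03, spectrum_sd = 0.02,
                               amp = 1.2) {
  shared <- list(band(1003, 0.9, 10), band(1445, 0.8, 18), band(1672, 0.6, 20))
  base <- c(2.5, 3.0, -4.0, 1.2)
  mk <- function(label, private) {
    spectral_profile(label, c(shared, list(private)), base,
                     sample_sd = sample_sd, spectrum_sd = spectrum_sd)
  }
  list(NORMAL = mk("NORMAL", band(600, amp, 16)),
       MSS = mk("MSS", band(815, amp, 16)),
       MSI_H = mk("MSI_H", band(1100, amp, 16)))
}

# Two classes identical except for one differential band at 815 cm-1
# (inside the 800-830 cm-1 region) — used for occlusion localisation.
one_band_profiles <- function(amp_gap = 0.8, sample_sd = 0.03,
                              spectrum_sd = 0.02) {
  shared <- list(band(1003, 0.9, 10), band(1445, 0.8, 18), band(1672, 0.6, 20))
  base <- c(2.5, 3.0, -4.0, 1.2)
  list(MSS = spectral_profile("MSS",
         c(shared, list(band(815, 0.3, 16))), base,
         sample_sd = sample_sd, spectrum_sd = spectrum_sd),
       MSI_H = spectral_profile("MSI_H",
         c(shared, list(band(815, 0.3 + amp_gap, 16))), base,
         sample_sd = sample_sd, spectrum_sd = spectrum_sd))
}

# Classes with no differential signal at all.
flat_profiles <- function(classes = c("MSS", "MSI_H"), sample_sd = 0.03,
                          spectrum_sd = 0.02) {
  shared <- list(band(1003, 0.9, 10), band(1445, 0.8, 18))
  base <- c(2.5, 3.0, -4.0, 1.2)
  out <- lapply(classes, function(cl)
    spectral_profile(cl, shared, base,
                     sample_sd = sample_sd, spectrum_sd = spectrum_sd))
  names(out) <- classes
  out
}

# Reduced study design: full 0-2100 cm-1 range at coarser spacing, fewer
# samples and spectra, so model fits stay fast.
small_design <- function(seed, samples_per_class = 6, spectra_per_sample = 6,
                         axis_step = 4) {
  study_design(samples_per_class = samples_per_class,
               spectra_per_sample = spectra_per_sample,
               short_sample_spectra = spectra_per_sample,
               axis_step = axis_step, seed = seed)
}

# A tiny hand-built sample_set (2 samples x 2 spectra, 6 channels).
tiny_set <- function() {
  w <- c(400, 500, 600, 700, 800, 900)
  X <- rbind(c(1, 2, 3, 4, 5, 6),
             c(2, 3, 4, 5, 6, 7),
             c(6, 5, 4, 3, 2, 1),
             c(7, 6, 5, 4, 3, 2))
  meta <- data.frame(
    spectrum_id = paste0("sp", 1:4),
    sample_id = c("a", "a", "b", "b"),
    class_label = c("MSS", "MSS", "MSI_H", "MSI_H"),
    stage = "raw", stringsAsFactors = FALSE)
  sample_set(w, X, meta)
}

# Build a fold_result by hand (compute_metrics / roc_curve only read fields).
make_fold_result <- function(truth, probs, voted, r = 1, f = 1,
                             classes = colnames(probs)) {
  ids <- sprintf("s%02d", seq_along(truth))
  rownames(probs) <- ids
  structure(list(repeat_index = r, fold_index = f,
                 spec = model_spec("pca_lda"),
                 class_order = classes,
                 train_samples = character(0), test_samples = ids,
                 truth = stats::setNames(truth, ids),
                 voted = stats::setNames(voted, ids),
                 sample_probs = probs),
            class = "fold_result")
}
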