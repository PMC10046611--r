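#!/usr/bin/env Rscript
# Class-mean spectra, the MSI-H minus MSS difference spectrum, and Raman
# band assignment of its extrema. Reads the simulated study written by
# 01_simulate.R (regenerates it if absent).

library(ramanmsi)

ss <- if (file.exists("scratch/data/spectra.csv")) {
  read_spectra("scratch/data")
} else {
  generate_study(study_design(seed = 20260925), default_profiles())
}

pp <- preprocess_set(ss)  # truncate to 400-1800 cm-1, then SNV

means <- lapply(c("NORMAL", "MSS", "MSI_H"), function(cl) class_mean(pp, cl))
names(means) <- c("NORMAL", "MSS", "MSI_H")
for (cl in names(means))
  cat(sprintf("%-7s mean spectrum over %4d spectra, mean channel SD %.3f\n",
              cl, means[[cl]]$n_spectra, mean(means[[cl]]$sd)))

diff <- difference_spectrum(means$MSI_H, means$MSS)
peaks <- annotate_peaks(diff, prominence_threshold = 0.5 * max(abs(diff$intensity)))
cat("\nTop difference-spectrum peaks (MSI-H minus MSS):\n")
print(head(peaks, 10), row.names = FALSE)

dir.create("results", showWarnings = FALSE)
write.csv(data.frame(wavenumber = diff$wavenumber, delta = diff$intensity),
          "results/02_difference_spectrum.csv", row.names = FALSE)
write.csv(peaks, "results/02_difference_peaks.csv", row.names = FALSE)
cat("\nwrote results/02_difference_spectrum.csv and results/02_difference_peaks.csv\n")
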