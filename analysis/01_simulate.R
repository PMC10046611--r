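#!/usr/bin/env Rscript
# Simulate the full synthetic study: 3 classes (normal / MSS / MSI-H) x 10
# samples x 50 point spectra (one sample with 40; 1490 spectra in total) on
# a 0-2100 cm-1 axis. The spectra land in scratch/ (they are bulky); the
# design summary lands in results/.

library(ramanmsi)

seed <- 20260925
design <- study_design(seed = seed)
ss <- generate_study(design, default_profiles())

cat("Simulated study:\n")
print(ss)

dir.create("scratch/data", recursive = TRUE, showWarnings = FALSE)
write_spectra(ss, "scratch/data")
cat("wrote scratch/data/spectra.csv + spectra.json\n")

dir.create("results", showWarnings = FALSE)
per_sample <- as.data.frame(table(sample_id = ss$meta$sample_id))
per_sample$class <- sample_labels(ss)[as.character(per_sample$sample_id)]
names(per_sample)[2] <- "n_spectra"
write.csv(per_sample[, c("sample_id", "class", "n_spectra")],
          "results/01_design_summary.csv", row.names = FALSE)
cat("wrote results/01_design_summary.csv:",
    nrow(per_sample), "samples,", sum(per_sample$n_spectra), "spectra\n")
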