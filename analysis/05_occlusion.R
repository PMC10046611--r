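#!/usr/bin/env Rscript
# Occlusion interpretability: refit the CNN on the full (augmented,
# preprocessed) two-class dataset, blank 30 cm-1 windows at 10 cm-1 stride,
# and rank windows by the drop in true-class probability. Windows with a
# large positive delta are the spectral regions the model relies on.

library(ramanmsi)

seed <- 20260925
ss <- generate_study(study_design(spectra_per_sample = 6,
                                  short_sample_spectra = 5,
                                  axis_step = 4, seed = seed),
                     default_profiles())
labs <- sample_labels(ss)
two <- subset_samples(ss, names(labs)[labs != "NORMAL"])

aug <- augmentation_config(factor = 8, seed = seed + 1)
train <- preprocess_set(augment_training_set(two, aug))
model <- fit_model(model_spec("cnn_1d", epochs = 20), train, seed = seed + 2)

probe <- preprocess_set(two)
occ <- occlusion_study(model, probe, window_width = 30, stride = 10)

top <- occ[order(-occ$mean_delta), ][1:10, ]
cat("Top 10 occlusion windows by mean true-class probability drop:\n")
print(top, row.names = FALSE)

dir.create("results", showWarnings = FALSE)
write.csv(occ, "results/05_occlusion_cnn.csv", row.names = FALSE)
cat("\nwrote results/05_occlusion_cnn.csv\n")
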