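#!/usr/bin/env Rscript
# Stage 1: simulate the labelled hyperspectral dataset.
#
# The generator emulates the four-class nitrogen trial (D0 = day before
# excess nitrogen, D1-D3 the days after): a common leaf-like base curve,
# class-specific absorption features at 723/781/901 nm, per-spectrum
# multiplicative scatter, and white noise. Writes the wide CSV the later
# stages consume.

library(nitrospec)

dir.create("results", showWarnings = FALSE)
cfg <- generator_config()  # n = 100 per class, seed 1
dataset <- generate_dataset(cfg)
write_dataset(dataset, "results/dataset.csv")

means <- class_mean_spectra(cfg)
utils::write.csv(
  data.frame(wavelength_nm = generator_grid(cfg), t(means)),
  "results/class_mean_spectra.csv", row.names = FALSE)

message(sprintf("simulated %d samples x %d wavelengths -> results/dataset.csv",
                n_samples(dataset), length(dataset$wavelengths)))
message("class means of the closed-form model -> results/class_mean_spectra.csv")
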