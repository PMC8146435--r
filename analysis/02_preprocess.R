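#!/usr/bin/env Rscript
# Stage 2: preprocessing - absorbance conversion (log10(1/R)),
# multiplicative scatter correction against the mean spectrum, and a
# width-5 running median. The MSC reference is persisted so new data can
# be corrected with frozen training statistics.

library(nitrospec)

dataset <- read_dataset("results/dataset.csv")
pre <- preprocess_dataset(dataset, window = 5L)
write_dataset(pre, "results/preprocessed.csv")

msc <- attr(pre, "msc_model")
utils::write.csv(
  data.frame(wavelength_nm = msc$wavelengths,
             reference_absorbance = msc$reference),
  "results/msc_reference.csv", row.names = FALSE)

message("preprocessed spectra -> results/preprocessed.csv")
message("MSC reference spectrum -> results/msc_reference.csv")
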