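# Small fixtures shared across test files; everything is generated in code.

# compact generator config: fewer samples, default band structure
small_config <- function(n = 30L, seed = 42L, ...) {
  generator_config(n_per_class = n, seed = seed, ...)
}

# tiny labelled dataset with hand-set spectra on a short grid
toy_dataset <- function() {
  wl <- c(500, 510, 520, 530)
  x <- rbind(c(0.2, 0.3, 0.4, 0.5),
             c(0.25, 0.35, 0.45, 0.55),
             c(0.5, 0.5, 0.5, 0.5))
  spectral_dataset(wl, x, c("D0", "D1", "D0"))
}

# well-separated 2-D Gaussian blobs, two classes
gaussian_blobs <- function(n = 40L, sd = 0.1, gap = 3, seed = 1L) {
  set.seed(seed)
  x <- rbind(cbind(rnorm(n, 0, sd), rnorm(n, 0, sd)),
             cbind(rnorm(n, gap, sd), rnorm(n, gap, sd)))
  list(x = x, y = factor(rep(c("a", "b"), each = n)))
}

# the printed pooled confusion matrices of the emulated trial
published <- reference_confusions()
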