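#' Configuration for the synthetic leaf-spectra generator
#'
#' The generator emulates a four-class nitrogen-treatment trial: class D0 is
#' the day before excess nitrogen is applied and D1-D3 the three days after.
#' Class mean spectra share a smooth leaf-like base curve and differ only in
#' the depth of absorption features planted at the informative bands; on top
#' of the class mean, every sample receives a multiplicative gain, an
#' additive offset (light-scatter effects that multiplicative scatter
#' correction is meant to remove) and white noise.
#'
#' The D3 mean is a convex combination of the D1 and D0 means with weight
#' `d1_d3_overlap` - newly grown leaves sampled on the last day partially
#' revert toward the untreated spectrum - plus, optionally, a small own
#' absorption feature per band (`d3_extra`), the spectral signature of the
#' new growth itself. The defaults give each band one exclusive role: the
#' 723 nm feature deepens only under the severe response (D2), 781 nm marks
#' any treatment (D1-D3), and 901 nm carries the weak new-growth feature
#' that is the only separation between D1 and D3. D1/D3 is therefore the
#' dominant confusion - the off-diagonal structure the workflow's
#' evaluation stage expects - and no informative band can substitute for
#' another.
#'
#' @param n_per_class Samples generated per class.
#' @param wavelength_start,wavelength_stop,wavelength_step Wavelength grid in
#'   nm (default 400-1100 nm in 2 nm steps, the camera range the workflow
#'   targets).
#' @param class_names Ordered class labels.
#' @param informative_bands List of bands; each band is a list with `center`
#'   (nm), `width` (Gaussian sd, nm), `depths` (per-class absorption depth
#'   offsets in reflectance units for classes D0, D1 and D2; D3's share of
#'   these is derived via `d1_d3_overlap`) and optionally `d3_extra`, an
#'   additional D3-only depth (default 0).
#' @param scatter_gain_sd SD of the per-spectrum multiplicative gain
#'   (mean 1, dimensionless).
#' @param scatter_offset_sd SD of the per-spectrum additive offset
#'   (reflectance units).
#' @param noise_sd SD of per-wavelength white noise (reflectance units).
#' @param d1_d3_overlap Weight in \[0, 1\] placed on the D1 mean when forming
#'   the D3 mean; values near 1 make D3 nearly indistinguishable from D1.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_per_class = 100L,
                             wavelength_start = 400,
                             wavelength_stop = 1100,
                             wavelength_step = 2,
                             class_names = c("D0", "D1", "D2", "D3"),
                             informative_bands = list(
                               list(center = 723, width = 4,
                                    depths = c(D0 = 0, D1 = 0, D2 = 0.050),
                                    d3_extra = 0),
                               list(center = 781, width = 4,
                                    depths = c(D0 = 0, D1 = 0.050, D2 = 0.050),
                                    d3_extra = 0.0125),
                               list(center = 901, width = 5,
                                    depths = c(D0 = 0, D1 = 0, D2 = 0),
                                    d3_extra = 0.016)
                             ),
                             scatter_gain_sd = 0.08,
                             scatter_offset_sd = 0.015,
                             noise_sd = 0.010,
                             d1_d3_overlap = 0.75,
                             seed = 1L) {
  if (n_per_class < 0) stop("n_per_class must be >= 0", call. = FALSE)
  if (wavelength_step <= 0) stop("wavelength_step must be > 0", call. = FALSE)
  if (wavelength_start < 400 || wavelength_stop > 1100 ||
      wavelength_start >= wavelength_stop)
    stop("wavelength grid must be strictly increasing and within [400, 1100] nm",
         call. = FALSE)
  if (scatter_gain_sd < 0 || scatter_offset_sd < 0 || noise_sd < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  if (d1_d3_overlap < 0 || d1_d3_overlap > 1)
    stop("d1_d3_overlap must be in [0, 1]", call. = FALSE)
  if (length(class_names) != 4L)
    stop("exactly four ordered classes are expected", call. = FALSE)
  for (b in informative_bands) {
    if (b$center < wavelength_start || b$center > wavelength_stop)
      stop("informative band center ", b$center,
           " nm lies outside the wavelength grid", call. = FALSE)
    if (b$width <= 0) stop("band width must be > 0", call. = FALSE)
    if (!is.null(b$d3_extra) && b$d3_extra < 0)
      stop("d3_extra must be >= 0", call. = FALSE)
  }
  structure(
    list(n_per_class = as.integer(n_per_class),
         wavelength_start = wavelength_start,
         wavelength_stop = wavelength_stop,
         wavelength_step = wavelength_step,
         class_names = class_names,
         informative_bands = informative_bands,
         scatter_gain_sd = scatter_gain_sd,
         scatter_offset_sd = scatter_offset_sd,
         noise_sd = noise_sd,
         d1_d3_overlap = d1_d3_overlap,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Smooth leaf-like base reflectance curve
#'
#' Fixed sum of a logistic red-edge rise (low reflectance below 700 nm, NIR
#' plateau above), a green-peak Gaussian near 550 nm and a shallow
#' NIR water-absorption dip near 970 nm.
#'
#' @param wavelengths Numeric vector of wavelengths (nm).
#' @return Reflectance values in (0, 1).
#' @export
base_leaf_spectrum <- function(wavelengths) {
  0.06 + 0.42 / (1 + exp(-(wavelengths - 715) / 16)) +
    0.06 * exp(-(wavelengths - 550)^2 / (2 * 25^2)) -
    0.05 * exp(-(wavelengths - 970)^2 / (2 * 35^2))
}

#' Closed-form class mean spectra of the generator
#'
#' The documented spectrum model: class mean = base curve minus, for each
#' informative band, a Gaussian absorption feature of the configured
#' per-class depth; the D3 mean is
#' `overlap * mean(D1) + (1 - overlap) * mean(D0)` minus each band's
#' `d3_extra` feature. Exported so tests can verify the generator against
#' an independent evaluation of the model.
#'
#' @param config A [generator_config()].
#' @return Matrix with one row per class (named), one column per wavelength.
#' @export
class_mean_spectra <- function(config) {
  wl <- generator_grid(config)
  cls <- config$class_names
  m <- matrix(NA_real_, 4L, length(wl), dimnames = list(cls, NULL))
  for (k in 1:3) {
    mk <- base_leaf_spectrum(wl)
    for (b in config$informative_bands)
      mk <- mk - b$depths[[k]] * exp(-(wl - b$center)^2 / (2 * b$width^2))
    m[k, ] <- mk
  }
  m[4L, ] <- config$d1_d3_overlap * m[2L, ] +
    (1 - config$d1_d3_overlap) * m[1L, ]
  for (b in config$informative_bands) {
    extra <- if (is.null(b$d3_extra)) 0 else b$d3_extra
    m[4L, ] <- m[4L, ] - extra * exp(-(wl - b$center)^2 / (2 * b$width^2))
  }
  m
}

#' Wavelength grid of a generator configuration
#' @param config A [generator_config()].
#' @return Numeric vector of wavelengths in nm.
#' @export
generator_grid <- function(config) {
  seq(config$wavelength_start, config$wavelength_stop,
      by = config$wavelength_step)
}

#' Generate a labelled synthetic hyperspectral dataset
#'
#' Each sample is `class_mean * gain + offset + noise`, clipped into
#' (0, 1], with `gain ~ N(1, scatter_gain_sd)`,
#' `offset ~ N(0, scatter_offset_sd)` and iid `N(0, noise_sd)` noise per
#' wavelength. Deterministic given `config` (including its seed).
#'
#' @param config A [generator_config()].
#' @return A [spectral_dataset()] with `n_per_class * 4` rows in class-block
#'   order.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  wl <- generator_grid(config)
  nw <- length(wl)
  means <- class_mean_spectra(config)
  n <- config$n_per_class
  total <- n * 4L
  x <- matrix(NA_real_, total, nw)
  labels <- factor(rep(config$class_names, each = n),
                   levels = config$class_names)
  if (total > 0L) {
    set.seed(config$seed)
    for (i in seq_len(total)) {
      k <- ((i - 1L) %/% n) + 1L
      gain <- rnorm(1L, 1, config$scatter_gain_sd)
      offset <- rnorm(1L, 0, config$scatter_offset_sd)
      x[i, ] <- means[k, ] * gain + offset + rnorm(nw, 0, config$noise_sd)
    }
    x <- pmin(pmax(x, 1e-4), 1)
  }
  spectral_dataset(wl, x, labels, "reflectance")
}
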