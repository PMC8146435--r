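#' Convert reflectance to absorbance
#'
#' Element-wise `A = log10(1 / R)`, the chemometric absorbance transform.
#'
#' @param dataset A reflectance-domain [spectral_dataset()] with all values
#'   strictly positive.
#' @return The dataset in the absorbance domain.
#' @export
reflectance_to_absorbance <- function(dataset) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (dataset$domain != "reflectance")
    stop("dataset is already in the absorbance domain", call. = FALSE)
  bad <- which(dataset$spectra <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-positive reflectance at sample ", bad[1L, 1L],
         ", wavelength ", dataset$wavelengths[bad[1L, 2L]], " nm",
         call. = FALSE)
  spectral_dataset(dataset$wavelengths, log10(1 / dataset$spectra),
                   dataset$labels, "absorbance")
}

#' Fit a multiplicative scatter correction model
#'
#' The reference is the column mean of the training spectra; each spectrum
#' `x` is regressed on the reference by ordinary least squares,
#' `x ~ a + b * reference`, and corrected as `(x - a) / b`. Fitting the
#' reference on training data only (and freezing it for test data via
#' [msc_apply()]) avoids information leakage.
#'
#' @param train A non-empty [spectral_dataset()].
#' @return An object of class `msc_model` with elements `reference` and
#'   `wavelengths`.
#' @export
msc_fit <- function(train) {
  stopifnot(inherits(train, "spectral_dataset"))
  if (nrow(train$spectra) == 0L)
    stop("cannot fit MSC on an empty dataset", call. = FALSE)
  structure(list(reference = colMeans(train$spectra),
                 wavelengths = train$wavelengths),
            class = "msc_model")
}

## OLS of x on the reference; closed form, returns c(a, b)
msc_coefficients <- function(reference, x) {
  rc <- reference - mean(reference)
  b <- sum(rc * (x - mean(x))) / sum(rc * rc)
  a <- mean(x) - b * mean(reference)
  c(a = a, b = b)
}

#' Apply a multiplicative scatter correction model
#'
#' @param model An [msc_fit()] model.
#' @param dataset A [spectral_dataset()] on the same wavelength grid.
#' @param tol Gain magnitudes below `tol` are treated as degenerate.
#' @return The corrected dataset; the per-spectrum coefficients are attached
#'   as attribute `"coefficients"` (columns `a`, `b`).
#' @export
msc_apply <- function(model, dataset, tol = 1e-12) {
  stopifnot(inherits(model, "msc_model"),
            inherits(dataset, "spectral_dataset"))
  if (!isTRUE(all.equal(model$wavelengths, dataset$wavelengths)))
    stop("wavelength grid of dataset does not match the MSC reference",
         call. = FALSE)
  n <- nrow(dataset$spectra)
  out <- dataset$spectra
  ab <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("a", "b")))
  for (i in seq_len(n)) {
    cf <- msc_coefficients(model$reference, dataset$spectra[i, ])
    if (!is.finite(cf[["b"]]) || abs(cf[["b"]]) < tol)
      stop("degenerate spectrum ", i, ": MSC gain is ~0", call. = FALSE)
    ab[i, ] <- cf
    out[i, ] <- (dataset$spectra[i, ] - cf[["a"]]) / cf[["b"]]
  }
  res <- spectral_dataset(dataset$wavelengths, out, dataset$labels,
                          dataset$domain)
  attr(res, "coefficients") <- ab
  res
}

#' Running-median smoothing of each spectrum
#'
#' Per-spectrum running median with replicate (edge-value) padding, so the
#' output length equals the input length. `window = 1` is the identity.
#'
#' @param dataset A [spectral_dataset()].
#' @param window Odd window width, `1 <= window <=` spectrum length.
#' @return The smoothed dataset.
#' @export
median_smooth <- function(dataset, window = 5L) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be a positive odd integer", call. = FALSE)
  nw <- length(dataset$wavelengths)
  if (window > nw)
    stop("window (", window, ") exceeds spectrum length (", nw, ")",
         call. = FALSE)
  if (window == 1L || nrow(dataset$spectra) == 0L) return(dataset)
  h <- (window - 1L) %/% 2L
  ## replicate-pad each spectrum, then run the compiled running median and
  ## trim the padding back off
  sm <- t(apply(dataset$spectra, 1L, function(x) {
    xp <- c(rep(x[1L], h), x, rep(x[nw], h))
    stats::runmed(xp, window, endrule = "keep")[(h + 1L):(h + nw)]
  }))
  spectral_dataset(dataset$wavelengths, sm, dataset$labels, dataset$domain)
}

#' Standard preprocessing chain
#'
#' Fixed order: reflectance to absorbance, multiplicative scatter correction
#' (reference fitted on `dataset` itself unless a frozen `msc_model` is
#' supplied), then median smoothing.
#'
#' @param dataset A reflectance-domain [spectral_dataset()].
#' @param window Median-filter window (odd; default 5).
#' @param msc_model Optional frozen [msc_fit()] model (e.g. fitted on
#'   training data) to apply instead of refitting.
#' @return The preprocessed absorbance-domain dataset; the MSC model used is
#'   attached as attribute `"msc_model"`.
#' @export
preprocess_dataset <- function(dataset, window = 5L, msc_model = NULL) {
  absorb <- reflectance_to_absorbance(dataset)
  if (is.null(msc_model)) msc_model <- msc_fit(absorb)
  out <- median_smooth(msc_apply(msc_model, absorb), window)
  attr(out, "msc_model") <- msc_model
  out
}
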