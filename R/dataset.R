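#' Labelled spectral dataset
#'
#' The pipeline's currency: a samples-by-wavelengths matrix with one class
#' label per row. The `domain` tag records whether values are reflectance
#' (dimensionless, in (0, 1]) or absorbance (log10(1/R)).
#'
#' @param wavelengths Strictly increasing numeric vector of wavelengths (nm).
#' @param spectra Numeric matrix, one row per sample, one column per
#'   wavelength.
#' @param labels Factor (or character coercible to factor) of per-sample
#'   class labels.
#' @param domain Either `"reflectance"` or `"absorbance"`.
#' @return An object of class `spectral_dataset`: a list with elements
#'   `wavelengths`, `spectra`, `labels`, `domain`.
#' @export
spectral_dataset <- function(wavelengths, spectra, labels,
                             domain = c("reflectance", "absorbance")) {
  domain <- match.arg(domain)
  wavelengths <- as.numeric(wavelengths)
  spectra <- as.matrix(spectra)
  if (!is.factor(labels)) labels <- factor(labels)
  if (ncol(spectra) != length(wavelengths))
    stop("spectra has ", ncol(spectra), " columns but ", length(wavelengths),
         " wavelengths were given", call. = FALSE)
  if (nrow(spectra) != length(labels))
    stop("spectra has ", nrow(spectra), " rows but ", length(labels),
         " labels were given", call. = FALSE)
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  if (anyNA(spectra))
    stop("spectra contain missing values", call. = FALSE)
  if (domain == "reflectance" && nrow(spectra) > 0L && any(spectra <= 0))
    stop("reflectance values must be strictly positive", call. = FALSE)
  structure(
    list(wavelengths = wavelengths, spectra = unname(spectra),
         labels = labels, domain = domain),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat("<spectral_dataset> ", nrow(x$spectra), " samples x ",
      length(x$wavelengths), " wavelengths (", x$domain, ")\n", sep = "")
  if (length(x$wavelengths))
    cat("  grid: ", min(x$wavelengths), "-", max(x$wavelengths), " nm\n",
        sep = "")
  if (nrow(x$spectra))
    cat("  classes: ",
        paste(sprintf("%s=%d", levels(x$labels), tabulate(x$labels)),
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$spectra)

#' Number of samples in a dataset
#' @param dataset A [spectral_dataset()].
#' @return Integer row count.
#' @export
n_samples <- function(dataset) nrow(dataset$spectra)

#' Subset the samples of a dataset
#' @param dataset A [spectral_dataset()].
#' @param i Row index vector.
#' @return A `spectral_dataset` with the selected rows (class levels kept).
#' @export
subset_samples <- function(dataset, i) {
  spectral_dataset(dataset$wavelengths, dataset$spectra[i, , drop = FALSE],
                   dataset$labels[i], dataset$domain)
}

#' Write a spectral dataset to wide CSV
#'
#' Layout: header `label,wl<nm>,...`, one sample per row, UTF-8,
#' comma-separated. Full double precision is preserved so that a write/read
#' round trip is the identity.
#'
#' @param dataset A [spectral_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  header <- c("label", paste0("wl", format(dataset$wavelengths,
                                           trim = TRUE, digits = 15)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  if (nrow(dataset$spectra) > 0L) {
    body <- apply(dataset$spectra, 1L, function(r)
      paste(format(r, trim = TRUE, digits = 17), collapse = ","))
    writeLines(paste(as.character(dataset$labels), body, sep = ","), con)
  }
  invisible(path)
}

#' Read a spectral dataset from wide CSV
#'
#' Accepts files produced by [write_dataset()]: a header whose first column
#' is the label and whose remaining column names carry the wavelength in nm
#' (any non-numeric prefix such as `wl` is stripped). Malformed cells are
#' reported with their row and column.
#'
#' @param path CSV file path.
#' @param domain Domain tag to stamp on the result (files store plain
#'   numbers; the tag is metadata).
#' @param class_levels Optional explicit label levels; defaults to sorted
#'   unique labels found in the file.
#' @return A [spectral_dataset()].
#' @export
read_dataset <- function(path, domain = "reflectance", class_levels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  header <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  if (length(header) < 2L || header[[1L]] != "label")
    stop("malformed header: expected 'label,<wavelength columns>'",
         call. = FALSE)
  wl <- suppressWarnings(as.numeric(sub("^[^0-9]*", "", header[-1L])))
  if (anyNA(wl))
    stop("malformed header: column ",
         which(is.na(wl))[1L] + 1L, " has no parseable wavelength",
         call. = FALSE)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  nw <- length(wl)
  labs <- character(length(body))
  mat <- matrix(NA_real_, length(body), nw)
  for (i in seq_along(body)) {
    cells <- strsplit(body[[i]], ",", fixed = TRUE)[[1L]]
    # strsplit drops a trailing empty field; restore it so the missing
    # cell is reported by name instead of as a count mismatch
    if (grepl(",$", body[[i]])) cells <- c(cells, "")
    if (length(cells) != nw + 1L)
      stop("row ", i, ": expected ", nw + 1L, " fields, found ",
           length(cells), call. = FALSE)
    labs[[i]] <- cells[[1L]]
    vals <- suppressWarnings(as.numeric(cells[-1L]))
    bad <- which(is.na(vals) | !nzchar(trimws(cells[-1L])))
    if (length(bad))
      stop("row ", i, ", column '", header[bad[1L] + 1L],
           "': non-numeric or missing cell", call. = FALSE)
    mat[i, ] <- vals
  }
  if (is.null(class_levels)) class_levels <- sort(unique(labs))
  if (length(body) && !all(labs %in% class_levels))
    stop("row ", which(!labs %in% class_levels)[1L], ": unknown label '",
         labs[!labs %in% class_levels][1L], "'", call. = FALSE)
  spectral_dataset(wl, mat, factor(labs, levels = class_levels), domain)
}
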