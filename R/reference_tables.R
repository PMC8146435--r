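#' Published reference results of the cucumber nitrogen trial
#'
#' The workflow emulates a greenhouse trial in which cucumber leaves were
#' classified into four nitrogen-treatment classes (D0 = day before excess
#' nitrogen, D1-D3 = the three days after) from hyperspectral reflectance.
#' The trial's raw spectra were never deposited, but its pooled results
#' over 200 iterations of a 60/30/10 protocol were printed and are shipped
#' here as plain-text tables: per-classifier confusion matrices, per-class
#' metrics, and the effective-vs-entire-wavelength performance summary.
#' They serve as fixed inputs for the evaluation arithmetic.
#'
#' @return `reference_confusions()`: named list of 4x4 integer confusion
#'   matrices (rows = actual) for ANN-ICA, ANN-HS, KNN, LDA, RBF and MV.
#' @export
reference_confusions <- function() {
  path <- system.file("extdata", "reference_confusions.csv",
                      package = "nitrospec", mustWork = TRUE)
  d <- read.csv(path, check.names = FALSE)
  out <- list()
  for (m in unique(d$method)) {
    block <- d[d$method == m, ]
    mm <- as.matrix(block[, c("D0", "D1", "D2", "D3")])
    rownames(mm) <- block$actual
    out[[m]] <- mm
  }
  out
}

#' @rdname reference_confusions
#' @return `reference_class_metrics()`: data frame of the printed per-class
#'   recall, accuracy, specificity, precision and F values (percent).
#' @export
reference_class_metrics <- function() {
  read.csv(system.file("extdata", "reference_class_metrics.csv",
                       package = "nitrospec", mustWork = TRUE))
}

#' @rdname reference_confusions
#' @return `reference_summary()`: data frame comparing majority-voting
#'   performance on the three effective wavelengths against the entire
#'   range: mean and SD of the CCR and the four per-class AUCs.
#' @export
reference_summary <- function() {
  read.csv(system.file("extdata", "reference_summary.csv",
                       package = "nitrospec", mustWork = TRUE))
}
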