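#' Majority vote over several classifiers
#'
#' Plurality label per sample. Ties are broken by (1) the highest summed
#' score among the tied classes and (2) class order.
#'
#' @param votes List of factors (one per classifier, equal length, shared
#'   levels).
#' @param scores List of score matrices aligned with `votes` (columns in
#'   class order). Optional; without scores ties fall through to class
#'   order.
#' @return Factor of ensemble labels.
#' @export
majority_vote <- function(votes, scores = NULL) {
  if (length(votes) == 0L) stop("at least one voter is required",
                                call. = FALSE)
  lev <- levels(votes[[1L]])
  for (v in votes)
    if (!identical(levels(v), lev))
      stop("all voters must share the same class order", call. = FALSE)
  n <- length(votes[[1L]])
  vote_mat <- vapply(votes, as.integer, integer(n))
  if (n == 1L) vote_mat <- matrix(vote_mat, nrow = 1L)
  total_score <- NULL
  if (!is.null(scores)) {
    total_score <- Reduce(`+`, scores)
  }
  out <- integer(n)
  for (i in seq_len(n)) {
    counts <- tabulate(vote_mat[i, ], nbins = length(lev))
    top <- which(counts == max(counts))
    if (length(top) > 1L && !is.null(total_score)) {
      s <- total_score[i, top]
      top <- top[s == max(s)]
    }
    out[i] <- top[1L]
  }
  factor(lev[out], levels = lev)
}

#' Confusion matrix
#'
#' `counts[i, j]` = number of samples with actual class `i` predicted as
#' class `j`.
#'
#' @param actual,predicted Equal-length label vectors.
#' @param class_levels Class order; defaults to the levels of `actual`.
#' @return Integer matrix with classes as row and column names.
#' @export
confusion <- function(actual, predicted, class_levels = NULL) {
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length", call. = FALSE)
  if (is.null(class_levels))
    class_levels <- if (is.factor(actual)) levels(actual)
                    else sort(unique(c(actual, predicted)))
  if (length(actual)) {
    bad <- !(as.character(actual) %in% class_levels) |
      !(as.character(predicted) %in% class_levels)
    if (any(bad))
      stop("unknown label at position ", which(bad)[1L], call. = FALSE)
  }
  a <- factor(as.character(actual), levels = class_levels)
  p <- factor(as.character(predicted), levels = class_levels)
  m <- table(actual = a, predicted = p)
  matrix(as.integer(m), nrow = length(class_levels),
         dimnames = list(class_levels, class_levels))
}

#' Correct classification rate
#'
#' @param m Confusion matrix (rows = actual).
#' @return Percent: `100 * trace / grand total`.
#' @export
ccr <- function(m) {
  m <- as.matrix(m)
  total <- sum(m)
  if (total <= 0) stop("confusion matrix has zero total", call. = FALSE)
  100 * sum(diag(m)) / total
}

#' Per-class misclassification percentage (row off-diagonal over diagonal)
#'
#' Nonstandard convention used in the trial's result tables: the off-
#' diagonal sum of a class's row divided by its diagonal cell, in percent
#' (can exceed 100 when a class is mostly misclassified).
#'
#' @param m Confusion matrix (rows = actual).
#' @param class Row name or index.
#' @return Percent misclassified for that class.
#' @export
misclassified_pct <- function(m, class) {
  m <- as.matrix(m)
  i <- if (is.character(class)) match(class, rownames(m)) else as.integer(class)
  if (is.na(i) || i < 1L || i > nrow(m))
    stop("unknown class: ", class, call. = FALSE)
  d <- m[i, i]
  if (d <= 0) stop("zero diagonal cell for class ", class, call. = FALSE)
  100 * (sum(m[i, ]) - d) / d
}

#' Per-class recall, accuracy, specificity, precision and F
#'
#' Two conventions are available. `"standard"` uses rows as actual classes:
#' TP = diagonal, FN = row total - TP, FP = column total - TP, TN =
#' remainder. `"published"` reproduces the orientation used in the trial's
#' result tables, which is the standard computation applied to the
#' transposed matrix (so its printed recall is diagonal over column total
#' and its precision diagonal over row total). F is the harmonic mean of
#' recall and precision in either convention.
#'
#' @param m Confusion matrix (rows = actual).
#' @param convention `"published"` or `"standard"`.
#' @return Data frame with one row per class and columns `class`, `recall`,
#'   `accuracy`, `specificity`, `precision`, `f` (all in percent).
#' @export
per_class_metrics <- function(m, convention = c("published", "standard")) {
  convention <- match.arg(convention)
  m <- as.matrix(m)
  total <- sum(m)
  if (total <= 0) stop("confusion matrix has zero total", call. = FALSE)
  if (convention == "published") m <- t(m)
  cls <- rownames(m)
  if (is.null(cls)) cls <- as.character(seq_len(nrow(m)))
  tp <- diag(m)
  fn <- rowSums(m) - tp
  fp <- colSums(m) - tp
  tn <- total - tp - fn - fp
  safe_pct <- function(num, den, what) {
    out <- ifelse(den > 0, 100 * num / den, 0)
    if (any(den <= 0))
      warning("zero denominator for ", what, " in class ",
              paste(cls[den <= 0], collapse = ", "), "; reported as 0")
    out
  }
  recall <- safe_pct(tp, tp + fn, "recall")
  precision <- safe_pct(tp, tp + fp, "precision")
  accuracy <- 100 * (tp + tn) / total
  specificity <- safe_pct(tn, tn + fp, "specificity")
  f <- ifelse(recall + precision > 0,
              2 * recall * precision / (recall + precision), 0)
  data.frame(class = cls, recall = recall, accuracy = accuracy,
             specificity = specificity, precision = precision, f = f,
             row.names = NULL)
}

#' ROC curve and AUC for one class (one-vs-rest)
#'
#' AUC by the trapezoidal rule over all score thresholds, which with tied
#' scores equals the midrank (Mann-Whitney) convention:
#' identical scores for every sample give 0.5.
#'
#' @param scores Numeric score for the positive class.
#' @param positive Logical (or 0/1) vector: `TRUE` for the positive class.
#' @return List with `auc` and `curve` (data frame of `fpr`, `tpr` points,
#'   thresholds descending).
#' @export
roc_auc <- function(scores, positive) {
  positive <- as.logical(positive)
  if (length(scores) != length(positive))
    stop("scores and labels must have equal length", call. = FALSE)
  npos <- sum(positive); nneg <- sum(!positive)
  if (npos == 0L || nneg == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)  # average ranks handle ties (midrank convention)
  auc <- (sum(r[positive]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[positive] >= t), numeric(1L))
  fpr <- vapply(thr, function(t) mean(scores[!positive] >= t), numeric(1L))
  list(auc = auc,
       curve = data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                          tpr = c(0, tpr)))
}

#' Paired two-sided t test
#'
#' @param values_a,values_b Equal-length numeric vectors (n >= 2).
#' @return List with `mean_difference`, `sd_difference`, `t`, `df`,
#'   `p_value`. Zero-variance differences are reported exactly: `t = 0`,
#'   `p = 1` when the mean difference is zero, otherwise a signed infinite
#'   `t` with `p = 0`.
#' @export
paired_t_test <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop("paired samples must have equal length", call. = FALSE)
  n <- length(values_a)
  if (n < 2L) stop("need at least two pairs", call. = FALSE)
  d <- values_a - values_b
  if (sd(d) == 0) {
    md <- mean(d)
    return(list(mean_difference = md, sd_difference = 0,
                t = if (md == 0) 0 else sign(md) * Inf,
                df = n - 1L, p_value = if (md == 0) 1 else 0))
  }
  tt <- t.test(values_a, values_b, paired = TRUE)
  list(mean_difference = mean(d), sd_difference = sd(d),
       t = unname(tt$statistic),
       df = as.integer(round(unname(tt$parameter))),
       p_value = tt$p.value)
}

#' Total nitrogen percentage by the Kjeldahl titration formula
#'
#' `N (%) = (Vs - Vb) / md * normality * 0.014 * 100`, the milliequivalent
#' conversion of titrated sulfuric acid volumes to percent nitrogen of dry
#' mass.
#'
#' @param sample_volume Titration volume consumed by the sample, Vs (mL).
#' @param blank_volume Volume consumed by the blank, Vb (mL).
#' @param normality Normality of the sulfuric acid (eq/L).
#' @param dry_mass Dry sample mass (g), > 0.
#' @return Percent nitrogen. Negative when the blank exceeds the sample
#'   volume (reported with a warning).
#' @export
kjeldahl_nitrogen <- function(sample_volume, blank_volume, normality,
                              dry_mass) {
  if (any(dry_mass <= 0)) stop("dry mass must be > 0", call. = FALSE)
  out <- 100 * ((sample_volume - blank_volume) / dry_mass) *
    normality * 0.014
  if (any(out < 0))
    warning("blank volume exceeds sample volume; negative nitrogen value")
  out
}

#' Repeated-split scheme
#'
#' @param train,test,validation Split fractions (must sum to 1).
#' @param iterations Number of repetitions (default 200).
#' @param seed Master seed.
#' @return List of class `split_scheme`.
#' @export
split_scheme <- function(train = 0.6, test = 0.3, validation = 0.1,
                         iterations = 200L, seed = 1L) {
  if (abs(train + test + validation - 1) > 1e-9)
    stop("split fractions must sum to 1", call. = FALSE)
  stopifnot(train > 0, test > 0, validation >= 0, iterations >= 1L)
  structure(list(train = train, test = test, validation = validation,
                 iterations = as.integer(iterations),
                 seed = as.integer(seed)),
            class = "split_scheme")
}

## disjoint, exhaustive 60/30/10 split of a seeded shuffle
split_indices <- function(n, scheme, seed) {
  set.seed(seed)
  ord <- sample.int(n)
  n_train <- floor(scheme$train * n)
  n_test <- floor(scheme$test * n)
  list(train = ord[seq_len(n_train)],
       test = ord[seq.int(n_train + 1L, n_train + n_test)],
       validation = if (n_train + n_test < n)
         ord[seq.int(n_train + n_test + 1L, n)] else integer(0))
}

#' Ensemble configuration for the repeated evaluation
#'
#' Desk-scale defaults for the five base classifiers; the metaheuristic
#' budgets are sized so a full repeated run stays interactive.
#'
#' @param ann_population,ann_generations Imperialist-competitive budget for
#'   the ANN-ICA member.
#' @param hs_memory,hs_improvisations Harmony-search budget for the ANN-HS
#'   member.
#' @param inner_epochs Backpropagation epochs inside both hybrid trainers.
#' @param knn_grid Candidate k values (selected on the validation split).
#' @param rbf_centers Gaussian units of the RBF member.
#' @param lda_stepwise Use stepwise variable selection in the LDA member.
#' @return List of class `ensemble_config`.
#' @export
ensemble_config <- function(ann_population = 20L, ann_generations = 8L,
                            hs_memory = 15L, hs_improvisations = 150L,
                            inner_epochs = 40L,
                            knn_grid = c(1L, 3L, 5L, 7L, 9L),
                            rbf_centers = 4L, lda_stepwise = TRUE) {
  structure(list(ann_population = ann_population,
                 ann_generations = ann_generations,
                 hs_memory = hs_memory,
                 hs_improvisations = hs_improvisations,
                 inner_epochs = inner_epochs, knn_grid = knn_grid,
                 rbf_centers = rbf_centers, lda_stepwise = lda_stepwise),
            class = "ensemble_config")
}

#' Repeated-split evaluation of the five classifiers and majority voting
#'
#' For each iteration: seeded shuffle, disjoint train/test/validation
#' split, fit all five classifiers on the (feature-standardized) training
#' split, classify the test split, form the majority vote, and accumulate
#' test-set confusion counts. Confusion matrices are pooled (summed) over
#' iterations. An iteration whose train or test split misses a class is
#' reseeded once, then raises an error.
#'
#' @param dataset A [spectral_dataset()], normally preprocessed and
#'   restricted to the selected bands.
#' @param scheme A [split_scheme()].
#' @param config An [ensemble_config()].
#' @return An `evaluation_report`: list with `confusions` (named list of
#'   pooled matrices, including `"MV"`), `ccr_series` (iterations x 6
#'   matrix), `auc_series` (per-iteration one-vs-rest AUC of the
#'   majority-vote scores, one column per class), `scheme`, `config` and
#'   `class_levels`.
#' @export
repeated_evaluation <- function(dataset, scheme = split_scheme(),
                                config = ensemble_config()) {
  stopifnot(inherits(dataset, "spectral_dataset"),
            inherits(scheme, "split_scheme"))
  x <- dataset$spectra
  y <- dataset$labels
  lev <- levels(y)
  members <- c("ANN-ICA", "ANN-HS", "KNN", "LDA", "RBF")
  all_names <- c(members, "MV")
  conf <- setNames(lapply(all_names, function(i)
    matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))),
    all_names)
  ccr_series <- matrix(NA_real_, scheme$iterations, length(all_names),
                       dimnames = list(NULL, all_names))
  auc_series <- matrix(NA_real_, scheme$iterations, length(lev),
                       dimnames = list(NULL, lev))

  for (it in seq_len(scheme$iterations)) {
    iter_seed <- stage_seed(scheme$seed, paste0("iteration-", it))
    sp <- split_indices(nrow(x), scheme, iter_seed)
    ok <- function(s) all(lev %in% y[s$train]) && all(lev %in% y[s$test])
    if (!ok(sp)) {
      sp <- split_indices(nrow(x), scheme,
                          stage_seed(iter_seed, "reseed"))
      if (!ok(sp))
        stop("iteration ", it, ": a split is missing a class", call. = FALSE)
    }
    scaler <- fit_scaler(x[sp$train, , drop = FALSE])
    xtr <- apply_scaler(scaler, x[sp$train, , drop = FALSE])
    xte <- apply_scaler(scaler, x[sp$test, , drop = FALSE])
    xva <- if (length(sp$validation))
      apply_scaler(scaler, x[sp$validation, , drop = FALSE]) else xtr
    ytr <- y[sp$train]
    yte <- y[sp$test]
    yva <- if (length(sp$validation)) y[sp$validation] else ytr

    fits <- list(
      "ANN-ICA" = train_ann_metaheuristic(
        xtr, ytr, "ica",
        params = ica_params(population = config$ann_population,
                            generations = config$ann_generations,
                            n_imperialists =
                              max(1L, min(5L, config$ann_population %/% 4L)),
                            seed = stage_seed(iter_seed, "ica")),
        inner_epochs = config$inner_epochs),
      "ANN-HS" = train_ann_metaheuristic(
        xtr, ytr, "hs",
        params = hs_params(memory_size = config$hs_memory,
                           improvisations = config$hs_improvisations,
                           seed = stage_seed(iter_seed, "hs")),
        inner_epochs = config$inner_epochs),
      "KNN" = knn_classifier(xtr, ytr, k = NULL,
                             validation_inputs = xva,
                             validation_labels = yva,
                             k_grid = config$knn_grid),
      "LDA" = lda_fit(xtr, ytr, stepwise = config$lda_stepwise),
      "RBF" = rbf_classifier(xtr, ytr, n_centers = config$rbf_centers,
                             seed = stage_seed(iter_seed, "rbf"))
    )
    labels <- lapply(fits, predict, newdata = xte, type = "class")
    scores <- lapply(fits, predict, newdata = xte, type = "score")
    mv <- majority_vote(labels, scores)
    mv_scores <- Reduce(`+`, scores) / length(scores)

    for (nm in members) {
      cm <- confusion(yte, labels[[nm]], lev)
      conf[[nm]] <- conf[[nm]] + cm
      ccr_series[it, nm] <- ccr(cm)
    }
    cm <- confusion(yte, mv, lev)
    conf[["MV"]] <- conf[["MV"]] + cm
    ccr_series[it, "MV"] <- ccr(cm)
    for (cl in seq_along(lev))
      auc_series[it, cl] <- roc_auc(mv_scores[, cl], yte == lev[cl])$auc
  }
  structure(list(confusions = conf, ccr_series = ccr_series,
                 auc_series = auc_series, scheme = scheme, config = config,
                 class_levels = lev),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", x$scheme$iterations,
      " iterations, pooled CCR (%):\n", sep = "")
  for (nm in names(x$confusions))
    cat(sprintf("  %-8s %6.2f\n", nm, ccr(x$confusions[[nm]])))
  invisible(x)
}
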