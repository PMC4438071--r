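# Classification harness: labeled feature corpora, leave-one-video-out and
# leave-one-subject-out folds, and pooled SVM cross-validated accuracy.

#' Construct a labeled feature corpus
#'
#' Bundles a feature matrix with per-sample metadata for cross-validated
#' evaluation.  All rows must share one feature layout; each sample has
#' exactly one subject and one class label.
#'
#' @param features Numeric matrix, one row per sample.
#' @param sample_id Character vector of unique sample identifiers.
#' @param subject_id Character or factor vector of subject identifiers.
#' @param label Character or factor vector of class labels.
#' @return An object of class `corpus`.
#' @export
corpus <- function(features, sample_id, subject_id, label) {
  features <- as.matrix(features)
  n <- nrow(features)
  sample_id <- as.character(sample_id)
  stopifnot(length(sample_id) == n, length(subject_id) == n, length(label) == n)
  if (anyDuplicated(sample_id)) stop("sample ids must be unique", call. = FALSE)
  if (any(!is.finite(features))) stop("features must be finite", call. = FALSE)
  structure(list(features = features,
                 meta = data.frame(sample_id = sample_id,
                                   subject_id = as.character(subject_id),
                                   label = as.character(label),
                                   stringsAsFactors = FALSE)),
            class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus> %d samples, %d features, %d subjects, %d classes\n",
              nrow(x$features), ncol(x$features),
              length(unique(x$meta$subject_id)), length(unique(x$meta$label))))
  invisible(x)
}

#' Cross-validation folds for a corpus
#'
#' `"lovo"` (leave-one-video-out) holds out each sample in turn, giving as
#' many folds as samples; it is subject-identity dependent.  `"loso"`
#' (leave-one-subject-out) holds out all samples of each subject in turn,
#' giving as many folds as subjects, and never places one subject in both
#' train and test.  Folds are ordered deterministically by sample/subject
#' id.
#'
#' @param corp A [corpus()].
#' @param scheme `"lovo"` or `"loso"`.
#' @return List of folds, each `list(train = ids, test = ids)` of sample
#'   ids.
#' @export
make_folds <- function(corp, scheme = c("lovo", "loso")) {
  stopifnot(inherits(corp, "corpus"))
  scheme <- match.arg(scheme)
  meta <- corp$meta
  if (nrow(meta) == 0) stop("empty corpus", call. = FALSE)
  if (scheme == "lovo") {
    ids <- sort(meta$sample_id)
    lapply(ids, function(id) list(train = setdiff(ids, id), test = id))
  } else {
    subjects <- sort(unique(meta$subject_id))
    if (length(subjects) < 2)
      stop("leave-one-subject-out needs at least 2 subjects", call. = FALSE)
    lapply(subjects, function(s) {
      test <- sort(meta$sample_id[meta$subject_id == s])
      list(train = sort(meta$sample_id[meta$subject_id != s]), test = test)
    })
  }
}

svm_kernel_args <- function(kernel, d, degree) {
  switch(kernel,
         linear = list(kernel = "linear"),
         rbf = list(kernel = "radial", gamma = 1 / d),
         poly6 = list(kernel = "polynomial", degree = degree, gamma = 1 / d,
                      coef0 = 1),
         stop(sprintf("unknown kernel '%s'", kernel), call. = FALSE))
}

#' Cross-validated SVM classification accuracy
#'
#' Runs an SVM (one-vs-one multi-class, regularization cost 1, kernel width
#' `1/ncol(features)` where applicable) over the folds of the chosen
#' cross-validation scheme and pools test predictions over all folds:
#' accuracy is the fraction of all test samples classified correctly, the
#' usual "recognition rate".  Features are used as-is (descriptor
#' histograms already lie in `[0, 1]`) unless `scale = TRUE`.
#'
#' A training fold containing fewer than two classes is skipped with a
#' warning and its test samples are excluded from the pooled accuracy; the
#' report lists skipped folds.
#'
#' @param corp A [corpus()].
#' @param scheme `"lovo"` or `"loso"` (see [make_folds()]).
#' @param kernel `"linear"`, `"rbf"`, or `"poly6"` (sixth-order polynomial).
#' @param cost SVM regularization constant (default 1).
#' @param degree Polynomial degree used by `"poly6"` (default 6).
#' @param scale Standardize features before fitting (default `FALSE`).
#' @param seed Integer seed fixing any randomness; identical seeds give
#'   bit-identical reports.
#' @return An object of class `cv_result`: list with `accuracy`,
#'   `predictions` (data frame: fold, sample_id, truth, predicted),
#'   `confusion` (table), `skipped_folds`, `scheme`, `kernel`.
#' @export
cross_validated_accuracy <- function(corp, scheme = c("lovo", "loso"),
                                     kernel = c("linear", "rbf", "poly6"),
                                     cost = 1, degree = 6, scale = FALSE,
                                     seed = 1) {
  stopifnot(inherits(corp, "corpus"))
  scheme <- match.arg(scheme)
  kernel <- match.arg(kernel)
  folds <- make_folds(corp, scheme)
  meta <- corp$meta
  rownames(corp$features) <- meta$sample_id
  labels <- factor(meta$label)
  names(labels) <- meta$sample_id
  kargs <- svm_kernel_args(kernel, ncol(corp$features), degree)
  preds <- list(); skipped <- character(0)
  with_seed(seed, {
    for (i in seq_along(folds)) {
      tr <- folds[[i]]$train; te <- folds[[i]]$test
      ytr <- droplevels(labels[tr])
      if (nlevels(ytr) < 2) {
        warning(sprintf("fold %d skipped: training data contains a single class", i),
                call. = FALSE)
        skipped <- c(skipped, sprintf("fold%d", i))
        next
      }
      fit <- do.call(e1071::svm,
                     c(list(x = corp$features[tr, , drop = FALSE], y = ytr,
                            cost = cost, scale = scale), kargs))
      p <- predict(fit, corp$features[te, , drop = FALSE])
      preds[[length(preds) + 1]] <-
        data.frame(fold = i, sample_id = te,
                   truth = as.character(labels[te]),
                   predicted = as.character(p),
                   stringsAsFactors = FALSE)
    }
  })
  predictions <- do.call(rbind, preds)
  if (is.null(predictions))
    stop("every fold was skipped; no predictions made", call. = FALSE)
  acc <- mean(predictions$predicted == predictions$truth)
  confusion <- table(truth = factor(predictions$truth, levels = levels(labels)),
                     predicted = factor(predictions$predicted, levels = levels(labels)))
  structure(list(accuracy = acc, predictions = predictions,
                 confusion = confusion, skipped_folds = skipped,
                 scheme = scheme, kernel = kernel),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s / %s: pooled accuracy %.4f over %d test predictions\n",
              toupper(x$scheme), x$kernel, x$accuracy, nrow(x$predictions)))
  if (length(x$skipped_folds))
    cat("  skipped folds:", paste(x$skipped_folds, collapse = ", "), "\n")
  invisible(x)
}
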