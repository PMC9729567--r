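#' Random train/test partition
#'
#' Uniform random subset without replacement of size `ceiling(fraction * n)`
#' as the training set (this rounding reproduces the published 65/16, 32/7
#' and 28/7 size pairs at n = 81, 39, 35); the remainder is the test set.
#' Deterministic given `seed`.
#'
#' @param n_rows Number of rows (>= 2).
#' @param fraction Target train share, strictly between 0 and 1 (default
#'   0.8).
#' @param seed Integer seed.
#' @return List of class `"partition"`: `train`, `test` (integer row
#'   indices), `fraction`, `seed`.
#' @export
partition <- function(n_rows, fraction = 0.8, seed) {
  stopifnot(n_rows >= 2, fraction > 0, fraction < 1)
  n_train <- ceiling(fraction * n_rows)
  if (n_train >= n_rows) stop("test set would be empty", call. = FALSE)
  withr::local_seed(as.integer(seed))
  train <- sort(sample.int(n_rows, n_train))
  structure(list(train = train, test = setdiff(seq_len(n_rows), train),
                 fraction = fraction, seed = seed),
            class = "partition")
}

# one call per test row: the class whose proportion exceeds `threshold`,
# else the argmax (ties broken by class order)
call_classes <- function(proportions, classes, threshold = 0.5) {
  apply(proportions, 1, function(p) {
    over <- which(p > threshold)
    if (length(over) >= 1) classes[over[1]] else classes[which.max(p)]
  })
}

#' Per-class one-vs-rest confusion matrices
#'
#' Each test row receives exactly one called class: the class whose leaf
#' proportion exceeds the decision threshold (default 0.5), falling back to
#' the argmax with class-order tie-break when none does.  For each class c
#' the 2x2 matrix counts TP (called c, actually c), FP (called c, actually
#' not), FN and TN; every matrix sums to the number of test rows.
#'
#' @param predictions Output of [predict.isotope_tree()]: list with `site`
#'   and `proportions`.
#' @param actual Character vector of true site labels.
#' @param classes Ordered class labels.
#' @param threshold Decision threshold on leaf proportions.
#' @return List of class `"confusion_set"`: `classes`, `threshold`,
#'   `called` (per-row calls), `matrices` (named list of `c(TP, FP, FN,
#'   TN)` per class).
#' @export
confusion <- function(predictions, actual, classes, threshold = 0.5) {
  prop <- predictions$proportions
  stopifnot(nrow(prop) == length(actual))
  if (any(abs(rowSums(prop) - 1) > 1e-9)) {
    stop("proportion vectors must sum to 1", call. = FALSE)
  }
  if (!all(actual %in% classes)) {
    stop("actual labels outside declared class set", call. = FALSE)
  }
  called <- call_classes(prop[, classes, drop = FALSE], classes, threshold)
  matrices <- lapply(classes, function(cl) {
    tp <- sum(called == cl & actual == cl)
    fp <- sum(called == cl & actual != cl)
    fn <- sum(called != cl & actual == cl)
    tn <- sum(called != cl & actual != cl)
    c(TP = tp, FP = fp, FN = fn, TN = tn)
  })
  names(matrices) <- classes
  structure(list(classes = classes, threshold = threshold, called = called,
                 matrices = matrices),
            class = "confusion_set")
}

#' Performance measures from a 2x2 confusion matrix
#'
#' The five standard ratios: accuracy (TP+TN over all), sensitivity
#' (TP/(TP+FN)), specificity (TN/(FP+TN)), positive predictive value
#' (TP/(TP+FP)) and negative predictive value (TN/(TN+FN)).  A measure
#' whose denominator is zero is returned as `NA` (undefined), never as an
#' error.
#'
#' @param matrix Named numeric vector `c(TP, FP, FN, TN)`.
#' @return Named list: `accuracy`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`; each in `[0, 1]` or `NA`.
#' @export
metrics <- function(matrix) {
  tp <- matrix[["TP"]]; fp <- matrix[["FP"]]
  fn <- matrix[["FN"]]; tn <- matrix[["TN"]]
  total <- tp + fp + fn + tn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(accuracy = ratio(tp + tn, total),
       sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, fp + tn),
       ppv = ratio(tp, tp + fp),
       npv = ratio(tn, tn + fn))
}

#' Train and evaluate one classifier model end to end
#'
#' Builds the model's [feature_matrix()] from the samples, orders rows
#' canonically by unit id (so the partition is invariant to input row
#' order), draws an 80/20 [partition()], grows the tree on the training
#' rows, predicts the test rows, and tallies per-class confusion matrices,
#' per-class metrics and the overall accuracy (fraction of correct calls
#' on the test set).
#'
#' @param table A [sample_table].
#' @param model Integer 1 (hair), 2 (toenail) or 3 (both tissues,
#'   individual-level).
#' @param config A [tree_config()].
#' @param seed Integer seed for the partition.
#' @param fraction Train share (default 0.8).
#' @param threshold Decision threshold for class calls (default 0.5).
#' @return List of class `"evaluation_report"`: `model`, `n`, `n_train`,
#'   `n_test`, `tree`, `confusion`, `metrics` (per class),
#'   `overall_accuracy`, `seed`.
#' @export
evaluate_model <- function(table, model, config = tree_config(), seed,
                           fraction = 0.8, threshold = 0.5) {
  fm <- feature_matrix(table, model)
  if (nrow(fm$x) < 2) stop("too few complete rows for model ", model,
                           call. = FALSE)
  ord <- order(fm$ids)
  fm$x <- fm$x[ord, , drop = FALSE]
  fm$y <- fm$y[ord]
  fm$ids <- fm$ids[ord]
  part <- partition(nrow(fm$x), fraction = fraction, seed = seed)
  train_fm <- list(x = fm$x[part$train, , drop = FALSE],
                   y = fm$y[part$train], features = fm$features)
  tree <- grow_tree(train_fm, config)
  preds <- stats::predict(tree, fm$x[part$test, , drop = FALSE])
  actual <- as.character(fm$y[part$test])
  conf <- confusion(preds, actual, classes = levels(fm$y),
                    threshold = threshold)
  per_class <- lapply(conf$matrices, metrics)
  structure(list(model = model, n = nrow(fm$x),
                 n_train = length(part$train), n_test = length(part$test),
                 tree = tree, confusion = conf, metrics = per_class,
                 overall_accuracy = mean(conf$called == actual),
                 test_ids = fm$ids[part$test], seed = seed),
            class = "evaluation_report")
}
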