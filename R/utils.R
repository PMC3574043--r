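# Internal helpers shared across modules: seed derivation, stratified CV
# splits and thin wrappers around e1071::svm.

#' Derive a stage-specific random seed
#'
#' Maps a global seed and a stage label to a reproducible child seed so that
#' adding or reordering pipeline stages never perturbs the random stream of
#' the others. Purely arithmetic; does not touch the RNG state.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483587
  as.integer((abs(seed) %% 2147483587 * 7919 + h) %% 2147483587 + 1)
}

# Stratified fold assignment: shuffles indices within each class using the
# current RNG state and deals them round-robin, so per-fold class counts
# differ by at most one.
stratified_fold_ids <- function(labels, n_folds) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# Gaussian-kernel SVM with the libsvm defaults the wrapper relies on:
# cost 1, kernel coefficient 1/(number of selected genes), no rescaling.
svm_fit <- function(x, y, kernel = "radial") {
  e1071::svm(x, y,
    kernel = kernel, cost = 1,
    gamma = 1 / ncol(x), scale = FALSE, fitted = FALSE
  )
}

# Cross-validated accuracy over a fixed fold assignment. `pool = TRUE`
# returns total correct / total samples; otherwise the mean of per-fold
# accuracies.
svm_cv_accuracy <- function(x, y, fold, kernel = "radial", pool = FALSE) {
  n_folds <- max(fold)
  correct <- numeric(n_folds)
  size <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    te <- fold == f
    m <- svm_fit(x[!te, , drop = FALSE], y[!te], kernel = kernel)
    pr <- predict(m, x[te, , drop = FALSE])
    correct[f] <- sum(pr == y[te])
    size[f] <- sum(te)
  }
  if (pool) sum(correct) / sum(size) else mean(correct / size)
}

# Validate that an expression matrix and a label vector agree.
check_expr_labels <- function(expr, labels) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  labels <- as.factor(labels)
  if (length(labels) != ncol(expr)) {
    stop("length of 'labels' must equal the number of samples (columns)")
  }
  if (nlevels(droplevels(labels)) != 2L) {
    stop("labels must contain exactly two classes, both non-empty")
  }
  droplevels(labels)
}

# Extract a class-label factor aligned to the matrix columns from a sample
# annotation data frame.
labels_for <- function(expr, annotation) {
  stopifnot(all(c("sample_id", "class_label") %in% names(annotation)))
  idx <- match(colnames(expr), annotation$sample_id)
  if (anyNA(idx)) stop("every sample in the matrix needs an annotation row")
  factor(annotation$class_label[idx])
}
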