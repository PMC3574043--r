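# Cross-validated evaluation of ranked gene lists and selector sets, and
# mutual-information redundancy profiling of top-ranked genes.

# equal-frequency discretization via quantile breaks; merges to fewer
# bins when the gene has too few distinct values
equal_freq_bins <- function(x, n_bins) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 3L) {
    return(rep(1L, length(x)))
  }
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

train_predict_accuracy <- function(expr, labels, genes, train_ids, test_ids,
                                   classifier, n_trees = 1000) {
  xtr <- t(expr[genes, train_ids, drop = FALSE])
  xte <- t(expr[genes, test_ids, drop = FALSE])
  ytr <- labels[match(train_ids, colnames(expr))]
  yte <- labels[match(test_ids, colnames(expr))]
  pr <- switch(classifier,
    svm_linear = predict(svm_fit(xtr, ytr, kernel = "linear"), xte),
    svm_gaussian = predict(svm_fit(xtr, ytr, kernel = "radial"), xte),
    random_forest = predict(
      randomForest::randomForest(xtr, ytr, ntree = n_trees), xte
    ),
    stop("unknown classifier: ", classifier)
  )
  mean(pr == yte)
}

#' Test-set accuracy of the top-k genes per ranking method
#'
#' For every fold, classifier and list size k: train the classifier on the
#' fold's training samples restricted to the top-k genes of that fold's
#' ranking (which must have been computed on the training subset only)
#' and report the accuracy (correct / total) on the held-out test
#' samples.
#'
#' @param rankings Per-fold list; each element is a named list of
#'   `ranked_list` objects (one per method) computed on that fold's
#'   training samples.
#' @param expr Expression matrix, genes x samples (all samples).
#' @param annotation Sample annotation data frame.
#' @param fold_plan A [make_grouped_folds()] plan aligned with `rankings`.
#' @param k_values List sizes; values exceeding a ranking's length are
#'   truncated with a warning.
#' @param classifiers Subset of `"svm_linear"`, `"svm_gaussian"`,
#'   `"random_forest"`.
#' @param n_trees Trees for the random-forest classifier.
#' @param seed Optional seed (random-forest training).
#' @return Data frame of class `accuracy_table`: `method`, `classifier`,
#'   `k`, `fold`, `accuracy`, plus the fold mean rows obtainable via
#'   [stats::aggregate()].
#' @export
accuracy_topk <- function(rankings, expr, annotation, fold_plan,
                          k_values = c(50, 40, 30, 20, 15, 10, 5, 3, 2, 1),
                          classifiers = c(
                            "svm_linear", "svm_gaussian",
                            "random_forest"
                          ),
                          n_trees = 1000, seed = NULL) {
  stopifnot(inherits(fold_plan, "fold_plan"))
  stopifnot(length(rankings) == fold_plan$n_folds)
  labels <- labels_for(expr, annotation)
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- NULL
  for (f in seq_len(fold_plan$n_folds)) {
    fold <- fold_plan$folds[[f]]
    for (method in names(rankings[[f]])) {
      rl <- rankings[[f]][[method]]
      for (k in k_values) {
        kk <- k
        if (kk > nrow(rl)) {
          warning("k = ", k, " exceeds ranking length; truncated")
          kk <- nrow(rl)
        }
        genes <- rl$gene[seq_len(kk)]
        for (cls in classifiers) {
          acc <- train_predict_accuracy(
            expr, labels, genes, fold$train, fold$test, cls, n_trees
          )
          out <- rbind(out, data.frame(
            method = method, classifier = cls, k = k, fold = f,
            accuracy = acc, stringsAsFactors = FALSE
          ))
        }
      }
    }
  }
  rownames(out) <- NULL
  class(out) <- c("accuracy_table", "data.frame")
  out
}

#' Test-set accuracy of individual selector sets, grouped by size
#'
#' Each final gene set from a single GA/SVM run (on a fold's training
#' samples) trains its own Gaussian-kernel SVM, evaluated on the fold's
#' test samples; accuracies are grouped by set cardinality. This is the
#' single-run-set counterpart of the combined-list evaluation.
#'
#' @param sets_per_fold Per-fold list of gene-set lists.
#' @param expr Expression matrix, genes x samples.
#' @param annotation Sample annotation data frame.
#' @param fold_plan A [make_grouped_folds()] plan.
#' @return List with `per_set` (data frame `fold`, `set`, `size`,
#'   `accuracy`) and `by_size` (mean accuracy per set size, averaged over
#'   sets within a fold and then over folds).
#' @export
small_set_accuracy <- function(sets_per_fold, expr, annotation, fold_plan) {
  stopifnot(inherits(fold_plan, "fold_plan"))
  stopifnot(length(sets_per_fold) == fold_plan$n_folds)
  labels <- labels_for(expr, annotation)
  per_set <- NULL
  for (f in seq_len(fold_plan$n_folds)) {
    fold <- fold_plan$folds[[f]]
    sets <- sets_per_fold[[f]]
    for (s in seq_along(sets)) {
      genes <- sets[[s]]
      acc <- train_predict_accuracy(
        expr, labels, genes, fold$train, fold$test, "svm_gaussian"
      )
      per_set <- rbind(per_set, data.frame(
        fold = f, set = s, size = length(genes), accuracy = acc
      ))
    }
  }
  rownames(per_set) <- NULL
  fold_size <- aggregate(accuracy ~ fold + size, per_set, mean)
  by_size <- aggregate(accuracy ~ size, fold_size, mean)
  names(by_size)[2] <- "mean_accuracy"
  list(per_set = per_set, by_size = by_size)
}

# plug-in mutual information in bits between two discretized vectors
mi_bits <- function(bi, bj) {
  tab <- table(bi, bj)
  n <- sum(tab)
  p <- tab / n
  pi_ <- rowSums(p)
  pj <- colSums(p)
  ind <- outer(pi_, pj)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / ind[nz]))
}

#' Pairwise mutual information of a gene list
#'
#' Discretizes each gene into equal-frequency bins over all samples and
#' computes plug-in mutual information (bits) for every gene pair. High
#' values flag redundant gene lists; the comparison of interest is
#' between selection methods, not absolute values. Genes with fewer
#' distinct values than bins get as many bins as the data support.
#'
#' @param expr Expression matrix, genes x samples.
#' @param genes Gene list (typically a top-50 ranking).
#' @param n_bins Equal-frequency bins per gene.
#' @return Data frame of class `mi_table`: `gene_i`, `gene_j`, `mi`;
#'   attributes `mean` and `median` hold the summary statistics.
#' @export
pairwise_mutual_information <- function(expr, genes, n_bins = 10) {
  stopifnot(length(genes) >= 2, all(genes %in% rownames(expr)))
  bins <- lapply(genes, function(g) equal_freq_bins(expr[g, ], n_bins))
  names(bins) <- genes
  cmb <- utils::combn(seq_along(genes), 2)
  mi <- vapply(seq_len(ncol(cmb)), function(c_) {
    mi_bits(bins[[cmb[1, c_]]], bins[[cmb[2, c_]]])
  }, numeric(1))
  out <- data.frame(
    gene_i = genes[cmb[1, ]], gene_j = genes[cmb[2, ]], mi = mi,
    stringsAsFactors = FALSE
  )
  attr(out, "mean") <- mean(mi)
  attr(out, "median") <- median(mi)
  class(out) <- c("mi_table", "data.frame")
  out
}
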