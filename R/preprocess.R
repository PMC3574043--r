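# Differential-expression prefiltering and leakage-free fold construction.
# The filtering track reduces a genome-scale matrix to a candidate pool:
# Welch t-test per gene, Benjamini-Hochberg FDR cutoff, then fold-change
# ranking truncated to the top genes.

#' Aggregate probe-level rows to gene symbols
#'
#' Collapses all probes mapping to the same gene symbol by their arithmetic
#' mean, the standard summarisation after array preprocessing. Unmapped
#' probes (absent from the mapping, or mapped to `NA`/empty symbols) are
#' dropped and counted.
#'
#' @param probe_matrix Numeric matrix, probes x samples, with probe IDs as
#'   row names.
#' @param mapping Data frame with columns `probe_id` and `gene_symbol`.
#' @return Numeric matrix, genes x samples, one row per symbol (sorted);
#'   attribute `n_dropped` holds the number of unmapped probes.
#' @export
aggregate_probes <- function(probe_matrix, mapping) {
  stopifnot(is.matrix(probe_matrix), !is.null(rownames(probe_matrix)))
  if (!all(c("probe_id", "gene_symbol") %in% names(mapping)) ||
    nrow(mapping) == 0L) {
    stop("'mapping' must be a non-empty data frame with probe_id and gene_symbol")
  }
  sym <- mapping$gene_symbol[match(rownames(probe_matrix), mapping$probe_id)]
  sym[!is.na(sym) & !nzchar(sym)] <- NA
  keep <- !is.na(sym)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " unmapped probe(s) dropped during aggregation")
  }
  if (!any(keep)) stop("no probe maps to a gene symbol")
  m <- probe_matrix[keep, , drop = FALSE]
  g <- sym[keep]
  out <- rowsum(m, group = g) / as.vector(table(g)[sort(unique(g))])
  out <- out[order(rownames(out)), , drop = FALSE]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Welch t-test filter with FDR control
#'
#' Per-gene two-sided Welch t-test (unequal variances) between the two
#' classes, Benjamini-Hochberg q-values, and a retention flag at the given
#' FDR cutoff. The fold change is the difference of class means on the log
#' scale (first factor level minus second). Genes whose standard error is
#' zero (no variance in either class) get `p = 1` rather than an error, so
#' degenerate inputs pass through the pipeline.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param labels Two-level factor (or a sample-annotation data frame with
#'   `sample_id` and `class_label` columns) aligned to the columns.
#' @param fdr_cutoff Retain genes with q-value at or below this cutoff.
#' @return A `filter_result` data frame: `gene`, `t`, `df`, `p`, `q`,
#'   `fold_change`, `retained`.
#' @export
welch_fdr_filter <- function(expr, labels, fdr_cutoff = 0.1) {
  if (is.data.frame(labels)) labels <- labels_for(expr, labels)
  labels <- check_expr_labels(expr, labels)
  i1 <- labels == levels(labels)[1]
  n1 <- sum(i1)
  n2 <- sum(!i1)
  if (n1 < 2 || n2 < 2) stop("need at least two samples per class")
  m1 <- rowMeans(expr[, i1, drop = FALSE])
  m2 <- rowMeans(expr[, !i1, drop = FALSE])
  v1 <- apply(expr[, i1, drop = FALSE], 1, var)
  v2 <- apply(expr[, !i1, drop = FALSE], 1, var)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
    se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))), NA_real_
  )
  p <- ifelse(se2 > 0, 2 * pt(abs(t_stat), df, lower.tail = FALSE), 1)
  n_degenerate <- sum(se2 == 0)
  if (n_degenerate > 0) {
    message(n_degenerate, " zero-variance gene(s) assigned p = 1")
  }
  q <- p.adjust(p, method = "BH")
  res <- data.frame(
    gene = rownames(expr), t = t_stat, df = df, p = p, q = q,
    fold_change = m1 - m2, retained = q <= fdr_cutoff,
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "fdr_cutoff") <- fdr_cutoff
  attr(res, "case_level") <- levels(labels)[1]
  class(res) <- c("filter_result", "data.frame")
  res
}

#' Rank the retained genes by fold change
#'
#' Sorts the genes retained by [welch_fdr_filter()] by fold change in
#' decreasing order and truncates to the top `top_k` candidate pool. The
#' default sorts by absolute fold change so that strongly down-regulated
#' genes rank as highly as up-regulated ones; `signed = TRUE` gives a plain
#' signed sort. Ties break by smaller q-value, then symbol order.
#'
#' @param filter_result Result of [welch_fdr_filter()].
#' @param expr Optional expression matrix to subset to the candidate pool.
#' @param top_k Pool size (all retained genes if fewer).
#' @param signed Sort by signed instead of absolute fold change.
#' @return A list of class `candidate_pool`: `genes` (ranked symbols),
#'   `table` (ranked `filter_result` rows with a `rank` column) and `expr`
#'   (reduced matrix in ranking order, if `expr` was supplied).
#' @export
rank_by_fold_change <- function(filter_result, expr = NULL, top_k = 1000,
                                signed = FALSE) {
  stopifnot(inherits(filter_result, "filter_result"))
  kept <- filter_result[filter_result$retained, , drop = FALSE]
  if (nrow(kept) == 0L) stop("no gene passed the FDR filter; nothing to rank")
  key <- if (signed) kept$fold_change else abs(kept$fold_change)
  ord <- order(-key, kept$q, kept$gene)
  kept <- kept[ord, , drop = FALSE]
  k <- min(top_k, nrow(kept))
  kept <- kept[seq_len(k), , drop = FALSE]
  kept$rank <- seq_len(k)
  rownames(kept) <- NULL
  out <- list(genes = kept$gene, table = kept)
  if (!is.null(expr)) out$expr <- expr[kept$gene, , drop = FALSE]
  structure(out, class = "candidate_pool")
}

#' @export
print.candidate_pool <- function(x, ...) {
  cat("Candidate gene pool:", length(x$genes), "genes\n")
  cat(
    " top genes:",
    paste(utils::head(x$genes, 5), collapse = ", "), "...\n"
  )
  invisible(x)
}

#' Subject-grouped stratified cross-validation folds
#'
#' Partitions samples into folds at the *subject* level, so no subject ever
#' straddles a training and a test set, while greedily balancing class
#' counts (per-fold subject counts per class differ by at most one) and
#' stratum proportions across folds.
#'
#' @param annotation Data frame with `sample_id`, `class_label`,
#'   `subject_id` and `stratum` columns.
#' @param n_folds Number of folds.
#' @param seed Integer seed for the subject shuffle.
#' @return An object of class `fold_plan`: list with `folds` (per fold,
#'   `train` and `test` sample-ID vectors), `assignment` (subject-to-fold
#'   table), `n_folds` and `seed`.
#' @export
make_grouped_folds <- function(annotation, n_folds = 3, seed = 1L) {
  stopifnot(all(c("sample_id", "class_label", "subject_id", "stratum")
  %in% names(annotation)))
  n_folds <- as.integer(n_folds)
  subj <- unique(annotation[, c("subject_id", "class_label")])
  if (anyDuplicated(subj$subject_id)) {
    stop("a subject carries more than one class label")
  }
  per_class <- table(subj$class_label)
  if (length(per_class) != 2L) stop("need exactly two classes")
  if (any(per_class < n_folds)) {
    stop("need at least n_folds subjects in every class")
  }

  set.seed(as.integer(seed))
  fold_of <- setNames(integer(nrow(subj)), subj$subject_id)
  # per-fold bookkeeping for the greedy assignment
  class_count <- matrix(0L, n_folds, 2,
    dimnames = list(NULL, names(per_class))
  )
  strata <- sort(unique(annotation$stratum))
  stratum_count <- matrix(0L, n_folds, length(strata),
    dimnames = list(NULL, strata)
  )
  n_samples_subj <- table(annotation$subject_id)

  for (lv in names(per_class)) {
    ids <- subj$subject_id[subj$class_label == lv]
    ids <- ids[sample.int(length(ids))]
    for (s in ids) {
      s_strata <- table(factor(
        annotation$stratum[annotation$subject_id == s],
        levels = strata
      ))
      cand <- which(class_count[, lv] == min(class_count[, lv]))
      if (length(cand) > 1L) {
        # among class-balanced folds, prefer the one keeping stratum
        # sample counts most even
        imbalance <- vapply(cand, function(f) {
          sum((stratum_count[f, ] + s_strata)^2)
        }, numeric(1))
        cand <- cand[imbalance == min(imbalance)]
      }
      f <- cand[1]
      fold_of[s] <- f
      class_count[f, lv] <- class_count[f, lv] + 1L
      stratum_count[f, ] <- stratum_count[f, ] + s_strata
    }
  }

  folds <- lapply(seq_len(n_folds), function(f) {
    test_subj <- names(fold_of)[fold_of == f]
    te <- annotation$subject_id %in% test_subj
    list(
      train = annotation$sample_id[!te],
      test = annotation$sample_id[te]
    )
  })
  plan <- structure(list(
    folds = folds,
    assignment = data.frame(
      subject_id = names(fold_of), fold = unname(fold_of),
      stringsAsFactors = FALSE
    ),
    n_folds = n_folds, seed = as.integer(seed)
  ), class = "fold_plan")

  # invariant: both classes present on both sides of every fold
  for (f in folds) {
    for (side in f) {
      cl <- annotation$class_label[annotation$sample_id %in% side]
      if (length(unique(cl)) < 2L) {
        stop("a fold lost one class entirely; use fewer folds")
      }
    }
  }
  plan
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("Grouped cross-validation plan:", x$n_folds, "folds\n")
  for (f in seq_len(x$n_folds)) {
    cat(
      "  fold", f, "-", length(x$folds[[f]]$train), "train /",
      length(x$folds[[f]]$test), "test samples\n"
    )
  }
  invisible(x)
}
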