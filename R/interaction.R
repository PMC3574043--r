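# Joint-occurrence analysis of gene pairs across many GA/SVM final sets.
# For genes i and j with single occurrence counts k_i, k_j over n runs,
# the expected joint count under independence is k'_ij = k_i * k_j / n;
# the strength of over-/under-representation is
# importance_jo = log(k_ij / k'_ij), and significance comes from a 2x2
# chi-square test (1 df) with BH-FDR correction, restricted to pairs with
# expected count > 5.

#' Count single and joint occurrences over gene sets
#'
#' `k_i` is the number of sets containing gene i; `k_ij` the number
#' containing both i and j. A set of n genes contributes n(n-1)/2 pairs.
#'
#' @param gene_sets List of character vectors (unique genes within a set).
#' @return List of class `occurrence_counts`: `single` (named integer
#'   vector), `pairs` (data frame `gene_i`, `gene_j`, `k_ij` with
#'   `gene_i < gene_j`), `n_sets`.
#' @export
count_occurrences <- function(gene_sets) {
  stopifnot(is.list(gene_sets), length(gene_sets) >= 1)
  gene_sets <- lapply(gene_sets, function(s) sort(unique(as.character(s))))
  single <- table(unlist(gene_sets))
  keys <- unlist(lapply(gene_sets, function(s) {
    if (length(s) < 2L) {
      return(character(0))
    }
    cmb <- utils::combn(s, 2)
    paste(cmb[1, ], cmb[2, ], sep = "\r")
  }))
  pairs <- if (length(keys) > 0) {
    tab <- table(keys)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    data.frame(
      gene_i = vapply(parts, `[`, "", 1),
      gene_j = vapply(parts, `[`, "", 2),
      k_ij = as.integer(tab), stringsAsFactors = FALSE, row.names = NULL
    )
  } else {
    data.frame(
      gene_i = character(0), gene_j = character(0),
      k_ij = integer(0), stringsAsFactors = FALSE
    )
  }
  structure(list(
    single = setNames(as.integer(single), names(single)),
    pairs = pairs, n_sets = length(gene_sets)
  ), class = "occurrence_counts")
}

# chi-square statistic of the 2x2 presence/absence table, no continuity
# correction; vectorised over pairs
chi2_2x2 <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  ifelse(denom > 0, n * (a * d - b * c_)^2 / denom, 0)
}

#' Joint-occurrence statistics for gene pairs
#'
#' Builds the pair table with expected counts, chi-square significance and
#' the over-/under-representation score. All pairs whose expected count
#' exceeds `min_expected` are tested, *including* pairs never observed
#' together (`k_ij = 0`, the strongest under-representation, reported with
#' an `importance_jo` of `-Inf`); the expectation filter is applied before
#' the FDR correction. Observed pairs failing the filter are reported with
#' `valid = FALSE` and no q-value.
#'
#' @param counts An `occurrence_counts` object (or a list of gene sets).
#' @param n_runs Number of selector runs the counts come from; defaults to
#'   `counts$n_sets`.
#' @param fdr_cutoff Significance cutoff on the BH q-value.
#' @param min_expected Expectation filter: pairs enter the test only when
#'   `expected > min_expected`.
#' @return A `pair_stats` data frame: `gene_i`, `gene_j`, `k_i`, `k_j`,
#'   `k_ij`, `expected`, `chi2`, `p`, `q`, `importance_jo`, `direction`
#'   (`"over"`/`"under"`), `valid`, `significant`.
#' @export
pair_statistics <- function(counts, n_runs = NULL, fdr_cutoff = 0.05,
                            min_expected = 5) {
  if (!inherits(counts, "occurrence_counts")) {
    counts <- count_occurrences(counts)
  }
  if (is.null(n_runs)) n_runs <- counts$n_sets
  single <- counts$single

  # candidate pairs: all observed pairs, plus every unobserved pair whose
  # expected count would pass the filter (those are under-represented)
  obs <- counts$pairs
  thresh <- min_expected * n_runs
  hi <- names(single)[order(single, decreasing = TRUE)]
  hi <- hi[single[hi] * single[hi][1] > thresh]
  extra <- NULL
  if (length(hi) >= 2L) {
    cmb <- utils::combn(sort(hi), 2)
    cand <- data.frame(
      gene_i = cmb[1, ], gene_j = cmb[2, ],
      stringsAsFactors = FALSE
    )
    cand <- cand[single[cand$gene_i] * single[cand$gene_j] > thresh, ,
      drop = FALSE
    ]
    key_obs <- paste(obs$gene_i, obs$gene_j, sep = "\r")
    key_cand <- paste(cand$gene_i, cand$gene_j, sep = "\r")
    extra <- cand[!key_cand %in% key_obs, , drop = FALSE]
    if (nrow(extra) > 0) extra$k_ij <- 0L
  }
  tab <- rbind(obs, extra)
  if (nrow(tab) == 0L) {
    warning("no gene pair to test")
  }
  tab$k_i <- as.numeric(single[tab$gene_i])
  tab$k_j <- as.numeric(single[tab$gene_j])
  tab$expected <- tab$k_i * tab$k_j / n_runs
  tab$valid <- tab$expected > min_expected

  a <- tab$k_ij
  b <- tab$k_i - tab$k_ij
  c_ <- tab$k_j - tab$k_ij
  d <- n_runs - tab$k_i - tab$k_j + tab$k_ij
  tab$chi2 <- chi2_2x2(a, b, c_, d)
  tab$p <- pchisq(tab$chi2, df = 1, lower.tail = FALSE)
  tab$q <- NA_real_
  tab$q[tab$valid] <- p.adjust(tab$p[tab$valid], method = "BH")
  tab$importance_jo <- suppressWarnings(log(tab$k_ij / tab$expected))
  tab$direction <- ifelse(tab$k_ij < tab$expected, "under", "over")
  tab$significant <- tab$valid & !is.na(tab$q) & tab$q <= fdr_cutoff
  tab <- tab[, c(
    "gene_i", "gene_j", "k_i", "k_j", "k_ij", "expected", "chi2",
    "p", "q", "importance_jo", "direction", "valid", "significant"
  )]
  rownames(tab) <- NULL
  attr(tab, "n_runs") <- n_runs
  attr(tab, "fdr_cutoff") <- fdr_cutoff
  attr(tab, "min_expected") <- min_expected
  class(tab) <- c("pair_stats", "data.frame")
  tab
}

#' SVM accuracy of a gene pair and its gain over the single genes
#'
#' Ten-fold cross-validated Gaussian-SVM accuracy of gene i alone, gene j
#' alone, and the pair, over the *same* frozen stratified fold split so
#' that the gains are not split-noise artifacts:
#' `gain_mean = acc_ij - (acc_i + acc_j) / 2` and
#' `gain_min = acc_ij - max(acc_i, acc_j)`.
#'
#' @param expr Expression matrix, genes x samples.
#' @param labels Two-level class factor (or annotation data frame).
#' @param gene_i,gene_j Gene symbols (rows of `expr`).
#' @param n_folds Cross-validation folds.
#' @param seed Optional integer seed for the fold draw.
#' @return List of class `pair_accuracy`: `acc_i`, `acc_j`, `acc_ij`,
#'   `gain_mean`, `gain_min`.
#' @export
pair_svm_accuracy <- function(expr, labels, gene_i, gene_j, n_folds = 10,
                              seed = NULL) {
  if (is.data.frame(labels)) labels <- labels_for(expr, labels)
  labels <- check_expr_labels(expr, labels)
  stopifnot(gene_i %in% rownames(expr), gene_j %in% rownames(expr))
  if (!is.null(seed)) set.seed(as.integer(seed))
  fold <- stratified_fold_ids(labels, n_folds)
  x <- t(expr[c(gene_i, gene_j), , drop = FALSE])
  acc_i <- svm_cv_accuracy(x[, 1, drop = FALSE], labels, fold, pool = TRUE)
  acc_j <- svm_cv_accuracy(x[, 2, drop = FALSE], labels, fold, pool = TRUE)
  acc_ij <- svm_cv_accuracy(x, labels, fold, pool = TRUE)
  structure(list(
    gene_i = gene_i, gene_j = gene_j,
    acc_i = acc_i, acc_j = acc_j, acc_ij = acc_ij,
    gain_mean = acc_ij - (acc_i + acc_j) / 2,
    gain_min = acc_ij - max(acc_i, acc_j)
  ), class = "pair_accuracy")
}

#' @export
print.pair_accuracy <- function(x, ...) {
  cat(sprintf(
    "%s/%s: acc %.3f (single %.3f / %.3f), gain mean %.3f, gain min %.3f\n",
    x$gene_i, x$gene_j, x$acc_ij, x$acc_i, x$acc_j, x$gain_mean, x$gain_min
  ))
  invisible(x)
}

#' Accuracy profile of the accumulated top pairs
#'
#' Sorts the significant pairs by `importance_jo` (descending for
#' over-represented, ascending for under-represented, with never-observed
#' `-Inf` pairs placed last) and reports running means of the pair
#' accuracy, mean gain and minimal gain at each accumulation size, per
#' direction. Sizes beyond the number of available pairs are dropped.
#'
#' @param pairstats A `pair_stats` data frame.
#' @param accuracies Data frame with `gene_i`, `gene_j`, `acc_ij`,
#'   `gain_mean`, `gain_min` for (at least) the significant pairs, e.g.
#'   rows built with [pair_svm_accuracy()].
#' @param sizes Accumulation sizes.
#' @return Data frame: `direction`, `size`, `mean_acc`, `mean_gain_mean`,
#'   `mean_gain_min`.
#' @export
accumulate_top_pairs <- function(pairstats, accuracies,
                                 sizes = seq(3, 75, by = 3)) {
  stopifnot(inherits(pairstats, "pair_stats"))
  sig <- pairstats[pairstats$significant, , drop = FALSE]
  if (nrow(sig) == 0L) {
    warning("no significant pair; empty accumulation table")
    return(data.frame(
      direction = character(0), size = integer(0), mean_acc = numeric(0),
      mean_gain_mean = numeric(0), mean_gain_min = numeric(0)
    ))
  }
  key <- function(d) paste(d$gene_i, d$gene_j, sep = "\r")
  idx <- match(key(sig), key(accuracies))
  if (anyNA(idx)) stop("accuracies missing for some significant pairs")
  sig <- cbind(sig, accuracies[idx, c("acc_ij", "gain_mean", "gain_min")])

  out <- NULL
  for (dir in c("over", "under")) {
    d <- sig[sig$direction == dir, , drop = FALSE]
    if (nrow(d) == 0L) next
    if (dir == "over") {
      d <- d[order(-d$importance_jo, d$gene_i, d$gene_j), , drop = FALSE]
    } else {
      # most under-represented first; -Inf sentinels (never co-occurring)
      # go last
      inf <- is.infinite(d$importance_jo)
      fin <- d[!inf, , drop = FALSE]
      fin <- fin[order(fin$importance_jo, fin$gene_i, fin$gene_j), ,
        drop = FALSE
      ]
      d <- rbind(fin, d[inf, , drop = FALSE])
    }
    for (s in sizes[sizes <= nrow(d)]) {
      out <- rbind(out, data.frame(
        direction = dir, size = s,
        mean_acc = mean(d$acc_ij[seq_len(s)]),
        mean_gain_mean = mean(d$gain_mean[seq_len(s)]),
        mean_gain_min = mean(d$gain_min[seq_len(s)]),
        stringsAsFactors = FALSE
      ))
    }
  }
  rownames(out) <- NULL
  out
}

#' Compare accuracy gains of over- vs under-represented pairs
#'
#' Two-sided Welch two-sample t-test between the two gain vectors. When
#' both groups are constant the p-value is defined as 1 for equal means
#' and ~0 otherwise instead of erroring.
#'
#' @param over_gains,under_gains Numeric vectors (at least 2 values each).
#' @return The two-sided p-value.
#' @export
compare_gain_distributions <- function(over_gains, under_gains) {
  stopifnot(length(over_gains) >= 2, length(under_gains) >= 2)
  if (sd(over_gains) == 0 && sd(under_gains) == 0) {
    return(if (mean(over_gains) == mean(under_gains)) 1 else 0)
  }
  t.test(over_gains, under_gains, var.equal = FALSE)$p.value
}
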