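# Baseline single-gene importance rankers and rank aggregation. Each
# ranker emits a ranked list: a data frame (gene, score, rank) ordered so
# that a higher score means more important, ties broken by symbol order.

ranked_list <- function(genes, scores, method, decreasing = TRUE) {
  ord <- order(if (decreasing) -scores else scores, genes)
  out <- data.frame(
    gene = genes[ord], score = scores[ord], rank = seq_along(genes),
    stringsAsFactors = FALSE
  )
  attr(out, "method") <- method
  class(out) <- c("ranked_list", "data.frame")
  out
}

# entropy in bits of a class count vector
entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# class entropy of a label vector
label_entropy <- function(y) entropy_bits(table(y))

# Best binary cut of x w.r.t. class labels y: evaluates every midpoint
# between adjacent distinct sorted values and returns the cut with maximal
# information gain together with the MDL acceptance decision
# (Fayyad-Irani criterion).
best_mdl_cut <- function(x, y) {
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  n <- length(xs)
  distinct <- which(diff(xs) > 0)
  if (length(distinct) == 0L) {
    return(NULL)
  }
  base_ent <- entropy_bits(table(ys))
  k <- length(unique(ys))
  # cumulative class counts left of each candidate split
  lev <- sort(unique(ys))
  cum <- sapply(lev, function(lv) cumsum(ys == lv))
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = n)
  total <- cum[n, ]
  best <- NULL
  for (i in distinct) {
    left <- cum[i, ]
    right <- total - left
    e1 <- entropy_bits(left)
    e2 <- entropy_bits(right)
    cond <- (i * e1 + (n - i) * e2) / n
    gain <- base_ent - cond
    if (is.null(best) || gain > best$gain + 1e-12) {
      best <- list(
        i = i, cut = (xs[i] + xs[i + 1]) / 2, gain = gain,
        e1 = e1, e2 = e2,
        k1 = sum(left > 0), k2 = sum(right > 0)
      )
    }
  }
  # MDL acceptance: gain must beat the coding cost of the split
  delta <- log2(3^k - 2) - (k * base_ent - best$k1 * best$e1 -
    best$k2 * best$e2)
  best$accepted <- best$gain > (log2(n - 1) + delta) / n
  best
}

#' Supervised MDL cut points for one gene
#'
#' Fayyad-Irani recursive binary discretization: at each node the cut
#' maximising information gain over all midpoints between adjacent
#' distinct values is accepted when the gain exceeds the MDL coding cost
#' of the split, and the two halves are split recursively.
#'
#' @param x Numeric expression values.
#' @param y Class labels.
#' @return Sorted numeric vector of accepted cut points (possibly empty).
#' @export
mdl_cut_points <- function(x, y) {
  recurse <- function(x, y) {
    if (length(x) < 2L || length(unique(y)) < 2L) {
      return(numeric(0))
    }
    best <- best_mdl_cut(x, y)
    if (is.null(best) || !best$accepted) {
      return(numeric(0))
    }
    left <- x <= best$cut
    c(
      recurse(x[left], y[left]), best$cut,
      recurse(x[!left], y[!left])
    )
  }
  sort(recurse(x, y))
}

#' Information-gain ranking with MDL discretization
#'
#' Scores each gene by the reduction in class entropy after discretizing
#' its expression by supervised MDL cut-point search:
#' `IG = H(class) - H(class | bins)`, in bits. Genes with no accepted cut
#' (including constant genes) score 0. The score depends only on the value
#' order, so it is invariant under monotone transformations, and the
#' method is fully deterministic.
#'
#' @param expr Expression matrix, genes x samples.
#' @param labels Two-level class factor (or annotation data frame).
#' @param method `"mdl"` (default) or `"equalfreq"` for a fixed
#'   equal-frequency binning fallback.
#' @param n_bins Bin count for the equal-frequency fallback.
#' @return A `ranked_list` data frame (`gene`, `score`, `rank`).
#' @export
information_gain_rank <- function(expr, labels, method = c("mdl", "equalfreq"),
                                  n_bins = 10) {
  if (is.data.frame(labels)) labels <- labels_for(expr, labels)
  labels <- check_expr_labels(expr, labels)
  method <- match.arg(method)
  h_class <- label_entropy(labels)
  scores <- apply(expr, 1, function(x) {
    if (method == "mdl") {
      cuts <- mdl_cut_points(x, labels)
      if (length(cuts) == 0L) {
        return(0)
      }
      bins <- findInterval(x, cuts)
    } else {
      bins <- equal_freq_bins(x, n_bins)
    }
    tab <- table(bins, labels)
    cond <- sum(rowSums(tab) / length(labels) *
      apply(tab, 1, entropy_bits))
    h_class - cond
  })
  ranked_list(rownames(expr), unname(scores), "information_gain")
}

#' Random-forest permutation importance ranking
#'
#' Mean decrease accuracy: per tree, the out-of-bag samples are classified
#' before and after permuting one gene's values, and the drop in correct
#' classifications (per OOB sample) is averaged over all trees; the score
#' is additionally averaged over `n_repeats` independently grown forests
#' to reduce its variance. Trees are grown to purity with
#' `ceiling(sqrt(m))` candidate genes per split.
#'
#' @param expr Expression matrix, genes x samples.
#' @param labels Two-level class factor (or annotation data frame).
#' @param n_trees Trees per forest.
#' @param n_repeats Forests averaged.
#' @param seed Optional integer seed.
#' @return A `ranked_list` data frame (`gene`, `score`, `rank`).
#' @export
rf_importance_rank <- function(expr, labels, n_trees = 1000, n_repeats = 3,
                               seed = NULL) {
  if (is.data.frame(labels)) labels <- labels_for(expr, labels)
  labels <- check_expr_labels(expr, labels)
  if (!is.null(seed)) set.seed(as.integer(seed))
  x <- t(expr)
  imp <- matrix(0, nrow(expr), n_repeats)
  for (r in seq_len(n_repeats)) {
    rf <- randomForest::randomForest(x, labels,
      ntree = n_trees, mtry = ceiling(sqrt(nrow(expr))),
      nodesize = 1, importance = TRUE
    )
    imp[, r] <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  }
  ranked_list(rownames(expr), rowMeans(imp), "random_forest")
}

#' Frequency ranking over gene sets
#'
#' Scores each gene by the number of sets it occurs in (each set counts a
#' gene at most once), the wrapper's importance score over repeated runs.
#'
#' @param gene_sets List of character vectors.
#' @return A `ranked_list` data frame (`gene`, `score`, `rank`).
#' @export
frequency_rank <- function(gene_sets) {
  stopifnot(is.list(gene_sets), length(gene_sets) >= 1)
  counts <- table(unlist(lapply(gene_sets, unique)))
  ranked_list(names(counts), as.numeric(counts), "ga_frequency")
}

#' Combine rankings by average rank
#'
#' Aggregates two or more ranked lists by averaging each gene's rank
#' position (not its score) across methods; a gene missing from one list
#' is assigned that list's length + 1. The output is ordered by ascending
#' average rank (its `score` column *is* the average rank, so smaller is
#' better here), ties broken by symbol.
#'
#' @param lists List of `ranked_list` data frames.
#' @param top_n Truncate to this many genes.
#' @return A `ranked_list` data frame with `score` = average rank.
#' @export
combine_ranks <- function(lists, top_n = 20) {
  stopifnot(is.list(lists), length(lists) >= 2)
  if (any(vapply(lists, nrow, 1L) == 0L)) stop("empty ranked list")
  universe <- sort(unique(unlist(lapply(lists, `[[`, "gene"))))
  ranks <- sapply(lists, function(l) {
    r <- l$rank[match(universe, l$gene)]
    r[is.na(r)] <- nrow(l) + 1L
    r
  })
  avg <- rowMeans(ranks)
  out <- ranked_list(universe, avg, "combined_rank", decreasing = FALSE)
  out[seq_len(min(top_n, nrow(out))), , drop = FALSE]
}
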