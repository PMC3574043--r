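# Hypergeometric over-representation analysis of selected gene sets
# against reference lists, with a three-state call per cell:
# "significant" (upper-tail p < 0.05), "enriched" (overlap above its
# expectation but not significant), "not_enriched" otherwise.

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric probability of observing at least the actual
#' overlap between a selected gene set and a reference list within a gene
#' universe. Reference genes outside the universe are dropped (with a
#' message) before testing.
#'
#' @param selected Character vector, a subset of `universe`.
#' @param reference Character vector of reference genes.
#' @param universe Character vector, the gene universe.
#' @param alpha Significance threshold for the `"significant"` status.
#' @return List of class `ora_result`: `n_selected`, `n_reference` (in
#'   universe), `n_universe`, `overlap`, `expected`, `p`, `status`.
#' @export
hypergeometric_ora <- function(selected, reference, universe, alpha = 0.05) {
  universe <- unique(universe)
  selected <- unique(selected)
  if (length(universe) == 0L) stop("empty universe")
  if (length(selected) == 0L) stop("empty selected set")
  if (!all(selected %in% universe)) {
    stop("selected genes must be a subset of the universe")
  }
  dropped <- sum(!unique(reference) %in% universe)
  if (dropped > 0) {
    message(dropped, " reference gene(s) outside the universe dropped")
  }
  reference <- intersect(unique(reference), universe)
  overlap <- length(intersect(selected, reference))
  n_u <- length(universe)
  n_r <- length(reference)
  n_s <- length(selected)
  p <- phyper(overlap - 1, n_r, n_u - n_r, n_s, lower.tail = FALSE)
  expected <- n_s * n_r / n_u
  status <- if (p < alpha) {
    "significant"
  } else if (overlap > expected) {
    "enriched"
  } else {
    "not_enriched"
  }
  structure(list(
    n_selected = n_s, n_reference = n_r, n_universe = n_u,
    overlap = overlap, expected = expected, p = p, status = status
  ), class = "ora_result")
}

#' @export
print.ora_result <- function(x, ...) {
  cat(sprintf(
    "ORA: overlap %d (expected %.2f) of %d selected vs %d reference in %d genes; p = %.3g [%s]\n",
    x$overlap, x$expected, x$n_selected, x$n_reference, x$n_universe,
    x$p, x$status
  ))
  invisible(x)
}

#' Enrichment sweep over increasing list sizes
#'
#' Tests the top `size` genes of a ranking against every reference list
#' for a grid of sizes, mirroring the usual heat-grid presentation.
#' P-values are reported raw per cell (no correction across the grid).
#'
#' @param ranking A `ranked_list` data frame.
#' @param reference_lists Named list of character vectors.
#' @param universe Gene universe.
#' @param sizes Top-list sizes; sizes beyond the ranking length are
#'   skipped with a warning.
#' @param alpha Significance threshold.
#' @return List with `results` (data frame `list`, `size`, `overlap`,
#'   `expected`, `p`, `status`) and `status_matrix` (lists x sizes).
#' @export
enrichment_sweep <- function(ranking, reference_lists, universe,
                             sizes = seq(40, 200, by = 20), alpha = 0.05) {
  stopifnot(is.data.frame(ranking), length(reference_lists) >= 1)
  if (is.null(names(reference_lists))) {
    names(reference_lists) <- paste0("list_", seq_along(reference_lists))
  }
  ok <- sizes <= nrow(ranking)
  if (!all(ok)) {
    warning("sizes beyond the ranking length skipped: ",
      paste(sizes[!ok], collapse = ", "))
    sizes <- sizes[ok]
  }
  if (length(sizes) == 0L) {
    return(list(
      results = data.frame(
        list = character(0), size = integer(0), overlap = integer(0),
        expected = numeric(0), p = numeric(0), status = character(0)
      ),
      status_matrix = matrix(character(0),
        nrow = length(reference_lists), ncol = 0,
        dimnames = list(names(reference_lists), NULL)
      )
    ))
  }
  res <- NULL
  for (nm in names(reference_lists)) {
    for (s in sizes) {
      r <- suppressMessages(hypergeometric_ora(
        ranking$gene[seq_len(s)], reference_lists[[nm]], universe, alpha
      ))
      res <- rbind(res, data.frame(
        list = nm, size = s, overlap = r$overlap, expected = r$expected,
        p = r$p, status = r$status, stringsAsFactors = FALSE
      ))
    }
  }
  rownames(res) <- NULL
  mat <- matrix(res$status,
    nrow = length(reference_lists), byrow = TRUE,
    dimnames = list(names(reference_lists), sizes)
  )
  list(results = res, status_matrix = mat)
}
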