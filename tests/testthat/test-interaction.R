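# Joint-occurrence statistics for gene pairs across selector runs.

test_that("occurrence counting matches hand counts and the incidence oracle", {
  cnt <- count_occurrences(list(c("a", "b", "c"), c("a", "b"), c("b", "c")))
  expect_equal(cnt$single[c("a", "b", "c")], c(a = 2L, b = 3L, c = 2L))
  k <- function(i, j) {
    row <- cnt$pairs$gene_i == i & cnt$pairs$gene_j == j
    if (any(row)) cnt$pairs$k_ij[row] else 0L
  }
  expect_equal(k("a", "b"), 2L)
  expect_equal(k("a", "c"), 1L)
  expect_equal(k("b", "c"), 2L)

  # one 15-gene set contributes 15 * 14 / 2 pairs
  cnt15 <- count_occurrences(list(sprintf("g%02d", 1:15)))
  expect_equal(nrow(cnt15$pairs), 105L)

  # incidence-matrix cross-product oracle on random sets
  set.seed(21)
  genes <- sprintf("g%02d", 1:30)
  sets <- replicate(400, sample(genes, sample(2:10, 1)), simplify = FALSE)
  cnt2 <- count_occurrences(sets)
  inc <- sapply(genes, function(g) vapply(sets, function(s) g %in% s, TRUE))
  xp <- crossprod(inc)
  expect_equal(unname(cnt2$single[genes]), unname(diag(xp)))
  for (r in sample(nrow(cnt2$pairs), 50)) {
    expect_equal(
      cnt2$pairs$k_ij[r],
      unname(xp[cnt2$pairs$gene_i[r], cnt2$pairs$gene_j[r]])
    )
  }
  # conservation: sums over singles and pairs match the set sizes
  sizes <- lengths(sets)
  expect_equal(sum(cnt2$single), sum(sizes))
  expect_equal(sum(cnt2$pairs$k_ij), sum(sizes * (sizes - 1) / 2))
})

test_that("expected counts, importance and chi-square follow the formulas", {
  counts <- structure(list(
    single = c(a = 600L, b = 500L, c = 10L),
    pairs = data.frame(
      gene_i = c("a", "a"), gene_j = c("b", "c"),
      k_ij = c(100L, 2L), stringsAsFactors = FALSE
    ),
    n_sets = 3000L
  ), class = "occurrence_counts")
  st <- pair_statistics(counts, n_runs = 3000)
  ab <- st[st$gene_i == "a" & st$gene_j == "b", ]
  expect_equal(ab$expected, 600 * 500 / 3000) # = 100
  # observed equals expected: no over/under-representation at all
  expect_equal(ab$importance_jo, 0)
  expect_equal(ab$chi2, 0, tolerance = 1e-12)
  # low-expectation pair is excluded from testing but still reported
  ac <- st[st$gene_i == "a" & st$gene_j == "c", ]
  expect_false(ac$valid)
  expect_true(is.na(ac$q))
})

test_that("chi-square p-values match chisq.test without continuity correction", {
  set.seed(22)
  for (i in 1:30) {
    n <- 500L
    k_i <- sample(50:300, 1)
    k_j <- sample(50:300, 1)
    k_ij <- sample(seq(max(1, k_i + k_j - n), min(k_i, k_j)), 1)
    counts <- structure(list(
      single = setNames(c(k_i, k_j), c("x", "y")),
      pairs = data.frame(
        gene_i = "x", gene_j = "y", k_ij = k_ij,
        stringsAsFactors = FALSE
      ),
      n_sets = n
    ), class = "occurrence_counts")
    st <- pair_statistics(counts, n_runs = n, min_expected = 0)
    tab <- matrix(c(
      k_ij, k_i - k_ij,
      k_j - k_ij, n - k_i - k_j + k_ij
    ), 2)
    oracle <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(st$p[1], oracle$p.value, tolerance = 1e-9)
    expect_equal(st$chi2[1], unname(oracle$statistic), tolerance = 1e-9)
  }
})

test_that("pairs never observed together get the -Inf sentinel", {
  sets <- c(
    replicate(40, c("a", "x"), simplify = FALSE),
    replicate(40, c("b", "y"), simplify = FALSE)
  )
  st <- pair_statistics(count_occurrences(sets), n_runs = 80)
  ab <- st[st$gene_i == "a" & st$gene_j == "b", ]
  expect_equal(nrow(ab), 1L) # enumerated although never co-occurring
  expect_true(is.infinite(ab$importance_jo) && ab$importance_jo < 0)
  expect_identical(ab$direction, "under")
})

test_that("a duplicated gene adds no accuracy; a synergistic partner does", {
  # exact duplicate: the pair cannot beat the better single gene
  set.seed(23)
  n <- 60
  y <- toy_labels(n)
  g <- ifelse(y == "affected", 1, -1) + rnorm(n)
  expr <- rbind(gi = g, gj = g, noise = rnorm(n))
  colnames(expr) <- sprintf("s%02d", 1:n)
  pa <- pair_svm_accuracy(expr, y, "gi", "gj", seed = 1)
  expect_lte(pa$gain_min, 0.01)
  expect_lte(pa$gain_min, pa$gain_mean)

  # class = which of the two genes is larger: strong joint gain
  d <- synergy_pair_data(n = 80, seed = 2)
  pa2 <- pair_svm_accuracy(d$expr, d$labels, "synA", "synB", seed = 1)
  expect_gte(pa2$gain_min, 0.1)
  expect_lte(pa2$gain_min, pa2$gain_mean)

  # the algebraic relation holds on arbitrary random inputs
  for (i in 1:5) {
    e <- matrix(rnorm(2 * 40), 2, dimnames = list(c("u", "v"), NULL))
    colnames(e) <- sprintf("s%02d", 1:40)
    p <- pair_svm_accuracy(e, toy_labels(40), "u", "v", seed = i)
    expect_lte(p$gain_min, p$gain_mean + 1e-12)
    expect_true(all(c(p$acc_i, p$acc_j, p$acc_ij) >= 0 &
      c(p$acc_i, p$acc_j, p$acc_ij) <= 1))
  }
})

test_that("accumulation tables are running means in importance order", {
  st <- structure(
    data.frame(
      gene_i = sprintf("a%d", 1:8), gene_j = sprintf("b%d", 1:8),
      k_i = 50, k_j = 50, k_ij = c(40, 35, 30, 28, 5, 4, 3, 2),
      expected = 20, chi2 = 30, p = 1e-7, q = 1e-6,
      importance_jo = log(c(40, 35, 30, 28, 5, 4, 3, 2) / 20),
      direction = rep(c("over", "under"), each = 4),
      valid = TRUE, significant = TRUE, stringsAsFactors = FALSE
    ),
    class = c("pair_stats", "data.frame"), n_runs = 125
  )
  acc <- data.frame(
    gene_i = st$gene_i, gene_j = st$gene_j,
    acc_ij = seq(0.9, 0.2, by = -0.1),
    gain_mean = seq(0.8, 0.1, by = -0.1),
    gain_min = seq(0.4, 0.05, by = -0.05),
    stringsAsFactors = FALSE
  )
  out <- accumulate_top_pairs(st, acc, sizes = c(2, 4, 6))
  over2 <- out[out$direction == "over" & out$size == 2, ]
  # over-represented sorted by descending importance: pairs 1, 2 first
  expect_equal(over2$mean_gain_mean, mean(c(0.8, 0.7)))
  under4 <- out[out$direction == "under" & out$size == 4, ]
  # under-represented sorted ascending: pairs 8, 7, 6, 5
  expect_equal(under4$mean_acc, mean(c(0.2, 0.3, 0.4, 0.5)))
  # sizes beyond the available pairs are dropped
  expect_false(any(out$size == 6))

  # a single significant pair gives a single row with its own values
  st1 <- st[1, , drop = FALSE]
  class(st1) <- c("pair_stats", "data.frame")
  out1 <- accumulate_top_pairs(st1, acc, sizes = c(1, 3))
  expect_equal(nrow(out1), 1L)
  expect_equal(out1$mean_acc, 0.9)
  # no significant pairs: empty table with a warning
  st0 <- st
  st0$significant <- FALSE
  class(st0) <- c("pair_stats", "data.frame")
  expect_warning(out0 <- accumulate_top_pairs(st0, acc), "no significant")
  expect_equal(nrow(out0), 0L)
})

test_that("gain comparison equals the textbook Welch test and is symmetric", {
  over <- c(10, 11, 12)
  under <- c(0, 1, 2)
  p <- compare_gain_distributions(over, under)
  # textbook Welch computation
  s2o <- var(over) / 3
  s2u <- var(under) / 3
  tt <- (mean(over) - mean(under)) / sqrt(s2o + s2u)
  df <- (s2o + s2u)^2 / (s2o^2 / 2 + s2u^2 / 2)
  expect_equal(p, 2 * pt(abs(tt), df, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(p, compare_gain_distributions(under, over))
  # identical groups: p = 1
  expect_equal(compare_gain_distributions(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(compare_gain_distributions(c(2, 2), c(2, 2)), 1)
})
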