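# Filtering track: probe aggregation, Welch/FDR filtering, fold-change
# ranking and grouped fold construction.

test_that("probe aggregation averages probes per gene and drops unmapped ones", {
  pm <- matrix(c(1, 3, 3, 5), nrow = 2, byrow = TRUE,
    dimnames = list(c("p1", "p2"), c("s1", "s2"))
  )
  mapping <- data.frame(probe_id = c("p1", "p2"), gene_symbol = "G")
  out <- aggregate_probes(pm, mapping)
  expect_equal(unname(out["G", ]), c(2, 4))

  # one probe per gene: identity on the mapped rows
  pm2 <- matrix(rnorm(6), nrow = 3,
    dimnames = list(c("p1", "p2", "p3"), c("s1", "s2"))
  )
  map2 <- data.frame(
    probe_id = c("p1", "p2"),
    gene_symbol = c("A", "B")
  )
  expect_message(out2 <- aggregate_probes(pm2, map2), "1 unmapped")
  expect_equal(attr(out2, "n_dropped"), 1L)
  expect_equal(out2["A", ], pm2["p1", ])
  expect_equal(out2["B", ], pm2["p2", ])

  # brute-force per-gene loop oracle on random input
  set.seed(4)
  pm3 <- matrix(rnorm(40), nrow = 10,
    dimnames = list(sprintf("p%02d", 1:10), sprintf("s%d", 1:4))
  )
  map3 <- data.frame(
    probe_id = rownames(pm3),
    gene_symbol = rep(c("g1", "g2", "g3"), c(5, 3, 2))
  )
  out3 <- aggregate_probes(pm3, map3)
  for (g in c("g1", "g2", "g3")) {
    probes <- map3$probe_id[map3$gene_symbol == g]
    oracle <- colMeans(pm3[probes, , drop = FALSE])
    expect_equal(out3[g, ], oracle, tolerance = 1e-12)
  }
  expect_error(aggregate_probes(pm3, data.frame()), "non-empty")
})

test_that("Welch t and BH q-values match the stats-package oracle", {
  set.seed(10)
  n <- 24
  expr <- matrix(rnorm(50 * n), nrow = 50,
    dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:n))
  )
  y <- toy_labels(n)
  flt <- welch_fdr_filter(expr, y, fdr_cutoff = 0.1)
  p_oracle <- apply(expr, 1, function(x) {
    t.test(x[y == "affected"], x[y == "control"], var.equal = FALSE)$p.value
  })
  t_oracle <- apply(expr, 1, function(x) {
    t.test(x[y == "affected"], x[y == "control"], var.equal = FALSE)$statistic
  })
  expect_equal(flt$p, unname(p_oracle), tolerance = 1e-10)
  expect_equal(flt$t, unname(t_oracle), tolerance = 1e-10)
  expect_equal(flt$q, unname(p.adjust(p_oracle, "BH")), tolerance = 1e-10)
  expect_equal(
    flt$fold_change,
    unname(rowMeans(expr[, y == "affected"]) - rowMeans(expr[, y == "control"])),
    tolerance = 1e-12
  )
  # q-values monotone in p-value order
  ord <- order(flt$p)
  expect_true(all(diff(flt$q[ord]) >= -1e-12))
})

test_that("degenerate genes get p = 1 and boundary cutoffs behave", {
  expr <- rbind(
    flat = rep(2, 10),
    real = c(rnorm(5, 3), rnorm(5))
  )
  colnames(expr) <- sprintf("s%02d", 1:10)
  y <- toy_labels(10)
  expect_message(flt <- welch_fdr_filter(expr, y), "zero-variance")
  expect_equal(flt$p[flt$gene == "flat"], 1)
  expect_false(flt$retained[flt$gene == "flat"])
  # cutoff 1 retains everything
  flt2 <- suppressMessages(welch_fdr_filter(expr, y, fdr_cutoff = 1))
  expect_true(all(flt2$retained))
})

test_that("fold-change ranking is by absolute value with deterministic ties", {
  flt <- structure(
    data.frame(
      gene = c("up", "down", "tiny"),
      t = c(3, -3, 0.1), df = 10, p = c(0.01, 0.01, 0.9),
      q = c(0.02, 0.01, 0.9),
      fold_change = c(0.9, -0.96, 0.04),
      retained = TRUE, stringsAsFactors = FALSE
    ),
    class = c("filter_result", "data.frame")
  )
  pool <- rank_by_fold_change(flt, top_k = 2)
  expect_identical(pool$genes, c("down", "up"))
  # signed sort would instead put the up-regulated gene first
  pool_s <- rank_by_fold_change(flt, top_k = 2, signed = TRUE)
  expect_identical(pool_s$genes[1], "up")
  # top_k beyond the pool: a permutation of the retained genes
  pool_all <- rank_by_fold_change(flt, top_k = 10)
  expect_setequal(pool_all$genes, flt$gene)
  # |fold change| ties break by smaller q, then symbol
  flt2 <- flt
  flt2$fold_change <- c(0.5, -0.5, 0.5)
  flt2$q <- c(0.05, 0.01, 0.05)
  pool2 <- rank_by_fold_change(flt2, top_k = 3)
  expect_identical(pool2$genes, c("down", "tiny", "up"))
  # nothing retained is an explicit error
  flt3 <- flt
  flt3$retained <- FALSE
  expect_error(rank_by_fold_change(flt3), "no gene passed")
})

test_that("filtering then ranking is idempotent on the reduced matrix", {
  set.seed(8)
  d <- perfect_gene_data(n_genes = 40, n = 20, seed = 8)
  flt <- suppressMessages(welch_fdr_filter(d$expr, d$labels, fdr_cutoff = 1))
  pool <- rank_by_fold_change(flt, d$expr, top_k = 20)
  flt2 <- suppressMessages(welch_fdr_filter(pool$expr, d$labels, fdr_cutoff = 1))
  pool2 <- rank_by_fold_change(flt2, pool$expr, top_k = 20)
  expect_identical(pool$genes, pool2$genes)
})

test_that("grouped folds keep subjects intact and balance classes and strata", {
  ds <- simulate_expression(synth_config(
    n_genes = 10, n_subjects = 30, samples_per_subject = 2,
    n_informative = 0, n_redundancy_blocks = 0, block_size = 0, seed = 1
  ))
  # 30 subjects, 15 per class, 3 folds: each test fold gets 5 + 5 subjects
  plan <- make_grouped_folds(ds$annotation, n_folds = 3, seed = 1)
  for (f in plan$folds) {
    test_subj <- unique(ds$annotation$subject_id[
      ds$annotation$sample_id %in% f$test
    ])
    cl <- ds$annotation$class_label[match(test_subj, ds$annotation$subject_id)]
    expect_equal(as.vector(table(cl)), c(5L, 5L))
  }
  # 6 subjects x 2 samples, 3 folds: each test set = exactly 2 whole subjects
  ann6 <- ds$annotation[ds$annotation$subject_id %in%
    unique(ds$annotation$subject_id)[c(1:3, 16:18)], ]
  plan6 <- make_grouped_folds(ann6, n_folds = 3, seed = 2)
  for (f in plan6$folds) {
    expect_length(f$test, 4L)
    expect_length(unique(ann6$subject_id[ann6$sample_id %in% f$test]), 2L)
  }
  expect_error(
    make_grouped_folds(ann6, n_folds = 4),
    "at least n_folds subjects"
  )
})

test_that("no subject ever straddles train and test, for any seed", {
  ds <- simulate_expression(synth_config(
    n_genes = 5, n_subjects = 17, samples_per_subject = 3,
    n_informative = 0, n_redundancy_blocks = 0, block_size = 0,
    class_balance = 0.4, seed = 2
  ))
  for (seed in 1:20) {
    plan <- make_grouped_folds(ds$annotation, n_folds = 3, seed = seed)
    all_test <- unlist(lapply(plan$folds, `[[`, "test"))
    expect_setequal(all_test, ds$annotation$sample_id)
    for (f in plan$folds) {
      tr <- unique(ds$annotation$subject_id[ds$annotation$sample_id %in% f$train])
      te <- unique(ds$annotation$subject_id[ds$annotation$sample_id %in% f$test])
      expect_length(intersect(tr, te), 0L)
    }
  }
})
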