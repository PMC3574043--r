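# End-to-end pipeline driver: simulate -> filter/folds -> GA + rankers ->
# evaluation -> pair statistics -> enrichment, with per-stage seeds
# derived from one global seed and a manifest of every artifact written.

#' Pipeline configuration
#'
#' Bundles the per-stage settings of [run_pipeline()]. Every stochastic
#' stage derives its own seed from the global seed plus the stage name,
#' so enabling or reordering stages never perturbs the other stages'
#' random streams. The defaults are sized for a desk-scale synthetic
#' study.
#'
#' @param synth A [synth_config()] (its `seed` is overridden by the
#'   derived stage seed).
#' @param fdr_cutoff FDR cutoff of the expression filter.
#' @param top_k Candidate-pool size after fold-change ranking.
#' @param n_folds Grouped cross-validation folds.
#' @param ga A [ga_config()] or `NULL` to derive a reduced configuration
#'   from the pool size at run time.
#' @param ga_runs GA/SVM repeats for the frequency ranking and pair
#'   analysis.
#' @param rf_trees,rf_repeats Random-forest importance settings.
#' @param k_values Top-k sizes of the accuracy evaluation.
#' @param mi_top Genes profiled for pairwise mutual information.
#' @param pair_top Significant pairs (per direction) scored with the pair
#'   SVM.
#' @param enrich_sizes Sizes of the enrichment sweep.
#' @param global_seed Global integer seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(
                              n_genes = 300, n_subjects = 30,
                              samples_per_subject = 4, n_informative = 10,
                              effect_size = 1.5, n_redundancy_blocks = 2,
                              block_size = 4, block_correlation = 0.8,
                              block_effect_size = 1.0
                            ),
                            fdr_cutoff = 0.1, top_k = 100, n_folds = 3,
                            ga = NULL, ga_runs = 30,
                            rf_trees = 300, rf_repeats = 3,
                            k_values = c(20, 10, 5, 3, 1), mi_top = 20,
                            pair_top = 10,
                            enrich_sizes = seq(10, 50, by = 10),
                            global_seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic biomarker pipeline
#'
#' Executes the stages in dependency order on a synthetic dataset:
#' simulation, expression filtering and fold construction, repeated GA/SVM
#' selection, baseline rankings and rank combination, mutual-information
#' profiling, pair joint-occurrence statistics with SVM accuracy gains,
#' and enrichment of each ranking against truth-derived reference lists.
#' All tabular artifacts are written as TSV under `out_dir` and listed in
#' the returned manifest; rerunning with the same configuration
#' reproduces them byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage `results` and the
#'   `manifest` data frame (`file`, `stage`, `seed`), which is also
#'   written to `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- NULL
  note <- function(file, stage, seed = NA_integer_) {
    manifest <<- rbind(manifest, data.frame(
      file = file, stage = stage, seed = seed, stringsAsFactors = FALSE
    ))
  }
  seed_of <- function(stage) derive_seed(config$global_seed, stage)

  # simulate
  sc <- config$synth
  sc$seed <- seed_of("simulate")
  ds <- simulate_expression(sc)
  write_expression(ds$expr, file.path(out_dir, "expression.tsv"))
  write_annotation(ds$annotation, file.path(out_dir, "annotation.tsv"))
  jsonlite::write_json(ds$truth, file.path(out_dir, "truth.json"),
    auto_unbox = FALSE, digits = NA
  )
  note("expression.tsv", "simulate", sc$seed)
  note("annotation.tsv", "simulate", sc$seed)
  note("truth.json", "simulate", sc$seed)

  # filter + candidate pool
  flt <- welch_fdr_filter(ds$expr, ds$annotation, config$fdr_cutoff)
  pool <- rank_by_fold_change(flt, ds$expr, top_k = config$top_k)
  utils::write.table(pool$table, file.path(out_dir, "filter.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  note("filter.tsv", "filter")

  # folds
  fold_seed <- seed_of("folds")
  plan <- make_grouped_folds(ds$annotation, config$n_folds, seed = fold_seed)
  jsonlite::write_json(
    list(assignment = plan$assignment, folds = plan$folds),
    file.path(out_dir, "folds.json"),
    auto_unbox = FALSE, digits = NA
  )
  note("folds.json", "folds", fold_seed)

  # GA/SVM runs on the whole candidate pool (biomarker-ranking track)
  ga_cfg <- config$ga
  if (is.null(ga_cfg)) {
    ga_cfg <- ga_config(length(pool$genes),
      population_size = 40, generations = 8, n_offspring = 32,
      n_mutants = 4, init_inclusion_prob = min(1, 10 / length(pool$genes))
    )
  } else if (ga_cfg$n_genes != length(pool$genes)) {
    # the filter may retain fewer genes than the configured pool size
    ga_cfg$n_genes <- length(pool$genes)
  }
  ga_seed <- seed_of("ga")
  runs <- ga_svm_runs(pool$expr, ds$annotation, ga_cfg,
    n_runs = config$ga_runs, base_seed = ga_seed
  )
  write_gene_sets(runs$sets, file.path(out_dir, "ga_sets.txt"))
  write_ranked_list(runs$frequency, file.path(out_dir, "rank_ga.tsv"))
  note("ga_sets.txt", "ga", ga_seed)
  note("rank_ga.tsv", "ga", ga_seed)

  # baseline rankers + combination
  labels <- labels_for(pool$expr, ds$annotation)
  ig <- information_gain_rank(pool$expr, labels)
  rf_seed <- seed_of("rf")
  rf <- rf_importance_rank(pool$expr, labels,
    n_trees = config$rf_trees, n_repeats = config$rf_repeats, seed = rf_seed
  )
  combined <- combine_ranks(list(runs$frequency, ig, rf), top_n = 20)
  write_ranked_list(ig, file.path(out_dir, "rank_ig.tsv"))
  write_ranked_list(rf, file.path(out_dir, "rank_rf.tsv"))
  write_ranked_list(combined, file.path(out_dir, "rank_combined.tsv"))
  note("rank_ig.tsv", "rank")
  note("rank_rf.tsv", "rank", rf_seed)
  note("rank_combined.tsv", "rank")

  # mutual-information redundancy profile of the top genes per method
  mi_summary <- NULL
  for (nm in c("ga", "ig", "rf")) {
    rl <- switch(nm, ga = runs$frequency, ig = ig, rf = rf)
    top <- rl$gene[seq_len(min(config$mi_top, nrow(rl)))]
    mi <- pairwise_mutual_information(ds$expr, top)
    mi_summary <- rbind(mi_summary, data.frame(
      method = nm, mean_mi = attr(mi, "mean"), median_mi = attr(mi, "median")
    ))
  }
  utils::write.table(mi_summary, file.path(out_dir, "mi_summary.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  note("mi_summary.tsv", "evaluate")

  # pair joint-occurrence statistics + SVM gains for the top pairs
  stats <- pair_statistics(runs$sets)
  utils::write.table(stats, file.path(out_dir, "pairs.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  note("pairs.tsv", "pairs")
  sig <- stats[stats$significant, , drop = FALSE]
  pair_seed <- seed_of("pair_svm")
  acc <- NULL
  for (dir in c("over", "under")) {
    d <- sig[sig$direction == dir, , drop = FALSE]
    d <- d[order(-abs(d$importance_jo)), , drop = FALSE]
    d <- d[seq_len(min(config$pair_top, nrow(d))), , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      pa <- pair_svm_accuracy(ds$expr, ds$annotation, d$gene_i[i],
        d$gene_j[i],
        seed = pair_seed
      )
      acc <- rbind(acc, data.frame(
        gene_i = d$gene_i[i], gene_j = d$gene_j[i], direction = dir,
        acc_i = pa$acc_i, acc_j = pa$acc_j, acc_ij = pa$acc_ij,
        gain_mean = pa$gain_mean, gain_min = pa$gain_min,
        stringsAsFactors = FALSE
      ))
    }
  }
  if (!is.null(acc)) {
    utils::write.table(acc, file.path(out_dir, "pair_accuracy.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    note("pair_accuracy.tsv", "pairs", pair_seed)
  }

  # enrichment of each ranking against truth-derived reference lists
  ref_seed <- seed_of("reference_lists")
  refs <- generate_reference_lists(ds,
    fraction = 1, n_fillers = 10,
    n_decoys = 1, decoy_size = 30, seed = ref_seed
  )
  sweep <- enrichment_sweep(runs$frequency, refs, rownames(ds$expr),
    sizes = config$enrich_sizes
  )
  utils::write.table(sweep$results, file.path(out_dir, "enrichment.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  note("enrichment.tsv", "enrich", ref_seed)

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = FALSE, digits = NA
  )
  note("manifest.json", "manifest")

  invisible(list(
    results = list(
      dataset = ds, filter = flt, pool = pool, fold_plan = plan,
      ga_runs = runs, rankings = list(ga = runs$frequency, ig = ig, rf = rf),
      combined = combined, mi_summary = mi_summary, pair_stats = stats,
      pair_accuracy = acc, enrichment = sweep
    ),
    manifest = manifest
  ))
}
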