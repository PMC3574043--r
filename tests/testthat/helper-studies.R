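# Lazily built, session-cached study objects shared by the acceptance
# tests. Each study is fully determined by the fixed seeds below.

# GA recovery study: 500-gene, 120-sample dataset with 10 planted markers
# (1.5 sigma), 50 reduced GA/SVM runs. The initial per-gene inclusion
# rate stays at the published 1.5 percent.
recovery_study <- function() {
  cached("recovery_study", function() {
    ds <- simulate_expression(synth_config(
      n_genes = 500, n_subjects = 30, samples_per_subject = 4,
      n_informative = 10, effect_size = 1.5, n_redundancy_blocks = 0,
      block_size = 0, subject_effect_sd = 0.5, seed = 101
    ))
    cfg <- ga_config(500,
      population_size = 60, generations = 12, n_offspring = 48,
      n_mutants = 6, init_inclusion_prob = 0.015
    )
    runs <- ga_svm_runs(ds$expr, ds$annotation, cfg,
      n_runs = 50, base_seed = 11
    )
    list(dataset = ds, runs = runs)
  })
}

# Redundancy study plus its 200 GA/SVM runs and marginal rankings.
redundancy_study_runs <- function() {
  cached("redundancy_study_runs", function() {
    ds <- make_redundancy_study(seed = 1)
    cfg <- small_ga_config(nrow(ds$expr), pop = 20, gens = 4, init = 8)
    runs <- ga_svm_runs(ds$expr, ds$annotation, cfg,
      n_runs = 200, base_seed = 7
    )
    labels <- factor(ds$annotation$class_label)
    ig <- information_gain_rank(ds$expr, labels)
    list(dataset = ds, runs = runs, ig = ig)
  })
}

# Synergy study plus its 200 GA/SVM runs and pair statistics.
synergy_study_runs <- function() {
  cached("synergy_study_runs", function() {
    d <- make_synergy_study(seed = 1)
    cfg <- ga_config(nrow(d$expr),
      population_size = 24, generations = 5,
      n_offspring = 19, n_mutants = 2,
      init_inclusion_prob = 6 / nrow(d$expr)
    )
    runs <- ga_svm_runs(d$expr, d$labels, cfg, n_runs = 200, base_seed = 42)
    stats <- pair_statistics(runs$sets)
    list(study = d, runs = runs, stats = stats)
  })
}
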