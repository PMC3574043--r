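library(gasvm)
ds <- simulate_expression(synth_config(
  n_genes = 500, n_subjects = 30, samples_per_subject = 4,
  n_informative = 10, effect_size = 1.5, n_redundancy_blocks = 0,
  block_size = 0, subject_effect_sd = 0.5, seed = 101))
for (gens in c(12, 20)) {
  cfg <- ga_config(500, population_size = 60, generations = gens,
                   n_offspring = 48, n_mutants = 6,
                   init_inclusion_prob = 0.015)
  runs <- ga_svm_runs(ds$expr, ds$annotation, cfg, n_runs = 12, base_seed = 1)
  sizes <- lengths(runs$sets)
  cat("gens", gens, "sizes:", sort(sizes), "\n")
}
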