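# Shared fixture builders. Everything is generated in code from fixed
# seeds; expensive study objects used by several tests are cached per
# session in `.fixture_cache`.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# balanced two-class labels
toy_labels <- function(n) {
  factor(rep(c("affected", "control"), each = n / 2))
}

# matrix with one perfectly separating gene among noise
perfect_gene_data <- function(n_genes = 50, n = 30, seed = 1) {
  set.seed(seed)
  y <- toy_labels(n)
  expr <- matrix(rnorm(n_genes * n),
    nrow = n_genes,
    dimnames = list(sprintf("g%03d", seq_len(n_genes)), sprintf("s%02d", seq_len(n)))
  )
  expr["g001", ] <- ifelse(y == "affected", 3, -3) + rnorm(n, sd = 0.1)
  list(expr = expr, labels = y)
}

# two genes separable only jointly: the class is which of the two is larger
synergy_pair_data <- function(n = 80, d = 1.5, latent_sd = 2, noise_sd = 0.5,
                              seed = 1) {
  set.seed(seed)
  y <- toy_labels(n)
  sgn <- ifelse(y == "affected", 1, -1)
  u <- rnorm(n, sd = latent_sd)
  a <- u + d / 2 * sgn + rnorm(n, sd = noise_sd)
  b <- u - d / 2 * sgn + rnorm(n, sd = noise_sd)
  expr <- rbind(synA = a, synB = b)
  colnames(expr) <- sprintf("s%02d", seq_len(n))
  list(expr = expr, labels = y)
}

# multi-pair synergy study: several planted synergy pairs, a group of
# identical copies of one strong marker, and background noise
make_synergy_study <- function(n_pairs = 6, n_copies = 4, n_noise = 22,
                               n = 80, seed = 1) {
  set.seed(seed)
  y <- toy_labels(n)
  sgn <- ifelse(y == "affected", 1, -1)
  rows <- list()
  for (p in seq_len(n_pairs)) {
    u <- rnorm(n, sd = 2)
    rows[[paste0("synA", p)]] <- u + 0.75 * sgn + rnorm(n, sd = 0.5)
    rows[[paste0("synB", p)]] <- u - 0.75 * sgn + rnorm(n, sd = 0.5)
  }
  base <- 1.2 * sgn + rnorm(n)
  for (k in seq_len(n_copies)) rows[[paste0("dup", k)]] <- base
  for (k in seq_len(n_noise)) rows[[paste0("noise", k)]] <- rnorm(n)
  expr <- do.call(rbind, rows)
  colnames(expr) <- sprintf("s%02d", seq_len(n))
  list(
    expr = expr, labels = y,
    pairs = data.frame(
      gene_i = paste0("synA", seq_len(n_pairs)),
      gene_j = paste0("synB", seq_len(n_pairs)), stringsAsFactors = FALSE
    ),
    dup_group = paste0("dup", seq_len(n_copies))
  )
}

# redundancy study: 18 unique informative genes, one standout marker
# duplicated into 5 identical rows, and strongly informative redundancy
# blocks (marginally stronger than the unique genes, so marginal rankers
# favour the correlated families)
make_redundancy_study <- function(seed = 1) {
  cfg <- synth_config(
    n_genes = 110, n_subjects = 20, samples_per_subject = 4,
    n_informative = 19, effect_size = 1.2, n_redundancy_blocks = 3,
    block_size = 5, block_correlation = 0.8, block_effect_size = 3.7,
    subject_effect_sd = 0.5, seed = seed
  )
  ds <- simulate_expression(cfg)
  aff <- ds$annotation$class_label == "affected"
  ds$expr["g0001", aff] <- ds$expr["g0001", aff] + 0.8
  bg <- setdiff(rownames(ds$expr), c(
    ds$truth$informative_genes,
    unlist(ds$truth$redundancy_blocks)
  ))
  dup_rows <- bg[1:4]
  for (r in dup_rows) ds$expr[r, ] <- ds$expr["g0001", ]
  ds$dup_group <- c("g0001", dup_rows)
  ds
}

# reduced GA configuration for desk-scale studies
small_ga_config <- function(n_genes, pop = 20, gens = 4, init = 8) {
  ga_config(n_genes,
    population_size = pop, generations = gens,
    n_offspring = round(0.8 * pop), n_mutants = max(1, round(0.1 * pop)),
    init_inclusion_prob = min(1, init / n_genes)
  )
}
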